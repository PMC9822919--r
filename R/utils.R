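## Internal helpers shared across modules.

## Run expr with a private RNG stream; the caller's RNG state is untouched.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Marginal simple-regression summary statistics of y on each column of G.
## Returns beta, se, p (t-based, df = n - 2) and the column means.
marginalStats <- function(G, y) {
  n <- length(y)
  stopifnot(nrow(G) == n, n > 2)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  gm <- colMeans(G)
  sxx <- colSums(G * G) - n * gm^2
  sxy <- as.vector(crossprod(G, yc))
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  sse <- pmax(syy - beta * sxy, 0)
  se <- ifelse(sxx > 0, sqrt(sse / ((n - 2) * sxx)), NA_real_)
  tt <- beta / se
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  ## numerically zero p-values are floored to the smallest double so that
  ## downstream p in (0, 1] invariants hold
  p <- pmax(p, .Machine$double.xmin)
  data.frame(beta = beta, se = se, p = p, mean_dosage = gm)
}

## TSV writers keep full double precision so read(write(x)) is exact.
writeTsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

readTsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

isPalindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

## Allele orientation of (a1, a2) relative to reference (r1, r2):
## "same", "swapped" or "mismatch".
alleleOrientation <- function(a1, a2, r1, r2) {
  out <- rep("mismatch", length(a1))
  out[a1 == r1 & a2 == r2] <- "same"
  out[a1 == r2 & a2 == r1] <- "swapped"
  out
}

stripGeneVersion <- function(x) sub("\\.[0-9]+$", "", x)
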