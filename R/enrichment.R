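#' @include utils.R
NULL

#' Gene-set over-representation test
#'
#' Upper-tail hypergeometric test of a query gene list against each gene
#' set: with \code{N} background genes, \code{K} of them in the set and a
#' query of size \code{n} overlapping the set in \code{k} genes, the
#' p-value is \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, n).
#' P-values are Benjamini-Hochberg adjusted across all tested sets; sets
#' overlapping the query in fewer than \code{minOverlap} genes are omitted
#' from the output (after adjustment).
#'
#' Query and set genes outside the background are dropped with a warning.
#'
#' @param query character vector of gene IDs.
#' @param sets named list of character vectors (gene sets), e.g. from
#'   \code{\link{readGmt}}.
#' @param background character vector of background gene IDs (the gene
#'   universe; typically all genes with a model in the focal tissue).
#' @param minOverlap minimum overlap for a set to be reported (default 1).
#' @return data.frame with columns \code{set_name}, \code{overlap},
#'   \code{set_size}, \code{query_size}, \code{background_size},
#'   \code{pvalue}, \code{p_adj}, \code{genes} (comma-separated overlap).
#' @examples
#' bg <- sprintf("g%02d", 1:20)
#' hypergeometricEnrichment(bg[1:5], list(s1 = bg[1:6], s2 = bg[7:20]), bg)
#' @export
hypergeometricEnrichment <- function(query, sets, background,
                                     minOverlap = 1) {
  background <- unique(background)
  if (!length(background)) stop("background gene list is empty")
  qOut <- setdiff(query, background)
  if (length(qOut))
    warning(length(qOut), " query gene(s) outside background dropped")
  query <- unique(intersect(query, background))
  if (!length(query)) {
    warning("empty query after background filtering")
    return(data.frame(set_name = character(), overlap = integer(),
                      set_size = integer(), query_size = integer(),
                      background_size = integer(), pvalue = numeric(),
                      p_adj = numeric(), genes = character(),
                      stringsAsFactors = FALSE))
  }
  N <- length(background)
  n <- length(query)
  dropped <- sum(vapply(sets, function(s) length(setdiff(s, background)),
                        integer(1)))
  if (dropped)
    warning(dropped, " set gene(s) outside background dropped")
  rows <- lapply(names(sets), function(nm) {
    s <- unique(intersect(sets[[nm]], background))
    if (!length(s)) return(NULL)
    ov <- intersect(query, s)
    k <- length(ov)
    K <- length(s)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = K, query_size = n,
               background_size = N, pvalue = p,
               genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res) || !nrow(res)) {
    warning("no non-empty sets to test")
    return(data.frame(set_name = character(), overlap = integer(),
                      set_size = integer(), query_size = integer(),
                      background_size = integer(), pvalue = numeric(),
                      p_adj = numeric(), genes = character(),
                      stringsAsFactors = FALSE))
  }
  res$p_adj <- stats::p.adjust(res$pvalue, method = "BH")
  res <- res[res$overlap >= minOverlap, , drop = FALSE]
  res <- res[order(res$pvalue), c("set_name", "overlap", "set_size",
                                  "query_size", "background_size",
                                  "pvalue", "p_adj", "genes")]
  rownames(res) <- NULL
  res
}

#' Read a GMT gene-set file
#'
#' GMT dialect: one set per line, tab-separated — set name, description,
#' then gene IDs.
#'
#' @param path file path.
#' @return named list of character vectors; descriptions are attached as
#'   \code{attr(, "descriptions")}.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad))
    stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[`, character(1), 2), names(sets))
  sets
}
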