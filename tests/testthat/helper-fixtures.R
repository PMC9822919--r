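# Fixtures built in code; no data files.

# A tiny GWAS summary data.frame with coherent alleles and z = beta/se.
toyGwas <- function() {
  data.frame(
    variant_id = c("v1", "v2", "v3"),
    chrom = "1", pos = c(100L, 200L, 300L),
    effect_allele = c("A", "T", "C"),
    other_allele = c("G", "C", "A"),
    eaf = c(0.3, 0.5, 0.2),
    beta = c(0.1, -0.05, 0.02),
    se = c(0.05, 0.02, 0.01),
    pvalue = c(0.0455, 0.0124, 0.0455),
    stringsAsFactors = FALSE)
}

writeToyTsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Deterministic toy panel: m variants, dosages drawn independently.
toyPanel <- function(n = 50, variants = NULL, seed = 99) {
  if (is.null(variants))
    variants <- data.frame(
      variant_id = c("v1", "v2", "v3"),
      chrom = "1", pos = c(100L, 200L, 300L),
      effect_allele = c("A", "T", "C"),
      other_allele = c("G", "C", "A"),
      freq = c(0.3, 0.5, 0.2),
      stringsAsFactors = FALSE)
  set.seed(seed)
  G <- sapply(variants$freq, function(f) stats::rbinom(n, 2, f))
  colnames(G) <- variants$variant_id
  LDPanel(G, variants)
}

# Independent brute-force clumping oracle: explicit greedy enumeration with
# hand-rolled Pearson correlation, no shared code with ldClump().
bruteClump <- function(candidates, G, r2 = 0.1, window = 250000) {
  ord <- order(candidates$pvalue, candidates$pos, candidates$variant_id)
  cand <- candidates[ord, , drop = FALSE]
  alive <- rep(TRUE, nrow(cand))
  kept <- character()
  pearson2 <- function(x, y) {
    n <- length(x)
    num <- n * sum(x * y) - sum(x) * sum(y)
    den <- (n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2)
    if (den <= 0) return(0)
    num^2 / den
  }
  while (any(alive)) {
    i <- which(alive)[1]
    kept <- c(kept, cand$variant_id[i])
    alive[i] <- FALSE
    for (j in which(alive)) {
      if (abs(cand$pos[j] - cand$pos[i]) <= window &&
          pearson2(G[, cand$variant_id[i]], G[, cand$variant_id[j]]) >= r2)
        alive[j] <- FALSE
    }
  }
  kept
}

# Minimal TissueResults builder for multi-tissue tests.
makeResults <- function(tissue, gene_id, pvalue, effect = NULL) {
  z <- -stats::qnorm(pvalue / 2)
  if (is.null(effect)) effect <- z * 0.01
  new("TissueResults", tissue = tissue,
      results = data.frame(
        gene_id = gene_id, tissue = tissue,
        zscore = z * sign(effect), effect = effect, se = abs(effect / z),
        pvalue = pvalue, sigma_g2 = 1,
        n_snps_model = 1L, n_snps_used = 1L, stringsAsFactors = FALSE),
      skipped = data.frame(gene_id = character(), reason = character(),
                           stringsAsFactors = FALSE))
}
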