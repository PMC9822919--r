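#' @include AllClasses.R utils.R io.R
NULL

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values for a vector of marginal p-values.  Input order
#' is preserved.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return numeric vector of adjusted values in (0, 1].
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03))
#' @export
fdrAdjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-variant expression variance explained
#'
#' Variance in expression explained by one biallelic variant under
#' Hardy-Weinberg equilibrium: 2 p q beta^2, with p the effect-allele
#' frequency, q = 1 - p, and beta the per-allele eQTL effect.
#'
#' @param eaf effect-allele frequency in [0, 1].
#' @param beta per-allele eQTL effect (SD of expression per allele).
#' @return 2 * eaf * (1 - eaf) * beta^2, vectorized.
#' @examples
#' snpVariance(0.5, 1)      # 0.5
#' snpVariance(0.2, 0.3)    # 0.0288
#' @export
snpVariance <- function(eaf, beta) {
  if (any(eaf < 0 | eaf > 1)) stop("eaf must lie in [0, 1]")
  2 * eaf * (1 - eaf) * beta^2
}

#' Greedy LD clumping
#'
#' Keeps the most significant remaining variant and discards every other
#' remaining variant within \code{windowBp} of it whose squared Pearson
#' dosage correlation (in the reference panel) is at least
#' \code{r2Threshold}; repeats until no candidates remain.  Ties in p are
#' broken by ascending (pos, variant_id) for determinism.
#'
#' @param candidates data.frame with columns \code{variant_id}, \code{pos}
#'   and \code{pvalue} (e.g. one gene's eQTL records).
#' @param panel an \code{\linkS4class{LDPanel}} containing every candidate.
#' @param r2Threshold squared-correlation threshold (default 0.1).
#' @param windowBp window half-width in bp (default 250000, i.e. +/-250 kb
#'   around the index variant).
#' @return character vector of retained variant IDs (in retention order).
#' @export
ldClump <- function(candidates, panel, r2Threshold = 0.1,
                    windowBp = 250000) {
  if (!nrow(candidates)) return(character())
  miss <- setdiff(candidates$variant_id,
                  variantInfo(panel)$variant_id)
  if (length(miss))
    stop("variant(s) missing from panel: ", paste(miss, collapse = ", "))
  ord <- order(candidates$pvalue, candidates$pos, candidates$variant_id)
  cand <- candidates[ord, , drop = FALSE]
  G <- panelGenotypes(panel)[, cand$variant_id, drop = FALSE]
  retained <- character()
  alive <- rep(TRUE, nrow(cand))
  while (any(alive)) {
    i <- which(alive)[1]
    retained <- c(retained, cand$variant_id[i])
    alive[i] <- FALSE
    near <- alive & abs(cand$pos - cand$pos[i]) <= windowBp
    if (any(near)) {
      r <- suppressWarnings(
        stats::cor(G[, i], G[, near, drop = FALSE]))
      r[is.na(r)] <- 0
      alive[which(near)[as.vector(r^2) >= r2Threshold]] <- FALSE
    }
  }
  retained
}

#' Build prediction models from eQTL summary statistics
#'
#' The four-stage builder: (1) FDR-adjust each gene's eQTL p-values
#' (Benjamini-Hochberg, within-gene by default) and drop records with
#' q >= \code{fdrThreshold}; (2) LD-clump the survivors against the
#' reference panel (greedy, \code{r2Threshold}, \code{windowBp}); (3) weight
#' each retained variant by its marginal eQTL beta and compute the
#' per-variant expression variance explained 2pq beta^2 and the gene total;
#' (4) exclude genes whose total falls strictly outside
#' \code{varBounds}.  Reference dosage covariances among each retained
#' gene's variants are attached for the association step.
#'
#' @param eqtls eQTL summary data.frame (see
#'   \code{\link{readEqtlSumstats}}); must carry \code{pos} per variant.
#' @param panel an \code{\linkS4class{LDPanel}}.
#' @param fdrThreshold within-gene FDR cut-off (default 0.1; records with
#'   adjusted q below this survive).
#' @param r2Threshold,windowBp clumping parameters (defaults 0.1, 250 kb).
#' @param varBounds length-2 numeric; genes with total variance explained
#'   strictly below \code{varBounds[1]} or strictly above
#'   \code{varBounds[2]} are excluded (defaults 0.01 and 2).
#' @param fdrScope \code{"within_gene"} (default) adjusts each gene's
#'   p-values separately; \code{"global"} adjusts across all records at
#'   once.
#' @param tissue tissue label for the resulting model set.
#' @return list with \code{models} (a \code{\linkS4class{GeneModelSet}})
#'   and \code{report}, a data.frame of gene/variant counts surviving each
#'   stage.
#' @examples
#' sc <- simScenario(seed = 1, nGenes = 5, nEqtl = 500, nPanel = 200)
#' panel <- simulatePanel(sc)
#' eq <- simulateEqtlSumstats(sc, "placenta")
#' fit <- buildModels(eq, panel, tissue = "placenta")
#' fit$report
#' @export
buildModels <- function(eqtls, panel, fdrThreshold = 0.1,
                        r2Threshold = 0.1, windowBp = 250000,
                        varBounds = c(0.01, 2.0),
                        fdrScope = c("within_gene", "global"),
                        tissue = "tissue") {
  fdrScope <- match.arg(fdrScope)
  emptyW <- data.frame(gene_id = character(), variant_id = character(),
                       effect_allele = character(),
                       other_allele = character(), weight = numeric(),
                       eaf = numeric(), var_explained = numeric(),
                       stringsAsFactors = FALSE)
  report <- function(stage, df) {
    data.frame(stage = stage,
               n_genes = length(unique(df$gene_id)),
               n_variants = nrow(df), stringsAsFactors = FALSE)
  }
  stages <- list(report("input", eqtls))
  if (!nrow(eqtls)) {
    stages <- c(stages, list(report("fdr", eqtls), report("clump", eqtls),
                             report("variance_filter", eqtls)))
    return(list(models = GeneModelSet(tissue, emptyW),
                report = do.call(rbind, stages)))
  }

  eq <- eqtls
  if (fdrScope == "within_gene") {
    eq$fdr_q <- stats::ave(eq$pvalue, eq$gene_id, FUN = fdrAdjust)
  } else {
    eq$fdr_q <- fdrAdjust(eq$pvalue)
  }
  eq <- eq[eq$fdr_q < fdrThreshold, , drop = FALSE]
  stages <- c(stages, list(report("fdr", eq)))

  if (nrow(eq)) {
    kept <- lapply(split(eq, eq$gene_id), function(g) {
      g[g$variant_id %in%
          ldClump(g, panel, r2Threshold, windowBp), , drop = FALSE]
    })
    eq <- do.call(rbind, kept)
    rownames(eq) <- NULL
  }
  stages <- c(stages, list(report("clump", eq)))

  if (nrow(eq)) {
    w <- data.frame(gene_id = eq$gene_id, variant_id = eq$variant_id,
                    effect_allele = eq$effect_allele,
                    other_allele = eq$other_allele,
                    weight = eq$beta, eaf = eq$eaf,
                    var_explained = snpVariance(eq$eaf, eq$beta),
                    stringsAsFactors = FALSE)
    ## deterministic order: gene, then position within gene
    w <- w[order(w$gene_id, eq$pos[match(w$variant_id, eq$variant_id)],
                 w$variant_id), , drop = FALSE]
    rownames(w) <- NULL
  } else w <- emptyW
  models <- GeneModelSet(tissue, w)
  models <- filterGeneVariance(models, varBounds[1], varBounds[2])
  stages <- c(stages, list(report("variance_filter", modelWeights(models))))

  models <- attachPanelCovariances(models, panel)
  list(models = models, report = do.call(rbind, stages))
}

## Pairwise reference dosage covariances among each gene's model variants
## (upper triangle incl. diagonal), stored on the model set.
attachPanelCovariances <- function(models, panel) {
  w <- modelWeights(models)
  if (!nrow(w)) return(models)
  G <- panelGenotypes(panel)
  out <- lapply(split(w$variant_id, w$gene_id), function(vids) {
    S <- stats::cov(G[, vids, drop = FALSE])
    ut <- which(upper.tri(S, diag = TRUE), arr.ind = TRUE)
    data.frame(variant_id_1 = vids[ut[, 1]], variant_id_2 = vids[ut[, 2]],
               covariance = S[ut], stringsAsFactors = FALSE)
  })
  cv <- do.call(rbind, Map(cbind,
                           gene_id = names(out), out,
                           stringsAsFactors = FALSE))
  rownames(cv) <- NULL
  new("GeneModelSet", tissue = tissueName(models), weights = w,
      genes = modelGenes(models), covariances = cv)
}
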