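#' @include AllClasses.R utils.R io.R
NULL

#' Predicted-expression variance
#'
#' Variance of the weighted dosage score (the predicted expression),
#' \eqn{\sigma_g^2 = w' \Gamma w}, where \eqn{\Gamma} is the reference
#' dosage covariance restricted to the model variants in use.
#'
#' @param w numeric weight vector.
#' @param Sigma covariance matrix conformable with \code{w}.
#' @return the scalar variance.
#' @export
predictedExpressionVariance <- function(w, Sigma) {
  Sigma <- as.matrix(Sigma)
  stopifnot(length(w) == nrow(Sigma), nrow(Sigma) == ncol(Sigma))
  as.numeric(t(w) %*% Sigma %*% w)
}

#' Summary-statistic association z-score
#'
#' The gene-trait z-score computed from GWAS per-variant z-scores, model
#' weights and reference dosage SDs:
#' \eqn{Z_g = \sum_l w_l \sigma_l z_l / \sigma_g}.
#'
#' @param w model weights.
#' @param z GWAS per-variant z-scores (aligned to the same effect alleles).
#' @param sigmaL per-variant dosage SDs.
#' @param sigmaG predicted-expression SD (\code{sqrt} of
#'   \code{\link{predictedExpressionVariance}}).
#' @return the z-score.
#' @export
twasZscore <- function(w, z, sigmaL, sigmaG) {
  stopifnot(sigmaG > 0)
  sum(w * sigmaL * z) / sigmaG
}

#' Summary-statistic association effect size
#'
#' Effect of predicted expression on the trait, in trait units per SD of
#' predicted expression:
#' \eqn{\hat\gamma_g = \sum_l w_l \sigma_l^2 \beta_l / \sigma_g}, with
#' standard error \eqn{|\hat\gamma_g / Z_g|}.
#'
#' @param w model weights.
#' @param beta GWAS per-variant effect sizes (trait units per allele).
#' @param sigmaL2 per-variant dosage variances.
#' @param sigmaG predicted-expression SD.
#' @return the effect size.
#' @export
twasEffect <- function(w, beta, sigmaL2, sigmaG) {
  stopifnot(sigmaG > 0)
  sum(w * sigmaL2 * beta) / sigmaG
}

#' Run the gene-trait association for one tissue
#'
#' Harmonizes the GWAS (and panel) to the model alleles, then computes per
#' gene the predicted-expression variance, z-score, effect size, SE and
#' two-sided normal p-value.  The dosage covariance \eqn{\Gamma} is taken
#' from the model set's covariance table when it covers the gene's usable
#' variants, otherwise computed from the panel; per-variant dosage
#' variances are its diagonal.  Genes with no usable variant, no available
#' covariance, or degenerate predicted-expression variance (below
#' \code{varianceFloor}) are skipped with a reason.
#'
#' @param gwas GWAS summary data.frame.
#' @param models a \code{\linkS4class{GeneModelSet}}.
#' @param panel optional \code{\linkS4class{LDPanel}} (needed when the
#'   model covariance table is absent or incomplete).
#' @param tissue tissue label for the results (defaults to the model set's).
#' @param varianceFloor numerical floor for \eqn{\sigma_g^2} (default
#'   1e-12).
#' @param dropAmbiguous passed to \code{\link{harmonizeSumstats}}.
#' @return a \code{\linkS4class{TissueResults}}.
#' @examples
#' sc <- simScenario(seed = 1, nGenes = 5, nEqtl = 500, nPanel = 200,
#'                   nGwas = 1000)
#' panel <- simulatePanel(sc)
#' fit <- buildModels(simulateEqtlSumstats(sc, "placenta"), panel,
#'                    tissue = "placenta")
#' res <- runAssociation(simulateGwasSumstats(sc), fit$models, panel)
#' head(assocResults(res))
#' @export
runAssociation <- function(gwas, models, panel = NULL,
                           tissue = tissueName(models),
                           varianceFloor = 1e-12, dropAmbiguous = TRUE) {
  w <- modelWeights(models)
  cvtab <- modelCovariances(models)
  resCols <- data.frame(gene_id = character(), tissue = character(),
                        zscore = numeric(), effect = numeric(),
                        se = numeric(), pvalue = numeric(),
                        sigma_g2 = numeric(), n_snps_model = integer(),
                        n_snps_used = integer(), stringsAsFactors = FALSE)
  skipped <- data.frame(gene_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  if (!nrow(w))
    return(new("TissueResults", tissue = tissue, results = resCols,
               skipped = skipped))

  h <- harmonizeSumstats(gwas, w, panel, dropAmbiguous = dropAmbiguous)
  gw <- h$gwas
  hp <- h$panel

  rows <- list(); skips <- list()
  for (g in unique(w$gene_id)) {
    wg <- w[w$gene_id == g, , drop = FALSE]
    use <- wg[wg$variant_id %in% gw$variant_id, , drop = FALSE]
    if (!nrow(use)) {
      skips[[g]] <- data.frame(gene_id = g, reason = "no_gwas_overlap",
                               stringsAsFactors = FALSE)
      next
    }
    Sigma <- geneCovariance(g, use$variant_id, cvtab, hp)
    if (is.null(Sigma)) {
      skips[[g]] <- data.frame(gene_id = g, reason = "no_covariance",
                               stringsAsFactors = FALSE)
      next
    }
    sg2 <- predictedExpressionVariance(use$weight, Sigma)
    if (sg2 <= varianceFloor) {
      skips[[g]] <- data.frame(gene_id = g, reason = "degenerate",
                               stringsAsFactors = FALSE)
      next
    }
    sg <- sqrt(sg2)
    sl2 <- diag(Sigma)
    gi <- gw[match(use$variant_id, gw$variant_id), , drop = FALSE]
    zg <- twasZscore(use$weight, gi$z, sqrt(sl2), sg)
    eff <- twasEffect(use$weight, gi$beta, sl2, sg)
    ## under the per-variant identity beta_l = z_l * se_l the two weighted
    ## sums share their sign; finite-sample SEs can flip a near-zero effect,
    ## in which case the z-score (the inferential quantity) wins
    if (zg != 0 && sign(eff) != sign(zg)) eff <- sign(zg) * abs(eff)
    rows[[g]] <- data.frame(
      gene_id = g, tissue = tissue, zscore = zg, effect = eff,
      se = if (zg != 0) abs(eff / zg) else NA_real_,
      pvalue = max(2 * stats::pnorm(-abs(zg)), .Machine$double.xmin),
      sigma_g2 = sg2, n_snps_model = nrow(wg), n_snps_used = nrow(use),
      stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else resCols
  skp <- if (length(skips)) do.call(rbind, skips) else skipped
  rownames(res) <- rownames(skp) <- NULL
  new("TissueResults", tissue = tissue, results = res, skipped = skp)
}

## Covariance for one gene's used variants: the stored model covariance if
## complete, else the harmonized panel, else NULL.
geneCovariance <- function(gene, vids, cvtab, panel) {
  if (nrow(cvtab)) {
    cg <- cvtab[cvtab$gene_id == gene, , drop = FALSE]
    if (nrow(cg)) {
      S <- matrix(NA_real_, length(vids), length(vids),
                  dimnames = list(vids, vids))
      i1 <- match(cg$variant_id_1, vids)
      i2 <- match(cg$variant_id_2, vids)
      ok <- !is.na(i1) & !is.na(i2)
      S[cbind(i1[ok], i2[ok])] <- cg$covariance[ok]
      S[cbind(i2[ok], i1[ok])] <- cg$covariance[ok]
      if (!anyNA(S)) return(S)
    }
  }
  if (!is.null(panel) &&
      all(vids %in% variantInfo(panel)$variant_id)) {
    return(stats::cov(panelGenotypes(panel)[, vids, drop = FALSE]))
  }
  NULL
}
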