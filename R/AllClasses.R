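#' @import methods
NULL

## ---------------------------------------------------------------------------
## LDPanel
## ---------------------------------------------------------------------------

#' Reference genotype panel
#'
#' An \code{LDPanel} holds a dosage matrix (individuals in rows, variants in
#' columns, values 0/1/2 counting copies of the effect allele) together with
#' per-variant metadata.  The panel supplies the pairwise dosage correlations
#' used for LD clumping and the dosage covariance used in the denominator of
#' the summary-statistic association z-score.
#'
#' The \code{freq} column of the variant table is the population frequency of
#' the effect allele used when the panel was generated (or estimated); the
#' realised in-sample frequency is available via \code{\link{alleleFreqs}}.
#'
#' @slot genotypes numeric matrix, \code{n_individuals x n_variants}, dosages
#'   in \{0, 1, 2\}; columns named by \code{variant_id}.
#' @slot variants data.frame with columns \code{variant_id}, \code{chrom},
#'   \code{pos} (1-based bp), \code{effect_allele}, \code{other_allele},
#'   \code{freq}.
#'
#' @seealso \code{\link{simulatePanel}}, \code{\link{ldClump}},
#'   \code{\link{runAssociation}}
#' @export
setClass("LDPanel",
  representation(genotypes = "matrix", variants = "data.frame"))

setValidity("LDPanel", function(object) {
  msg <- character()
  g <- object@genotypes
  v <- object@variants
  need <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
            "freq")
  if (!all(need %in% names(v)))
    msg <- c(msg, paste0("variant table must have columns: ",
                         paste(setdiff(need, names(v)), collapse = ", ")))
  else {
    if (ncol(g) != nrow(v))
      msg <- c(msg, "ncol(genotypes) must equal nrow(variants)")
    else if (!identical(colnames(g), as.character(v$variant_id)))
      msg <- c(msg, "colnames(genotypes) must match variants$variant_id")
    if (any(v$freq < 0 | v$freq > 1))
      msg <- c(msg, "allele frequencies must lie in [0, 1]")
  }
  if (length(g) && !all(g %in% c(0, 1, 2)))
    msg <- c(msg, "dosages must be 0, 1 or 2")
  if (length(msg)) msg else TRUE
})

#' Construct an LDPanel
#'
#' @param genotypes dosage matrix (individuals x variants, values 0/1/2).
#' @param variants variant metadata data.frame (see \code{\linkS4class{LDPanel}}).
#' @return an \code{LDPanel} object.
#' @export
LDPanel <- function(genotypes, variants) {
  genotypes <- as.matrix(genotypes)
  colnames(genotypes) <- as.character(variants$variant_id)
  new("LDPanel", genotypes = genotypes, variants = variants)
}

## ---------------------------------------------------------------------------
## SimScenario
## ---------------------------------------------------------------------------

#' Simulation scenario
#'
#' A \code{SimScenario} fixes every parameter of the synthetic study: cohort
#' sizes, the blocked-LD genotype model, the sparse cis-eQTL architecture
#' shared across tissues, and the trait model in which the phenotype is partly
#' mediated by the genetically-regulated expression (GReX) of designated true
#' genes.  A scenario plus its seed fully determines all generated data.
#'
#' Genes are laid out one per chromosome with \code{mPerGene} cis variants at
#' \code{variantSpacing} bp intervals, so each gene's cis window is disjoint
#' from every other gene's.  Variants are grouped into haplotype blocks of
#' \code{blockSize} adjacent variants; within a block adjacent haplotypes have
#' allele correlation \code{rho} (so allele correlation decays as
#' \code{rho^distance}), across blocks variants are independent.  Each block
#' draws one effect-allele frequency uniformly from \code{mafRange}; the
#' block-constant frequency is what makes the adjacent-variant correlation
#' exactly \code{rho} under the haplotype-copy model.
#'
#' \code{trueGenes} maps gene IDs to \code{alpha}, the trait effect per SD of
#' focal-tissue GReX; genes flagged \code{exclusive} receive causal eQTL sets
#' that are disjoint across tissues, so only the focal-tissue model tags the
#' trait signal.
#'
#' @slot seed integer; drives all randomness.
#' @slot nPanel,nEqtl,nGwas integer cohort sizes (reference panel, eQTL
#'   cohort, GWAS cohort); the three cohorts are independent draws from the
#'   same population.
#' @slot nGenes,mPerGene integer; number of genes and cis variants per gene.
#' @slot blockSize integer; variants per LD block.
#' @slot rho numeric in [0, 1); adjacent-variant haplotype correlation.
#' @slot mafRange numeric length 2; range of block allele frequencies.
#' @slot nCausal integer; causal cis variants per gene and tissue.
#' @slot sharedFrac numeric in [0, 1]; fraction of each non-exclusive gene's
#'   causal set shared (same variant, same effect) across tissues.
#' @slot eqtlH2 numeric in (0, 1); fraction of expression variance explained
#'   by cis genotype.
#' @slot cisWindow integer bp; cis window around the gene TSS.
#' @slot variantSpacing integer bp between adjacent variants.
#' @slot tissues character; tissue names, first entries arbitrary.
#' @slot focalTissue character; the tissue whose GReX mediates the trait.
#' @slot trueGenes data.frame with columns \code{gene_id}, \code{alpha},
#'   \code{exclusive}.
#' @slot traitNoiseSd numeric; SD of the non-genetic trait component.
#'   \code{NA_real_} means "choose so the trait has unit variance"
#'   (\code{sqrt(1 - sum(alpha^2))}).
#'
#' @seealso \code{\link{simScenario}}, \code{\link{simulateStudy}}
#' @export
setClass("SimScenario",
  representation(seed = "integer",
                 nPanel = "integer", nEqtl = "integer", nGwas = "integer",
                 nGenes = "integer", mPerGene = "integer",
                 blockSize = "integer", rho = "numeric",
                 mafRange = "numeric", nCausal = "integer",
                 sharedFrac = "numeric", eqtlH2 = "numeric",
                 cisWindow = "integer", variantSpacing = "integer",
                 tissues = "character", focalTissue = "character",
                 trueGenes = "data.frame", traitNoiseSd = "numeric"))

setValidity("SimScenario", function(object) {
  msg <- character()
  if (object@rho < 0 || object@rho >= 1)
    msg <- c(msg, "rho must lie in [0, 1)")
  if (object@eqtlH2 <= 0 || object@eqtlH2 >= 1)
    msg <- c(msg, "eqtlH2 must lie in (0, 1)")
  if (length(object@mafRange) != 2 || any(object@mafRange <= 0) ||
      any(object@mafRange > 0.5))
    msg <- c(msg, "mafRange must be two frequencies in (0, 0.5]")
  if (!(object@focalTissue %in% object@tissues))
    msg <- c(msg, "focalTissue must be one of tissues")
  if (anyDuplicated(object@tissues))
    msg <- c(msg, "tissue names must be unique")
  tg <- object@trueGenes
  if (nrow(tg)) {
    if (!all(c("gene_id", "alpha", "exclusive") %in% names(tg)))
      msg <- c(msg, "trueGenes needs columns gene_id, alpha, exclusive")
    else {
      ids <- sprintf("SIMG%04d", seq_len(object@nGenes))
      if (!all(tg$gene_id %in% ids))
        msg <- c(msg, "trueGenes references gene IDs outside the scenario")
    }
  }
  if (object@nCausal > object@mPerGene)
    msg <- c(msg, "nCausal cannot exceed mPerGene")
  if (object@nCausal * length(object@tissues) > object@mPerGene &&
      nrow(tg) && any(tg$exclusive))
    msg <- c(msg, paste0("exclusive genes need nCausal * n_tissues ",
                         "<= mPerGene (disjoint causal sets)"))
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## GroundTruth
## ---------------------------------------------------------------------------

#' Ground truth of a simulated study
#'
#' Records what the generator actually planted: per gene x tissue the causal
#' cis variants and their per-allele expression effects, per true gene its
#' trait effect \code{alpha} (per SD of focal-tissue GReX), and per variant
#' its expected marginal GWAS effect on the unit-variance trait.
#'
#' @slot eqtl data.frame: \code{tissue}, \code{gene_id}, \code{variant_id},
#'   \code{b} (expression SD per effect allele), \code{shared} (logical:
#'   effect shared across tissues).
#' @slot genes data.frame: \code{gene_id}, \code{alpha}, \code{exclusive}.
#' @slot gwasMarginal data.frame: \code{variant_id}, \code{true_beta}
#'   (expected per-allele marginal effect on the standardized trait).
#' @export
setClass("GroundTruth",
  representation(eqtl = "data.frame", genes = "data.frame",
                 gwasMarginal = "data.frame"))

## ---------------------------------------------------------------------------
## GeneModelSet
## ---------------------------------------------------------------------------

#' A set of genetically-predicted expression models for one tissue
#'
#' Each gene's model is a sparse set of cis variants with weights (the
#' retained marginal eQTL effect sizes, in SD of expression per effect
#' allele), the per-variant expression variance explained 2pq*beta^2, the
#' gene-level total, and the reference dosage covariance among the model
#' variants used by the association denominator.
#'
#' @slot tissue character scalar.
#' @slot weights data.frame: \code{gene_id}, \code{variant_id},
#'   \code{effect_allele}, \code{other_allele}, \code{weight}, \code{eaf},
#'   \code{var_explained}.
#' @slot genes data.frame: \code{gene_id}, \code{total_variance},
#'   \code{n_snps}.
#' @slot covariances data.frame: \code{gene_id}, \code{variant_id_1},
#'   \code{variant_id_2}, \code{covariance} (upper triangle incl. diagonal).
#' @seealso \code{\link{buildModels}}, \code{\link{writeModelFiles}}
#' @export
setClass("GeneModelSet",
  representation(tissue = "character", weights = "data.frame",
                 genes = "data.frame", covariances = "data.frame"))

setValidity("GeneModelSet", function(object) {
  msg <- character()
  w <- object@weights
  g <- object@genes
  cv <- object@covariances
  if (nrow(w)) {
    if (any(w$var_explained < 0))
      msg <- c(msg, "per-SNP variance explained must be >= 0")
    tot <- tapply(w$var_explained, w$gene_id, sum)
    if (!all(g$gene_id %in% names(tot)))
      msg <- c(msg, "gene table lists genes with no weights")
    else if (any(abs(g$total_variance - tot[g$gene_id]) > 1e-8))
      msg <- c(msg, "total_variance must equal the sum of per-SNP variances")
    ns <- tapply(w$variant_id, w$gene_id, length)
    if (any(g$n_snps != ns[g$gene_id]))
      msg <- c(msg, "n_snps must match the weight rows per gene")
  } else if (nrow(g)) {
    msg <- c(msg, "gene table non-empty but no weights")
  }
  if (nrow(cv)) {
    key <- paste(w$gene_id, w$variant_id)
    bad <- !(paste(cv$gene_id, cv$variant_id_1) %in% key) |
           !(paste(cv$gene_id, cv$variant_id_2) %in% key)
    if (any(bad))
      msg <- c(msg, "covariance entries reference variants absent from weights")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname GeneModelSet-class
#' @param tissue tissue label.
#' @param weights,genes,covariances see slots of
#'   \code{\linkS4class{GeneModelSet}}; \code{genes} is recomputed from
#'   \code{weights} when missing.
#' @return a \code{GeneModelSet}.
#' @export
GeneModelSet <- function(tissue, weights, genes = NULL, covariances = NULL) {
  if (is.null(genes)) {
    if (nrow(weights)) {
      tot <- tapply(weights$var_explained, weights$gene_id, sum)
      ns <- tapply(weights$variant_id, weights$gene_id, length)
      genes <- data.frame(gene_id = names(tot),
                          total_variance = as.numeric(tot),
                          n_snps = as.integer(ns[names(tot)]),
                          stringsAsFactors = FALSE)
      rownames(genes) <- NULL
    } else {
      genes <- data.frame(gene_id = character(), total_variance = numeric(),
                          n_snps = integer())
    }
  }
  if (is.null(covariances))
    covariances <- data.frame(gene_id = character(),
                              variant_id_1 = character(),
                              variant_id_2 = character(),
                              covariance = numeric())
  new("GeneModelSet", tissue = tissue, weights = weights, genes = genes,
      covariances = covariances)
}

## ---------------------------------------------------------------------------
## TissueResults
## ---------------------------------------------------------------------------

#' Gene-trait association results for one tissue
#'
#' One row per tested gene: the summary-statistic association z-score, the
#' effect size in trait units per SD of predicted expression, its standard
#' error, the two-sided p-value, the predicted-expression variance
#' \code{sigma_g2}, and the model/used variant counts.  Genes that could not
#' be tested are listed in the skip report with a reason.
#'
#' @slot tissue character scalar.
#' @slot results data.frame: \code{gene_id}, \code{tissue}, \code{zscore},
#'   \code{effect}, \code{se}, \code{pvalue}, \code{sigma_g2},
#'   \code{n_snps_model}, \code{n_snps_used}.
#' @slot skipped data.frame: \code{gene_id}, \code{reason}.
#' @seealso \code{\link{runAssociation}}, \code{\link{classifyResults}}
#' @export
setClass("TissueResults",
  representation(tissue = "character", results = "data.frame",
                 skipped = "data.frame"))

setValidity("TissueResults", function(object) {
  msg <- character()
  r <- object@results
  if (nrow(r)) {
    if (any(r$pvalue <= 0 | r$pvalue > 1))
      msg <- c(msg, "p-values must lie in (0, 1]")
    nz <- r$zscore != 0
    if (any(sign(r$effect[nz]) != sign(r$zscore[nz])))
      msg <- c(msg, "effect and zscore must agree in sign")
    if (any(r$n_snps_used > r$n_snps_model))
      msg <- c(msg, "n_snps_used cannot exceed n_snps_model")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## PhenotypeSummary
## ---------------------------------------------------------------------------

#' Study-wide multi-tissue significance summary for one phenotype
#'
#' Pools every gene x tissue association for a phenotype, applies the
#' study-wide Bonferroni threshold \code{alpha / n_tests_total}, and counts
#' suggestive (nominal p < alpha) and significant (p < threshold) results,
#' with a per-tissue breakdown.
#'
#' @slot phenotype character scalar.
#' @slot alpha numeric; nominal significance level (default 0.05).
#' @slot nTests integer; total gene x tissue tests.
#' @slot threshold numeric; \code{alpha / nTests}.
#' @slot results pooled data.frame of per-gene results plus logical columns
#'   \code{suggestive} and \code{significant}.
#' @slot perTissue data.frame: \code{tissue}, \code{n_tests},
#'   \code{n_suggestive}, \code{n_significant}.
#' @seealso \code{\link{classifyResults}}, \code{\link{findExclusive}}
#' @export
setClass("PhenotypeSummary",
  representation(phenotype = "character", alpha = "numeric",
                 nTests = "integer", threshold = "numeric",
                 results = "data.frame", perTissue = "data.frame"))

setValidity("PhenotypeSummary", function(object) {
  msg <- character()
  if (object@nTests != nrow(object@results))
    msg <- c(msg, "nTests must equal the number of pooled results")
  if (object@nTests >= 1 &&
      abs(object@threshold - object@alpha / object@nTests) > 0)
    msg <- c(msg, "threshold must equal alpha / nTests exactly")
  ns <- sum(object@results$significant)
  nsug <- sum(object@results$suggestive)
  if (ns > nsug)
    msg <- c(msg, "significant results must be a subset of suggestive ones")
  if (length(msg)) msg else TRUE
})
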