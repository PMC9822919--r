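#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("panelGenotypes", "LDPanel", function(object) object@genotypes)

#' @rdname accessors
#' @export
setMethod("variantInfo", "LDPanel", function(object) object@variants)

#' @rdname accessors
#' @export
setMethod("nVariants", "LDPanel", function(object) ncol(object@genotypes))

#' @rdname accessors
#' @export
setMethod("nIndividuals", "LDPanel", function(object) nrow(object@genotypes))

#' @rdname accessors
#' @export
setMethod("alleleFreqs", "LDPanel",
          function(object) colMeans(object@genotypes) / 2)

setMethod("show", "LDPanel", function(object) {
  cat("LDPanel:", nIndividuals(object), "individuals x",
      nVariants(object), "variants\n")
  cat("  chromosomes:", length(unique(object@variants$chrom)), "\n")
})

#' @rdname accessors
#' @export
setMethod("modelWeights", "GeneModelSet", function(object) object@weights)

#' @rdname accessors
#' @export
setMethod("modelGenes", "GeneModelSet", function(object) object@genes)

#' @rdname accessors
#' @export
setMethod("modelCovariances", "GeneModelSet",
          function(object) object@covariances)

#' @rdname accessors
#' @export
setMethod("tissueName", "GeneModelSet", function(object) object@tissue)

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet [", object@tissue, "]: ", nrow(object@genes),
      " genes, ", nrow(object@weights), " variant weights\n", sep = "")
  if (nrow(object@genes))
    cat("  total variance explained: ",
        sprintf("%.3g-%.3g", min(object@genes$total_variance),
                max(object@genes$total_variance)), "\n", sep = "")
})

#' @rdname filterGeneVariance
#' @export
setMethod("filterGeneVariance", "GeneModelSet",
  function(object, lower = 0.01, upper = 2.0) {
    keep <- !(object@genes$total_variance > upper |
              object@genes$total_variance < lower)
    genes <- object@genes[keep, , drop = FALSE]
    w <- object@weights[object@weights$gene_id %in% genes$gene_id, ,
                        drop = FALSE]
    cv <- object@covariances[object@covariances$gene_id %in% genes$gene_id, ,
                             drop = FALSE]
    rownames(genes) <- rownames(w) <- rownames(cv) <- NULL
    new("GeneModelSet", tissue = object@tissue, weights = w, genes = genes,
        covariances = cv)
  })

#' @rdname accessors
#' @export
setMethod("tissueName", "TissueResults", function(object) object@tissue)

#' @rdname accessors
#' @export
setMethod("assocResults", "TissueResults", function(object) object@results)

#' @rdname accessors
#' @export
setMethod("skipReport", "TissueResults", function(object) object@skipped)

#' @rdname accessors
#' @export
setMethod("nTests", "TissueResults", function(object) nrow(object@results))

setMethod("show", "TissueResults", function(object) {
  cat("TissueResults [", object@tissue, "]: ", nrow(object@results),
      " genes tested, ", nrow(object@skipped), " skipped\n", sep = "")
})

#' @rdname accessors
#' @export
setMethod("nTests", "PhenotypeSummary", function(object) object@nTests)

#' @rdname accessors
#' @export
setMethod("significanceThreshold", "PhenotypeSummary",
          function(object) object@threshold)

#' @rdname accessors
#' @export
setMethod("pooledResults", "PhenotypeSummary", function(object) object@results)

#' @rdname accessors
#' @export
setMethod("perTissueCounts", "PhenotypeSummary",
          function(object) object@perTissue)

setMethod("show", "PhenotypeSummary", function(object) {
  ns <- sum(object@results$significant)
  nsug <- sum(object@results$suggestive)
  cat("PhenotypeSummary [", object@phenotype, "]\n", sep = "")
  cat("  tests: ", object@nTests, " across ",
      nrow(object@perTissue), " tissue(s)\n", sep = "")
  cat("  Bonferroni threshold: ", format(object@threshold, digits = 5),
      "\n", sep = "")
  cat("  suggestive (p < ", object@alpha, "): ", nsug,
      sprintf(" (%.2f%%)", 100 * nsug / max(object@nTests, 1)), "\n",
      sep = "")
  cat("  significant: ", ns,
      sprintf(" (%.2f%%)", 100 * ns / max(object@nTests, 1)), "\n", sep = "")
})

#' @rdname accessors
#' @export
setMethod("truthEqtls", "GroundTruth", function(object) object@eqtl)

#' @rdname accessors
#' @export
setMethod("truthGenes", "GroundTruth", function(object) object@genes)

#' @rdname accessors
#' @export
setMethod("truthGwasEffects", "GroundTruth",
          function(object) object@gwasMarginal)

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@genes), "trait gene(s),",
      nrow(object@eqtl), "causal eQTL effects\n")
})

setMethod("show", "SimScenario", function(object) {
  cat("SimScenario (seed ", object@seed, ")\n", sep = "")
  cat("  cohorts: panel ", object@nPanel, ", eQTL ", object@nEqtl,
      ", GWAS ", object@nGwas, "\n", sep = "")
  cat("  genome: ", object@nGenes, " genes x ", object@mPerGene,
      " variants; blocks of ", object@blockSize, ", rho ", object@rho,
      "\n", sep = "")
  cat("  eQTL: ", object@nCausal, " causal/gene, h2 ", object@eqtlH2,
      ", ", length(object@tissues), " tissues (focal ", object@focalTissue,
      ")\n", sep = "")
  cat("  true genes: ", nrow(object@trueGenes), " (",
      sum(object@trueGenes$exclusive), " focal-exclusive)\n", sep = "")
})
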