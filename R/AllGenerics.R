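#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' @param object an object of one of the package's classes.
#' @return the corresponding slot content; \code{alleleFreqs} returns the
#'   in-sample effect-allele frequencies (mean dosage / 2).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("panelGenotypes", function(object) standardGeneric("panelGenotypes"))

#' @rdname accessors
#' @export
setGeneric("variantInfo", function(object) standardGeneric("variantInfo"))

#' @rdname accessors
#' @export
setGeneric("nVariants", function(object) standardGeneric("nVariants"))

#' @rdname accessors
#' @export
setGeneric("nIndividuals", function(object) standardGeneric("nIndividuals"))

#' @rdname accessors
#' @export
setGeneric("alleleFreqs", function(object) standardGeneric("alleleFreqs"))

#' @rdname accessors
#' @export
setGeneric("modelWeights", function(object) standardGeneric("modelWeights"))

#' @rdname accessors
#' @export
setGeneric("modelGenes", function(object) standardGeneric("modelGenes"))

#' @rdname accessors
#' @export
setGeneric("modelCovariances",
           function(object) standardGeneric("modelCovariances"))

#' @rdname accessors
#' @export
setGeneric("tissueName", function(object) standardGeneric("tissueName"))

#' @rdname accessors
#' @export
setGeneric("assocResults", function(object) standardGeneric("assocResults"))

#' @rdname accessors
#' @export
setGeneric("skipReport", function(object) standardGeneric("skipReport"))

#' @rdname accessors
#' @export
setGeneric("nTests", function(object) standardGeneric("nTests"))

#' @rdname accessors
#' @export
setGeneric("significanceThreshold",
           function(object) standardGeneric("significanceThreshold"))

#' @rdname accessors
#' @export
setGeneric("pooledResults", function(object) standardGeneric("pooledResults"))

#' @rdname accessors
#' @export
setGeneric("perTissueCounts",
           function(object) standardGeneric("perTissueCounts"))

#' @rdname accessors
#' @export
setGeneric("truthEqtls", function(object) standardGeneric("truthEqtls"))

#' @rdname accessors
#' @export
setGeneric("truthGenes", function(object) standardGeneric("truthGenes"))

#' @rdname accessors
#' @export
setGeneric("truthGwasEffects",
           function(object) standardGeneric("truthGwasEffects"))

#' Gene-level variance-explained filter
#'
#' @param object a \code{\linkS4class{GeneModelSet}}.
#' @param lower,upper retention bounds on the gene's total expression
#'   variance explained; genes are kept iff
#'   \code{lower <= total_variance <= upper} (exclusion is strict, so
#'   boundary values survive).
#' @return the filtered \code{GeneModelSet}.
#' @export
setGeneric("filterGeneVariance",
           function(object, lower = 0.01, upper = 2.0)
             standardGeneric("filterGeneVariance"))
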