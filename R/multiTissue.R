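#' @include AllClasses.R
NULL

#' Bonferroni significance threshold
#'
#' @param nTests number of tests (>= 1).
#' @param alpha family-wise error rate (default 0.05).
#' @return \code{alpha / nTests}.
#' @examples
#' bonferroniThreshold(263683)
#' @export
bonferroniThreshold <- function(nTests, alpha = 0.05) {
  if (length(nTests) != 1 || is.na(nTests) || nTests < 1)
    stop("nTests must be a single count >= 1")
  alpha / nTests
}

#' Pool per-tissue results and apply study-wide Bonferroni correction
#'
#' Pools all gene x tissue associations for one phenotype, counts
#' suggestive results (nominal p < alpha) and significant ones
#' (p < alpha / total tests; comparisons are strict), and attaches a
#' per-tissue breakdown.
#'
#' @param resultSets a \code{\linkS4class{TissueResults}} or a list of
#'   them (one per tissue).
#' @param phenotype phenotype label.
#' @param alpha nominal significance level (default 0.05).
#' @return a \code{\linkS4class{PhenotypeSummary}}.
#' @export
classifyResults <- function(resultSets, phenotype = "trait", alpha = 0.05) {
  if (is(resultSets, "TissueResults")) resultSets <- list(resultSets)
  pooled <- do.call(rbind, lapply(resultSets, assocResults))
  rownames(pooled) <- NULL
  if (is.null(pooled) || !nrow(pooled))
    stop("no results to classify")
  key <- paste(pooled$gene_id, pooled$tissue)
  if (anyDuplicated(key))
    stop("duplicate (gene, tissue) result(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  n <- nrow(pooled)
  thr <- bonferroniThreshold(n, alpha)
  pooled$suggestive <- pooled$pvalue < alpha
  pooled$significant <- pooled$pvalue < thr
  per <- do.call(rbind, lapply(split(pooled, pooled$tissue), function(d) {
    data.frame(tissue = d$tissue[1], n_tests = nrow(d),
               n_suggestive = sum(d$suggestive),
               n_significant = sum(d$significant),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  new("PhenotypeSummary", phenotype = phenotype, alpha = alpha,
      nTests = n, threshold = thr, results = pooled, perTissue = per)
}

#' Classify focal-tissue-exclusive genes
#'
#' For every gene Bonferroni-significant in the focal tissue, reports
#' whether it is significant in any other tissue where it was tested; a
#' gene is exclusive iff it is not.  \code{tested_in_n_tissues} records how
#' many tissues carried a model for the gene, so "significant only in the
#' focal tissue but untestable elsewhere" cases remain distinguishable
#' from "tested elsewhere and null".
#'
#' @param summary a \code{\linkS4class{PhenotypeSummary}}.
#' @param focalTissue focal tissue name (must appear in the results).
#' @return data.frame with columns \code{gene_id}, \code{focal_tissue},
#'   \code{significant_in_focal}, \code{other_tissues_significant}
#'   (comma-separated, "" when none), \code{exclusive},
#'   \code{tested_in_n_tissues}, plus the focal-tissue \code{effect},
#'   \code{se}, \code{pvalue} and \code{zscore}.
#' @export
findExclusive <- function(summary, focalTissue) {
  res <- pooledResults(summary)
  if (!focalTissue %in% res$tissue)
    stop("focal tissue '", focalTissue, "' absent from results")
  focal <- res[res$tissue == focalTissue & res$significant, , drop = FALSE]
  if (!nrow(focal))
    return(data.frame(gene_id = character(), focal_tissue = character(),
                      significant_in_focal = logical(),
                      other_tissues_significant = character(),
                      exclusive = logical(),
                      tested_in_n_tissues = integer(),
                      effect = numeric(), se = numeric(),
                      pvalue = numeric(), zscore = numeric(),
                      stringsAsFactors = FALSE))
  out <- lapply(seq_len(nrow(focal)), function(i) {
    g <- focal$gene_id[i]
    other <- res[res$gene_id == g & res$tissue != focalTissue, ,
                 drop = FALSE]
    sigOther <- other$tissue[other$significant]
    data.frame(gene_id = g, focal_tissue = focalTissue,
               significant_in_focal = TRUE,
               other_tissues_significant = paste(sigOther, collapse = ","),
               exclusive = length(sigOther) == 0,
               tested_in_n_tissues = 1L + nrow(other),
               effect = focal$effect[i], se = focal$se[i],
               pvalue = focal$pvalue[i], zscore = focal$zscore[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$pvalue), , drop = FALSE]
}

#' Genes exclusively significant in the focal tissue for two phenotypes
#'
#' Intersects the focal-tissue-exclusive gene sets of two phenotype
#' summaries and reports each shared gene with its per-phenotype effect
#' direction.
#'
#' @param summaryA,summaryB \code{\linkS4class{PhenotypeSummary}} objects.
#' @param focalTissue focal tissue name.
#' @return data.frame with columns \code{gene_id}, \code{effect_a},
#'   \code{pvalue_a}, \code{effect_b}, \code{pvalue_b},
#'   \code{direction_consistent}.
#' @export
overlapPhenotypes <- function(summaryA, summaryB, focalTissue) {
  exA <- findExclusive(summaryA, focalTissue)
  exB <- findExclusive(summaryB, focalTissue)
  exA <- exA[exA$exclusive, , drop = FALSE]
  exB <- exB[exB$exclusive, , drop = FALSE]
  shared <- intersect(exA$gene_id, exB$gene_id)
  a <- exA[match(shared, exA$gene_id), , drop = FALSE]
  b <- exB[match(shared, exB$gene_id), , drop = FALSE]
  data.frame(gene_id = shared,
             effect_a = a$effect, pvalue_a = a$pvalue,
             effect_b = b$effect, pvalue_b = b$pvalue,
             direction_consistent = sign(a$effect) == sign(b$effect),
             stringsAsFactors = FALSE)
}
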