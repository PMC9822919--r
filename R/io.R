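#' @include AllClasses.R utils.R
NULL

.gwasRequired <- c("variant_id", "chrom", "pos", "effect_allele",
                   "other_allele", "eaf", "beta", "se", "pvalue")

applyColumnMap <- function(df, columnMap) {
  if (is.null(columnMap)) return(df)
  for (canon in names(columnMap)) {
    src <- columnMap[[canon]]
    if (!src %in% names(df))
      stop("mapped column '", src, "' (for ", canon, ") not found")
    names(df)[names(df) == src] <- canon
  }
  df
}

## Coerce numeric columns, flag rows violating the summary-record
## invariants; returns list(df, n_skipped).
cleanSumstatRows <- function(df, numericCols, what) {
  for (col in numericCols)
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  bad <- rep(FALSE, nrow(df))
  for (col in intersect(c("beta", "se", "eaf"), numericCols))
    bad <- bad | is.na(df[[col]])
  if ("se" %in% numericCols) bad <- bad | (!is.na(df$se) & df$se <= 0)
  if ("eaf" %in% numericCols)
    bad <- bad | (!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1))
  if ("pvalue" %in% numericCols)
    bad <- bad | is.na(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1
  n_skipped <- sum(bad)
  if (n_skipped)
    message(what, ": skipped ", n_skipped, " malformed row(s)")
  df <- df[!bad, , drop = FALSE]
  rownames(df) <- NULL
  list(df = df, n_skipped = n_skipped)
}

#' Read GWAS summary statistics
#'
#' Reads a tab-separated GWAS summary-statistics file with columns
#' \code{variant_id, chrom, pos, effect_allele, other_allele, eaf, beta,
#' se, pvalue} and optionally \code{z} and \code{n}.  Rows violating the
#' record invariants (non-numeric beta/se, se <= 0, eaf outside [0,1],
#' p outside (0,1]) are skipped and counted; the z-score is computed as
#' beta/se when absent.
#'
#' @param path file path.
#' @param columnMap optional named character vector mapping canonical column
#'   names to the file's column names, e.g. \code{c(variant_id = "SNP")}.
#' @return data.frame of variant records; the number of skipped rows is
#'   attached as \code{attr(, "n_skipped")}.
#' @export
readGwasSumstats <- function(path, columnMap = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- applyColumnMap(readTsv(path), columnMap)
  miss <- setdiff(.gwasRequired, names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  num <- intersect(c("pos", "eaf", "beta", "se", "pvalue", "z", "n"),
                   names(df))
  cl <- cleanSumstatRows(df, num, "GWAS sumstats")
  df <- cl$df
  if (!"z" %in% names(df)) df$z <- df$beta / df$se
  df$z[is.na(df$z)] <- df$beta[is.na(df$z)] / df$se[is.na(df$z)]
  df$chrom <- as.character(df$chrom)
  attr(df, "n_skipped") <- cl$n_skipped
  df
}

#' Read cis-eQTL summary statistics
#'
#' As \code{\link{readGwasSumstats}} plus a mandatory \code{gene_id} column.
#' Gene ID versions (\code{ENSG0001.5}) are stripped; duplicate
#' (gene, variant) pairs are an error.
#'
#' @inheritParams readGwasSumstats
#' @return data.frame of eQTL records keyed by (gene_id, variant_id), with
#'   \code{attr(, "n_skipped")}.
#' @export
readEqtlSumstats <- function(path, columnMap = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- applyColumnMap(readTsv(path), columnMap)
  req <- c("gene_id", setdiff(.gwasRequired, c("chrom", "pos")))
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  num <- intersect(c("pos", "eaf", "beta", "se", "pvalue"), names(df))
  cl <- cleanSumstatRows(df, num, "eQTL sumstats")
  df <- cl$df
  df$gene_id <- stripGeneVersion(df$gene_id)
  key <- paste(df$gene_id, df$variant_id)
  if (anyDuplicated(key))
    stop("duplicate (gene, variant) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  attr(df, "n_skipped") <- cl$n_skipped
  df
}

#' Harmonize GWAS, model and panel alleles
#'
#' Aligns the three sources to the model's effect allele, keyed by
#' \code{variant_id}.  GWAS rows whose alleles are swapped relative to the
#' model have beta and z sign-flipped and eaf replaced by 1 - eaf; panel
#' variants in swapped orientation have dosages recoded to 2 - dosage.
#' Strand-ambiguous palindromic variants (A/T, C/G) are dropped when
#' \code{dropAmbiguous} is set (default), since summary files carry no
#' strand information.  Variants absent from any source, or whose allele
#' pair matches neither orientation, are dropped and counted.
#'
#' Harmonizing an already-harmonized triple is a no-op.
#'
#' @param gwas GWAS summary data.frame (as from
#'   \code{\link{readGwasSumstats}}).
#' @param modelSnps data.frame with \code{variant_id}, \code{effect_allele},
#'   \code{other_allele} — typically the weights of a
#'   \code{\linkS4class{GeneModelSet}}.
#' @param panel an \code{\linkS4class{LDPanel}}, or \code{NULL} to align
#'   GWAS and model only.
#' @param dropAmbiguous drop palindromic variants (default \code{TRUE}).
#' @return list with elements \code{gwas}, \code{modelSnps}, \code{panel}
#'   (aligned to the same variants and effect alleles) and \code{log}, a
#'   data.frame of drop reasons and counts whose total plus retained equals
#'   the number of distinct model variants.
#' @export
harmonizeSumstats <- function(gwas, modelSnps, panel = NULL,
                              dropAmbiguous = TRUE) {
  ref <- unique(modelSnps[c("variant_id", "effect_allele", "other_allele")])
  counts <- c(retained = 0L, ambiguous = 0L, mismatched = 0L,
              missing_gwas = 0L, missing_panel = 0L)

  inGwas <- ref$variant_id %in% gwas$variant_id
  counts["missing_gwas"] <- sum(!inGwas)
  ref <- ref[inGwas, , drop = FALSE]
  if (!is.null(panel)) {
    pv <- variantInfo(panel)
    inPanel <- ref$variant_id %in% pv$variant_id
    counts["missing_panel"] <- sum(!inPanel)
    ref <- ref[inPanel, , drop = FALSE]
  }
  if (dropAmbiguous) {
    amb <- isPalindromic(ref$effect_allele, ref$other_allele)
    counts["ambiguous"] <- sum(amb)
    ref <- ref[!amb, , drop = FALSE]
  }

  gw <- gwas[match(ref$variant_id, gwas$variant_id), , drop = FALSE]
  ori <- alleleOrientation(gw$effect_allele, gw$other_allele,
                           ref$effect_allele, ref$other_allele)
  if (!is.null(panel)) {
    pv <- variantInfo(panel)
    pidx <- match(ref$variant_id, pv$variant_id)
    pori <- alleleOrientation(pv$effect_allele[pidx], pv$other_allele[pidx],
                              ref$effect_allele, ref$other_allele)
    bad <- ori == "mismatch" | pori == "mismatch"
  } else {
    pori <- NULL
    bad <- ori == "mismatch"
  }
  counts["mismatched"] <- sum(bad)
  keep <- !bad
  ref <- ref[keep, , drop = FALSE]
  gw <- gw[keep, , drop = FALSE]
  ori <- ori[keep]
  counts["retained"] <- nrow(ref)

  sw <- ori == "swapped"
  if (any(sw)) {
    gw$beta[sw] <- -gw$beta[sw]
    if ("z" %in% names(gw)) gw$z[sw] <- -gw$z[sw]
    gw$eaf[sw] <- 1 - gw$eaf[sw]
    tmp <- gw$effect_allele[sw]
    gw$effect_allele[sw] <- gw$other_allele[sw]
    gw$other_allele[sw] <- tmp
  }
  rownames(gw) <- NULL

  outPanel <- NULL
  if (!is.null(panel)) {
    pv <- variantInfo(panel)
    pidx <- match(ref$variant_id, pv$variant_id)
    pori <- pori[keep]
    G <- panelGenotypes(panel)[, pidx, drop = FALSE]
    pvv <- pv[pidx, , drop = FALSE]
    psw <- pori == "swapped"
    if (any(psw)) {
      G[, psw] <- 2 - G[, psw]
      pvv$freq[psw] <- 1 - pvv$freq[psw]
      tmp <- pvv$effect_allele[psw]
      pvv$effect_allele[psw] <- pvv$other_allele[psw]
      pvv$other_allele[psw] <- tmp
    }
    rownames(pvv) <- NULL
    outPanel <- LDPanel(G, pvv)
  }

  model <- modelSnps[modelSnps$variant_id %in% ref$variant_id, ,
                     drop = FALSE]
  rownames(model) <- NULL
  list(gwas = gw, modelSnps = model, panel = outPanel,
       log = data.frame(reason = names(counts),
                        count = as.integer(counts),
                        stringsAsFactors = FALSE))
}

#' Write / read prediction model files
#'
#' Models are distributed as two TSVs: a weights file (\code{gene_id,
#' variant_id, effect_allele, other_allele, weight, eaf, var_explained})
#' and a covariance file (\code{gene_id, variant_id_1, variant_id_2,
#' covariance}).  Numeric columns are stored at full double precision, so
#' \code{readModelFiles(writeModelFiles(x))} reproduces the models exactly.
#'
#' @param models a \code{\linkS4class{GeneModelSet}}.
#' @param weightsPath,covariancePath file paths.
#' @return \code{writeModelFiles} returns the paths invisibly;
#'   \code{readModelFiles} returns a \code{GeneModelSet}.
#' @export
writeModelFiles <- function(models, weightsPath, covariancePath) {
  writeTsv(modelWeights(models)[c("gene_id", "variant_id", "effect_allele",
                                  "other_allele", "weight", "eaf",
                                  "var_explained")], weightsPath)
  writeTsv(modelCovariances(models), covariancePath)
  invisible(c(weightsPath, covariancePath))
}

#' @rdname writeModelFiles
#' @param tissue tissue label for the reconstructed model set.
#' @export
readModelFiles <- function(weightsPath, covariancePath,
                           tissue = "tissue") {
  w <- readTsv(weightsPath)
  cv <- readTsv(covariancePath)
  for (col in c("weight", "eaf", "var_explained"))
    w[[col]] <- as.numeric(w[[col]])
  if (nrow(cv)) cv$covariance <- as.numeric(cv$covariance)
  if (nrow(cv)) {
    key <- paste(w$gene_id, w$variant_id)
    bad <- !(paste(cv$gene_id, cv$variant_id_1) %in% key) |
           !(paste(cv$gene_id, cv$variant_id_2) %in% key)
    if (any(bad))
      stop("covariance entries reference variant(s) absent from weights: ",
           paste(unique(c(cv$variant_id_1[bad], cv$variant_id_2[bad])),
                 collapse = ", "))
  }
  GeneModelSet(tissue = tissue, weights = w, covariances = cv)
}

#' Write / read an LD panel as TSV
#'
#' The panel is stored as a variant metadata TSV plus a genotype dosage TSV
#' (individuals in rows, variant IDs as column names).
#'
#' @param panel an \code{\linkS4class{LDPanel}}.
#' @param variantsPath,genotypesPath file paths.
#' @return \code{writeLDPanel} returns the paths invisibly;
#'   \code{readLDPanel} returns an \code{LDPanel}.
#' @export
writeLDPanel <- function(panel, variantsPath, genotypesPath) {
  writeTsv(variantInfo(panel), variantsPath)
  utils::write.table(panelGenotypes(panel), genotypesPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(variantsPath, genotypesPath))
}

#' @rdname writeLDPanel
#' @export
readLDPanel <- function(variantsPath, genotypesPath) {
  v <- readTsv(variantsPath)
  v$freq <- as.numeric(v$freq)
  v$chrom <- as.character(v$chrom)
  G <- as.matrix(utils::read.delim(genotypesPath, sep = "\t",
                                   check.names = FALSE))
  LDPanel(G, v)
}
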