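#' @include AllClasses.R utils.R
NULL

#' Define a simulation scenario
#'
#' Constructs a validated \code{\linkS4class{SimScenario}}.  The defaults
#' describe the package's reference study: a modest external LD panel, an
#' eQTL cohort of 150 RNA-seq samples (the size of the placental eQTL study
#' the pipeline is designed around), a GWAS cohort of 10,000, 100
#' cis-regulated genes with 30 cis variants each in LD blocks of 10 at
#' adjacent-haplotype correlation 0.7, two causal cis variants per gene
#' explaining 20\% of expression variance, five tissues of which the first
#' ("placenta") is focal, and five trait genes — three with focal-exclusive
#' causal eQTL architecture and two whose causal eQTLs are shared across
#' tissues.
#'
#' @param seed integer seed; every generated dataset is a deterministic
#'   function of the scenario including this seed.
#' @param nPanel,nEqtl,nGwas cohort sizes.
#' @param nGenes,mPerGene genome layout (genes x cis variants per gene).
#' @param blockSize,rho,mafRange LD model: variants per haplotype block,
#'   adjacent-variant haplotype correlation, block allele-frequency range.
#' @param nCausal causal cis variants per gene and tissue (0 gives purely
#'   noise-driven expression).
#' @param sharedFrac fraction of each non-exclusive gene's causal set shared
#'   across tissues.
#' @param eqtlH2 cis heritability of expression.
#' @param cisWindow,variantSpacing cis window half-width and inter-variant
#'   spacing, bp.
#' @param tissues,focalTissue tissue names and the focal (trait-mediating)
#'   tissue.
#' @param trueGenes data.frame(gene_id, alpha, exclusive) of trait genes;
#'   \code{alpha} is the trait effect per SD of focal-tissue GReX.
#' @param traitNoiseSd non-genetic trait SD; \code{NA} selects
#'   \code{sqrt(1 - sum(alpha^2))} so the trait has unit variance.
#' @return a \code{SimScenario}.
#' @examples
#' sc <- simScenario(seed = 1, nGenes = 10, nGwas = 1000)
#' sc
#' @export
simScenario <- function(seed = 1L,
                        nPanel = 500L, nEqtl = 150L, nGwas = 10000L,
                        nGenes = 100L, mPerGene = 30L,
                        blockSize = 10L, rho = 0.7,
                        mafRange = c(0.05, 0.5),
                        nCausal = 2L, sharedFrac = 0.5, eqtlH2 = 0.2,
                        cisWindow = 250000L, variantSpacing = 5000L,
                        tissues = c("placenta", paste0("tissue", 1:4)),
                        focalTissue = "placenta",
                        trueGenes = NULL,
                        traitNoiseSd = NA_real_) {
  if (is.null(trueGenes)) {
    trueGenes <- data.frame(
      gene_id = sprintf("SIMG%04d", seq_len(min(5L, nGenes))),
      alpha = c(0.3, 0.25, 0.2, 0.3, 0.2)[seq_len(min(5L, nGenes))],
      exclusive = c(TRUE, TRUE, TRUE, FALSE, FALSE)[seq_len(min(5L, nGenes))],
      stringsAsFactors = FALSE)
  }
  new("SimScenario", seed = as.integer(seed),
      nPanel = as.integer(nPanel), nEqtl = as.integer(nEqtl),
      nGwas = as.integer(nGwas), nGenes = as.integer(nGenes),
      mPerGene = as.integer(mPerGene), blockSize = as.integer(blockSize),
      rho = rho, mafRange = mafRange, nCausal = as.integer(nCausal),
      sharedFrac = sharedFrac, eqtlH2 = eqtlH2,
      cisWindow = as.integer(cisWindow),
      variantSpacing = as.integer(variantSpacing),
      tissues = tissues, focalTissue = focalTissue,
      trueGenes = trueGenes, traitNoiseSd = traitNoiseSd)
}

subSeed <- function(scenario, k) scenario@seed + 1009L * as.integer(k)

## Non-palindromic allele pairs cycled across variants.
.allelePairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                         "G", "A", "C", "A", "G", "T", "C", "T"),
                       ncol = 2, byrow = TRUE)

## Deterministic genome layout + seeded block frequencies and causal
## architecture.  Everything downstream re-derives this from the scenario.
scenarioSetup <- function(scenario) {
  ng <- scenario@nGenes
  m <- scenario@mPerGene
  geneIds <- sprintf("SIMG%04d", seq_len(ng))
  geneOf <- rep(geneIds, each = m)
  within <- rep(seq_len(m), times = ng)
  pos <- within * scenario@variantSpacing
  tss <- as.integer(round((m + 1) / 2) * scenario@variantSpacing)
  blockWithin <- (within - 1L) %/% scenario@blockSize
  block <- paste0(geneOf, "_b", blockWithin)
  ap <- .allelePairs[((seq_len(ng * m) - 1L) %% nrow(.allelePairs)) + 1L, ,
                     drop = FALSE]
  variants <- data.frame(
    variant_id = sprintf("%s_v%03d", geneOf, within),
    chrom = as.character(match(geneOf, geneIds)),
    pos = pos, gene_id = geneOf, block = block,
    effect_allele = ap[, 1], other_allele = ap[, 2],
    stringsAsFactors = FALSE)
  withSeed(subSeed(scenario, 0L), {
    blocks <- unique(block)
    bf <- stats::runif(length(blocks), scenario@mafRange[1],
                       scenario@mafRange[2])
    variants$freq <- bf[match(block, blocks)]
    arch <- drawArchitecture(scenario, variants, geneIds)
  })
  genes <- data.frame(gene_id = geneIds,
                      chrom = as.character(seq_len(ng)),
                      tss = tss, stringsAsFactors = FALSE)
  list(variants = variants, genes = genes, arch = arch)
}

## Causal sets and effect sizes per gene x tissue.  Exclusive trait genes get
## disjoint causal sets across tissues; other genes share a fraction of their
## causal set (same variant, same effect) with tissue-specific remainders.
drawArchitecture <- function(scenario, variants, geneIds) {
  tiss <- scenario@tissues
  nc <- scenario@nCausal
  out <- vector("list", length(geneIds))
  excl <- scenario@trueGenes$gene_id[scenario@trueGenes$exclusive]
  for (gi in seq_along(geneIds)) {
    g <- geneIds[gi]
    vid <- variants$variant_id[variants$gene_id == g]
    if (nc == 0L) { out[[gi]] <- NULL; next }
    rows <- list()
    if (g %in% excl) {
      pool <- vid
      for (t in tiss) {
        pick <- sample(pool, nc)
        pool <- setdiff(pool, pick)
        rows[[t]] <- data.frame(tissue = t, gene_id = g, variant_id = pick,
                                b = stats::rnorm(nc), shared = FALSE,
                                stringsAsFactors = FALSE)
      }
    } else {
      nShared <- round(scenario@sharedFrac * nc)
      sharedSet <- if (nShared > 0) sample(vid, nShared) else character()
      bShared <- stats::rnorm(length(sharedSet))
      pool <- setdiff(vid, sharedSet)
      nSpec <- nc - nShared
      for (t in tiss) {
        if (nSpec > 0) {
          if (length(pool) < nSpec) pool <- setdiff(vid, sharedSet)
          pick <- sample(pool, nSpec)
          pool <- setdiff(pool, pick)
        } else pick <- character()
        rows[[t]] <- data.frame(
          tissue = t, gene_id = g,
          variant_id = c(sharedSet, pick),
          b = c(bShared, stats::rnorm(length(pick))),
          shared = c(rep(TRUE, length(sharedSet)), rep(FALSE, length(pick))),
          stringsAsFactors = FALSE)
      }
    }
    out[[gi]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(tissue = character(), gene_id = character(),
                      variant_id = character(), b = numeric(),
                      shared = logical())
  rownames(res) <- NULL
  res
}

## Haplotype-copy genotype draw: within a block the first variant is
## Bernoulli(f); each later variant copies its left neighbour with
## probability rho, else redraws Bernoulli(f).  Allele correlation between
## variants d apart is exactly rho^d; blocks are independent.
drawGenotypes <- function(variants, n, rho) {
  m <- nrow(variants)
  H <- matrix(0L, nrow = 2L * n, ncol = m)
  blocks <- unique(variants$block)
  for (b in blocks) {
    idx <- which(variants$block == b)
    f <- variants$freq[idx[1]]
    H[, idx[1]] <- stats::rbinom(2L * n, 1L, f)
    for (j in seq_along(idx)[-1]) {
      copy <- stats::rbinom(2L * n, 1L, rho)
      fresh <- stats::rbinom(2L * n, 1L, f)
      H[, idx[j]] <- copy * H[, idx[j - 1L]] + (1L - copy) * fresh
    }
  }
  G <- H[seq_len(n), , drop = FALSE] + H[n + seq_len(n), , drop = FALSE]
  colnames(G) <- variants$variant_id
  G
}

## Population dosage covariance among a gene's variants under the haplotype
## model: 2 f (1-f) rho^|i-j| within a block, 0 across blocks.
theoreticalDosageCov <- function(variants, rho) {
  m <- nrow(variants)
  S <- matrix(0, m, m, dimnames = list(variants$variant_id,
                                       variants$variant_id))
  for (b in unique(variants$block)) {
    idx <- which(variants$block == b)
    f <- variants$freq[idx[1]]
    d <- abs(outer(seq_along(idx), seq_along(idx), "-"))
    S[idx, idx] <- 2 * f * (1 - f) * rho^d
  }
  S
}

#' Simulate a reference genotype panel
#'
#' Draws \code{nPanel} individuals from the scenario's blocked-LD haplotype
#' model.  The panel plays the role of the external LD reference used for
#' clumping and for the association denominator; it is an independent draw
#' from the same population as the eQTL and GWAS cohorts.
#'
#' @param scenario a \code{\linkS4class{SimScenario}}.
#' @return an \code{\linkS4class{LDPanel}}.
#' @examples
#' panel <- simulatePanel(simScenario(seed = 1, nGenes = 2, nPanel = 100))
#' panel
#' @export
simulatePanel <- function(scenario) {
  stopifnot(is(scenario, "SimScenario"))
  setup <- scenarioSetup(scenario)
  G <- withSeed(subSeed(scenario, 1L),
                drawGenotypes(setup$variants, scenario@nPanel, scenario@rho))
  v <- setup$variants[c("variant_id", "chrom", "pos", "effect_allele",
                        "other_allele", "freq")]
  LDPanel(G, v)
}

#' Ground truth of a scenario
#'
#' Returns the planted causal eQTL effects per gene and tissue, the trait
#' gene effects, and the expected per-variant marginal GWAS effect on the
#' unit-variance trait (computed from the scenario's population LD, not from
#' any realised cohort).
#'
#' @param scenario a \code{\linkS4class{SimScenario}}.
#' @return a \code{\linkS4class{GroundTruth}}.
#' @export
simulateTruth <- function(scenario) {
  stopifnot(is(scenario, "SimScenario"))
  setup <- scenarioSetup(scenario)
  arch <- setup$arch
  tg <- scenario@trueGenes
  v <- setup$variants
  trueBeta <- stats::setNames(numeric(nrow(v)), v$variant_id)
  if (nrow(tg)) {
    for (i in seq_len(nrow(tg))) {
      g <- tg$gene_id[i]
      ca <- arch[arch$gene_id == g & arch$tissue == scenario@focalTissue, ,
                 drop = FALSE]
      if (!nrow(ca)) next
      gv <- v[v$gene_id == g, , drop = FALSE]
      S <- theoreticalDosageCov(gv, scenario@rho)
      b <- stats::setNames(numeric(nrow(gv)), gv$variant_id)
      b[ca$variant_id] <- ca$b
      covGrex <- as.vector(S %*% b)          # cov(dosage_v, GReX)
      sdGrex <- sqrt(as.numeric(t(b) %*% S %*% b))
      varV <- diag(S)
      trueBeta[gv$variant_id] <- trueBeta[gv$variant_id] +
        tg$alpha[i] * covGrex / (sdGrex * varV)
    }
  }
  new("GroundTruth", eqtl = arch,
      genes = tg,
      gwasMarginal = data.frame(variant_id = v$variant_id,
                                true_beta = as.numeric(trueBeta),
                                stringsAsFactors = FALSE))
}

#' Simulate cis-eQTL summary statistics for one tissue
#'
#' Draws a fresh eQTL cohort, builds each gene's expression as the causal
#' dosage score plus Gaussian noise scaled so the cis-genotype fraction of
#' expression variance equals \code{eqtlH2} (in the population), and returns
#' per-variant marginal simple-regression summary statistics for every
#' variant in the gene's cis window.
#'
#' @param scenario a \code{\linkS4class{SimScenario}}.
#' @param tissue tissue name (must be one of \code{scenario@tissues}).
#' @return data.frame with columns \code{gene_id}, \code{variant_id},
#'   \code{chrom}, \code{pos}, \code{effect_allele}, \code{other_allele},
#'   \code{eaf} (in-cohort), \code{beta}, \code{se}, \code{pvalue}.
#' @examples
#' sc <- simScenario(seed = 1, nGenes = 2, nEqtl = 100)
#' eq <- simulateEqtlSumstats(sc, "placenta")
#' head(eq)
#' @export
simulateEqtlSumstats <- function(scenario, tissue) {
  stopifnot(is(scenario, "SimScenario"))
  ti <- match(tissue, scenario@tissues)
  if (is.na(ti)) stop("unknown tissue: ", tissue)
  setup <- scenarioSetup(scenario)
  v <- setup$variants
  arch <- setup$arch
  withSeed(subSeed(scenario, 1L + ti), {
    G <- drawGenotypes(v, scenario@nEqtl, scenario@rho)
    out <- vector("list", nrow(setup$genes))
    for (gi in seq_len(nrow(setup$genes))) {
      g <- setup$genes$gene_id[gi]
      gv <- v[v$gene_id == g, , drop = FALSE]
      cis <- abs(gv$pos - setup$genes$tss[gi]) <= scenario@cisWindow
      gv <- gv[cis, , drop = FALSE]
      if (!nrow(gv)) stop("gene ", g, " has zero cis variants")
      ca <- arch[arch$gene_id == g & arch$tissue == tissue, , drop = FALSE]
      if (nrow(ca)) {
        S <- theoreticalDosageCov(v[v$gene_id == g, , drop = FALSE],
                                  scenario@rho)
        b <- stats::setNames(numeric(nrow(S)), rownames(S))
        b[ca$variant_id] <- ca$b
        varGen <- as.numeric(t(b) %*% S %*% b)
        noiseSd <- sqrt(varGen * (1 - scenario@eqtlH2) / scenario@eqtlH2)
        expr <- as.vector(G[, names(b), drop = FALSE] %*% b) +
          stats::rnorm(scenario@nEqtl, 0, noiseSd)
      } else {
        expr <- stats::rnorm(scenario@nEqtl)
      }
      ms <- marginalStats(G[, gv$variant_id, drop = FALSE], expr)
      out[[gi]] <- data.frame(
        gene_id = g, variant_id = gv$variant_id, chrom = gv$chrom,
        pos = gv$pos, effect_allele = gv$effect_allele,
        other_allele = gv$other_allele, eaf = ms$mean_dosage / 2,
        beta = ms$beta, se = ms$se, pvalue = ms$p,
        stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Simulate GWAS summary statistics
#'
#' Draws a fresh GWAS cohort; the trait is the sum over true genes of
#' \code{alpha} times the cohort-standardized true focal-tissue GReX, plus
#' Gaussian noise, then standardized to zero mean and unit variance (a
#' trait z-score).  Per-variant marginal regression of the trait on dosage
#' gives beta, SE, p and z.
#'
#' @param scenario a \code{\linkS4class{SimScenario}}.
#' @param returnCohort when \code{TRUE}, also return the cohort's genotype
#'   matrix and trait vector (useful for validating summary-statistic
#'   results against individual-level regression).
#' @return data.frame with columns \code{variant_id}, \code{chrom},
#'   \code{pos}, \code{effect_allele}, \code{other_allele}, \code{eaf},
#'   \code{beta}, \code{se}, \code{pvalue}, \code{z}, \code{n}; or, with
#'   \code{returnCohort}, a list with elements \code{sumstats},
#'   \code{genotypes} and \code{trait}.
#' @examples
#' sc <- simScenario(seed = 1, nGenes = 2, nGwas = 500)
#' gw <- simulateGwasSumstats(sc)
#' head(gw)
#' @export
simulateGwasSumstats <- function(scenario, returnCohort = FALSE) {
  stopifnot(is(scenario, "SimScenario"))
  setup <- scenarioSetup(scenario)
  v <- setup$variants
  arch <- setup$arch
  tg <- scenario@trueGenes
  if (nrow(tg) && !all(tg$gene_id %in% setup$genes$gene_id))
    stop("trueGenes references unknown gene IDs")
  nT <- length(scenario@tissues)
  withSeed(subSeed(scenario, 2L + nT), {
    G <- drawGenotypes(v, scenario@nGwas, scenario@rho)
    genetic <- numeric(scenario@nGwas)
    if (nrow(tg)) {
      for (i in seq_len(nrow(tg))) {
        ca <- arch[arch$gene_id == tg$gene_id[i] &
                   arch$tissue == scenario@focalTissue, , drop = FALSE]
        if (!nrow(ca))
          stop("true gene ", tg$gene_id[i],
               " has no causal eQTLs in the focal tissue")
        grex <- as.vector(G[, ca$variant_id, drop = FALSE] %*% ca$b)
        genetic <- genetic + tg$alpha[i] * as.vector(scale(grex))
      }
    }
    noiseSd <- scenario@traitNoiseSd
    if (is.na(noiseSd))
      noiseSd <- sqrt(max(1 - sum(tg$alpha^2), 0.05))
    trait <- genetic + stats::rnorm(scenario@nGwas, 0, noiseSd)
    trait <- as.vector(scale(trait))
    ms <- marginalStats(G, trait)
    ss <- data.frame(variant_id = v$variant_id, chrom = v$chrom,
                     pos = v$pos, effect_allele = v$effect_allele,
                     other_allele = v$other_allele,
                     eaf = ms$mean_dosage / 2, beta = ms$beta, se = ms$se,
                     pvalue = ms$p, z = ms$beta / ms$se,
                     n = scenario@nGwas, stringsAsFactors = FALSE)
    if (returnCohort) list(sumstats = ss, genotypes = G, trait = trait)
    else ss
  })
}

#' Simulate a full study
#'
#' Convenience wrapper: reference panel, per-tissue eQTL summary statistics,
#' GWAS summary statistics and ground truth in one call, optionally written
#' as TSV files that round-trip through the package readers.
#'
#' @param scenario a \code{\linkS4class{SimScenario}}.
#' @param dir optional output directory; when given, writes
#'   \code{panel_variants.tsv}, \code{panel_genotypes.tsv},
#'   \code{eqtl_<tissue>.tsv}, \code{gwas.tsv} and
#'   \code{truth_*.tsv}.
#' @return list with elements \code{panel} (\code{LDPanel}), \code{eqtl}
#'   (named list of data.frames, one per tissue), \code{gwas} (data.frame)
#'   and \code{truth} (\code{GroundTruth}).
#' @export
simulateStudy <- function(scenario, dir = NULL) {
  panel <- simulatePanel(scenario)
  eqtl <- lapply(stats::setNames(scenario@tissues, scenario@tissues),
                 function(t) simulateEqtlSumstats(scenario, t))
  gwas <- simulateGwasSumstats(scenario)
  truth <- simulateTruth(scenario)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeLDPanel(panel, file.path(dir, "panel_variants.tsv"),
                 file.path(dir, "panel_genotypes.tsv"))
    for (t in names(eqtl))
      writeTsv(eqtl[[t]], file.path(dir, paste0("eqtl_", t, ".tsv")))
    writeTsv(gwas, file.path(dir, "gwas.tsv"))
    writeTsv(truth@eqtl, file.path(dir, "truth_eqtl.tsv"))
    writeTsv(truth@genes, file.path(dir, "truth_genes.tsv"))
    writeTsv(truth@gwasMarginal, file.path(dir, "truth_gwas.tsv"))
  }
  list(panel = panel, eqtl = eqtl, gwas = gwas, truth = truth)
}
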