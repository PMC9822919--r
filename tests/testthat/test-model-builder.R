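test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdrAdjust(0.04), 0.04)
  expect_equal(fdrAdjust(c(0.5, 1.0)), c(1.0, 1.0))
  expect_error(fdrAdjust(c(0.5, 0)), "0, 1")
  expect_error(fdrAdjust(c(0.5, 1.2)), "0, 1")
  # order-preserving and monotone against a direct step-up oracle
  set.seed(1)
  p <- runif(20)
  q <- fdrAdjust(p)
  m <- length(p)
  o <- order(p)
  oracle <- rev(cummin(rev(p[o] * m / seq_len(m))))[order(o)]
  expect_equal(q, pmin(oracle, 1))
  expect_true(all(q >= p))
})

test_that("per-SNP variance explained follows 2pq beta^2", {
  expect_equal(snpVariance(0.5, 1), 0.5)
  expect_equal(snpVariance(0, 3), 0)
  expect_equal(snpVariance(1, 3), 0)
  expect_equal(snpVariance(0.2, 0.3), 0.0288)
  expect_error(snpVariance(1.2, 0.3), "eaf")
})

test_that("clumping keeps the most significant of a correlated pair", {
  sc <- simScenario(seed = 31, nGenes = 1, mPerGene = 10, blockSize = 10,
                    rho = 0.8, nPanel = 400)
  panel <- simulatePanel(sc)
  v <- variantInfo(panel)
  cand <- data.frame(variant_id = v$variant_id[1:2], pos = v$pos[1:2],
                     pvalue = c(1e-8, 1e-4), stringsAsFactors = FALSE)
  expect_equal(ldClump(cand, panel), v$variant_id[1])
  # single candidate is always retained
  expect_equal(ldClump(cand[2, ], panel), v$variant_id[2])
  # a candidate absent from the panel is an error naming it
  cand$variant_id[2] <- "ghost"
  expect_error(ldClump(cand, panel), "ghost")
})

test_that("clumping matches a brute-force greedy oracle on 20-variant instances", {
  for (seed in c(41, 42, 43)) {
    sc <- simScenario(seed = seed, nGenes = 1, mPerGene = 20, blockSize = 10,
                      rho = 0.7, nPanel = 300)
    panel <- simulatePanel(sc)
    v <- variantInfo(panel)
    set.seed(seed)
    cand <- data.frame(variant_id = v$variant_id, pos = v$pos,
                       pvalue = runif(20, 1e-10, 0.1),
                       stringsAsFactors = FALSE)
    kept <- ldClump(cand, panel, r2Threshold = 0.1, windowBp = 250000)
    oracle <- bruteClump(cand, panelGenotypes(panel), 0.1, 250000)
    expect_identical(kept, oracle)
    # no retained pair within the window is correlated at or above 0.1
    G <- panelGenotypes(panel)
    pos <- v$pos[match(kept, v$variant_id)]
    for (i in seq_along(kept)) for (j in seq_along(kept)) {
      if (i < j && abs(pos[i] - pos[j]) <= 250000)
        expect_lt(cor(G[, kept[i]], G[, kept[j]])^2, 0.1)
    }
    # retained set is invariant to candidate row order
    shuf <- cand[sample(nrow(cand)), , drop = FALSE]
    expect_identical(sort(ldClump(shuf, panel)), sort(kept))
  }
})

test_that("gene-level variance filter excludes strictly outside [0.01, 2]", {
  mk <- function(v) {
    # single-SNP gene with eaf 0.5 gives var_explained = beta^2 / 2
    data.frame(gene_id = paste0("g", seq_along(v)),
               variant_id = paste0("s", seq_along(v)),
               effect_allele = "A", other_allele = "G",
               weight = sqrt(2 * v), eaf = 0.5, var_explained = v,
               stringsAsFactors = FALSE)
  }
  models <- GeneModelSet("t", mk(c(0.005, 0.01, 0.5, 2.0, 2.1)))
  kept <- filterGeneVariance(models)
  expect_setequal(modelGenes(kept)$gene_id, c("g2", "g3", "g4"))
})

test_that("buildModels composes the four stages with monotone counts", {
  sc <- simScenario(seed = 51, nGenes = 10, nEqtl = 800, nPanel = 300,
                    eqtlH2 = 0.3, tissues = "placenta")
  panel <- simulatePanel(sc)
  eq <- simulateEqtlSumstats(sc, "placenta")
  fit <- buildModels(eq, panel, tissue = "placenta")
  rep <- fit$report
  expect_equal(rep$stage, c("input", "fdr", "clump", "variance_filter"))
  expect_true(all(diff(rep$n_variants) <= 0))
  expect_true(all(diff(rep$n_genes) <= 0))
  g <- modelGenes(fit$models)
  w <- modelWeights(fit$models)
  expect_equal(g$total_variance,
               as.numeric(tapply(w$var_explained, w$gene_id, sum)[g$gene_id]))
  # weights are the retained marginal eQTL betas, unshrunken
  expect_equal(w$weight, eq$beta[match(w$variant_id, eq$variant_id)])
  # retained per-gene sets are mutually unlinked at the clump threshold
  G <- panelGenotypes(panel)
  for (gene in g$gene_id) {
    vids <- w$variant_id[w$gene_id == gene]
    if (length(vids) > 1) {
      C <- cor(G[, vids])^2
      expect_lt(max(C[upper.tri(C)]), 0.1)
    }
  }
  # input row order does not change the result
  set.seed(1)
  fit2 <- buildModels(eq[sample(nrow(eq)), ], panel, tissue = "placenta")
  expect_equal(modelWeights(fit2$models), modelWeights(fit$models))
})

test_that("buildModels drops weak genes and handles empty input", {
  # a gene whose best within-gene q-value is >= 0.1 yields no model
  eq <- data.frame(gene_id = "g1", variant_id = c("v1", "v2", "v3"),
                   pos = c(100L, 200L, 300L),
                   effect_allele = c("A", "T", "C"),
                   other_allele = c("G", "C", "A"),
                   eaf = c(0.3, 0.5, 0.2), beta = 0.1, se = 0.1,
                   pvalue = c(0.2, 0.5, 0.9), stringsAsFactors = FALSE)
  fit <- buildModels(eq, toyPanel(), tissue = "t")
  expect_equal(nrow(modelGenes(fit$models)), 0)

  # one strong eQTL at eaf 0.5, beta 1 -> weight 1, V_g = 0.5
  eq2 <- eq[2, ]; eq2$pvalue <- 1e-6; eq2$beta <- 1
  fit2 <- buildModels(eq2, toyPanel(), tissue = "t")
  expect_equal(modelWeights(fit2$models)$weight, 1)
  expect_equal(modelGenes(fit2$models)$total_variance, 0.5)

  fit3 <- buildModels(eq[0, ], toyPanel(), tissue = "t")
  expect_equal(nrow(modelWeights(fit3$models)), 0)
  expect_equal(nrow(fit3$report), 4)
})

test_that("clumping removes nothing on an LD-free panel", {
  sc <- simScenario(seed = 61, nGenes = 4, mPerGene = 10, rho = 0,
                    nEqtl = 2000, nPanel = 2000, eqtlH2 = 0.4,
                    tissues = "placenta")
  panel <- simulatePanel(sc)
  eq <- simulateEqtlSumstats(sc, "placenta")
  eq$fdr_q <- ave(eq$pvalue, eq$gene_id, FUN = fdrAdjust)
  surv <- eq[eq$fdr_q < 0.1, ]
  fit <- buildModels(eq, panel, tissue = "placenta",
                     varBounds = c(0, Inf))
  expect_equal(nrow(modelWeights(fit$models)), nrow(surv))
})

test_that("global FDR scope matches a transcriptome-wide adjustment", {
  sc <- simScenario(seed = 71, nGenes = 8, nEqtl = 400, nPanel = 200,
                    tissues = "placenta")
  panel <- simulatePanel(sc)
  eq <- simulateEqtlSumstats(sc, "placenta")
  gl <- buildModels(eq, panel, tissue = "placenta", fdrScope = "global")
  nSurvive <- sum(fdrAdjust(eq$pvalue) < 0.1)
  expect_equal(gl$report$n_variants[gl$report$stage == "fdr"], nSurvive)
  expect_lte(gl$report$n_variants[gl$report$stage == "clump"], nSurvive)
})

test_that("well-powered models tag the planted causal variants", {
  # at n_eqtl = 5000 and h2 = 0.3 most retained models should contain a
  # variant in strong LD (r2 >= 0.5) with a true causal variant
  sc <- simScenario(seed = 101, nGenes = 20, nEqtl = 5000, nPanel = 400,
                    eqtlH2 = 0.3, tissues = "placenta")
  panel <- simulatePanel(sc)
  eq <- simulateEqtlSumstats(sc, "placenta")
  tr <- truthEqtls(simulateTruth(sc))
  fit <- buildModels(eq, panel, tissue = "placenta")
  w <- modelWeights(fit$models)
  G <- panelGenotypes(panel)
  tagged <- vapply(unique(w$gene_id), function(g) {
    vids <- w$variant_id[w$gene_id == g]
    causal <- tr$variant_id[tr$gene_id == g & tr$tissue == "placenta"]
    any(cor(G[, vids, drop = FALSE], G[, causal, drop = FALSE])^2 >= 0.5)
  }, logical(1))
  expect_gt(length(tagged), 10)
  expect_gte(mean(tagged), 0.8)
})
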