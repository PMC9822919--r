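test_that("predicted-expression variance is the weighted covariance form", {
  expect_equal(predictedExpressionVariance(1, matrix(0.5)), 0.5)
  expect_equal(predictedExpressionVariance(c(1, 1), diag(c(0.5, 0.5))), 1.0)
  # empirical oracle: w' Cov(G) w equals the variance of the weighted score
  sc <- simScenario(seed = 81, nGenes = 1, mPerGene = 5, blockSize = 5,
                    rho = 0.6, nPanel = 200, tissues = "placenta")
  G <- panelGenotypes(simulatePanel(sc))
  w <- c(0.4, -1.2, 0.05, 0.9, -0.3)
  direct <- var(as.vector(G %*% w))
  expect_equal(predictedExpressionVariance(w, cov(G)), direct,
               tolerance = 1e-10)
})

test_that("z-score and effect reduce to closed forms on toy models", {
  # single-SNP model: sigma_l / sigma_g cancels, Z = z_l
  expect_equal(twasZscore(1, z = 1.7, sigmaL = sqrt(0.5),
                          sigmaG = sqrt(0.5)), 1.7)
  # two uncorrelated SNPs, unit weights and SDs: Z = (2 + 2) / sqrt(2)
  expect_equal(twasZscore(c(1, 1), z = c(2, 2), sigmaL = c(1, 1),
                          sigmaG = sqrt(2)), 4 / sqrt(2))
  # single-SNP effect per SD of expression is the per-allele GWAS effect
  # rescaled by the dosage SD
  expect_equal(twasEffect(1, beta = 0.2, sigmaL2 = 0.5, sigmaG = sqrt(0.5)),
               0.2 * sqrt(0.5))
})

test_that("association is invariant to weight rescaling and allele flips", {
  sc <- simScenario(seed = 82, nGenes = 4, nEqtl = 500, nPanel = 250,
                    nGwas = 1500, tissues = "placenta")
  st <- simulateStudy(sc)
  fit <- buildModels(st$eqtl$placenta, st$panel, tissue = "placenta")
  base <- assocResults(runAssociation(st$gwas, fit$models, st$panel))

  # scale every weight by c > 0: Z and p unchanged
  w2 <- modelWeights(fit$models)
  w2$weight <- w2$weight * 3.7
  w2$var_explained <- snpVariance(w2$eaf, w2$weight)
  scaled <- GeneModelSet("placenta", w2)
  res2 <- assocResults(runAssociation(st$gwas, scaled, st$panel))
  expect_equal(res2$zscore, base$zscore, tolerance = 1e-12)
  expect_equal(res2$pvalue, base$pvalue, tolerance = 1e-12)

  # flip the reported effect allele of every GWAS row: results unchanged
  gw <- st$gwas
  flip <- gw
  flip$effect_allele <- gw$other_allele
  flip$other_allele <- gw$effect_allele
  flip$beta <- -gw$beta
  flip$z <- -gw$z
  flip$eaf <- 1 - gw$eaf
  res3 <- assocResults(runAssociation(flip, fit$models, st$panel))
  expect_equal(res3$zscore, base$zscore, tolerance = 1e-12)
  expect_equal(res3$effect, base$effect, tolerance = 1e-12)
})

test_that("genes without usable variants are skipped with a reason", {
  models <- GeneModelSet("t", data.frame(
    gene_id = c("g1", "g2"), variant_id = c("v2", "zz"),
    effect_allele = c("T", "A"), other_allele = c("C", "G"),
    weight = 1, eaf = 0.5, var_explained = 0.5, stringsAsFactors = FALSE))
  res <- runAssociation(toyGwas(), models, toyPanel())
  expect_equal(assocResults(res)$gene_id, "g1")
  skp <- skipReport(res)
  expect_equal(skp$gene_id, "g2")
  expect_equal(skp$reason, "no_gwas_overlap")

  # empty model set gives an empty result set, not an error
  empty <- GeneModelSet("t", modelWeights(models)[0, ])
  expect_equal(nrow(assocResults(runAssociation(toyGwas(), empty,
                                                toyPanel()))), 0)
})

test_that("covariance falls back from model file to panel", {
  sc <- simScenario(seed = 83, nGenes = 2, nEqtl = 400, nPanel = 200,
                    nGwas = 800, tissues = "placenta")
  st <- simulateStudy(sc)
  fit <- buildModels(st$eqtl$placenta, st$panel, tissue = "placenta")
  withCov <- assocResults(runAssociation(st$gwas, fit$models, panel = NULL))
  noCov <- GeneModelSet("placenta", modelWeights(fit$models))
  fromPanel <- assocResults(runAssociation(st$gwas, noCov, st$panel))
  expect_equal(withCov$zscore, fromPanel$zscore, tolerance = 1e-12)
  # neither covariance nor panel: genes are skipped, not zeroed
  none <- runAssociation(st$gwas, noCov, panel = NULL)
  expect_equal(nrow(assocResults(none)), 0)
  expect_true(all(skipReport(none)$reason == "no_covariance"))
})

test_that("fixed-seed reruns give identical result tables", {
  sc <- simScenario(seed = 84, nGenes = 3, nEqtl = 300, nPanel = 150,
                    nGwas = 500, tissues = "placenta")
  run <- function() {
    st <- simulateStudy(sc)
    fit <- buildModels(st$eqtl$placenta, st$panel, tissue = "placenta")
    assocResults(runAssociation(st$gwas, fit$models, st$panel))
  }
  expect_identical(run(), run())
})

test_that("signs of detected effects recover the signs of planted effects", {
  hits <- 0; total <- 0
  for (seed in 91:95) {
    tg <- data.frame(gene_id = sprintf("SIMG%04d", 1:4),
                     alpha = c(0.3, -0.3, 0.25, -0.2),
                     exclusive = FALSE)
    sc <- simScenario(seed = seed, nGenes = 8, nEqtl = 1500, nPanel = 300,
                      nGwas = 6000, eqtlH2 = 0.3, tissues = "placenta",
                      trueGenes = tg)
    st <- simulateStudy(sc)
    fit <- buildModels(st$eqtl$placenta, st$panel, tissue = "placenta")
    res <- assocResults(runAssociation(st$gwas, fit$models, st$panel))
    res <- res[res$gene_id %in% tg$gene_id &
               res$pvalue < 0.05 / nrow(res), , drop = FALSE]
    if (nrow(res)) {
      truth <- tg$alpha[match(res$gene_id, tg$gene_id)]
      hits <- hits + sum(sign(res$effect) == sign(truth))
      total <- total + nrow(res)
    }
  }
  expect_gt(total, 5)
  expect_gte(hits / total, 0.95)
})
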