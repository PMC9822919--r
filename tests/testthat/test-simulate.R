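test_that("scenario validation catches bad LD and heritability parameters", {
  expect_error(simScenario(rho = 1), "rho")
  expect_error(simScenario(rho = -0.1), "rho")
  expect_error(simScenario(eqtlH2 = 0), "eqtlH2")
  expect_error(simScenario(seed = 1, nGenes = 3,
                           trueGenes = data.frame(gene_id = "SIMG9999",
                                                  alpha = 0.3,
                                                  exclusive = FALSE)),
               "outside the scenario")
})

test_that("panel draws are deterministic and respect dosage invariants", {
  sc <- simScenario(seed = 5, nGenes = 3, nPanel = 80)
  p1 <- simulatePanel(sc)
  p2 <- simulatePanel(sc)
  expect_identical(panelGenotypes(p1), panelGenotypes(p2))
  expect_true(all(panelGenotypes(p1) %in% 0:2))
  expect_true(all(alleleFreqs(p1) >= 0 & alleleFreqs(p1) <= 1))
  expect_equal(nVariants(p1), 3 * 30)
  expect_equal(nIndividuals(p1), 80)
})

test_that("rho = 0 panels are LD-free and rho = 0.9 gives adjacent r2 near 0.81", {
  sc0 <- simScenario(seed = 3, nGenes = 2, mPerGene = 20, rho = 0,
                     nPanel = 2000)
  G <- panelGenotypes(simulatePanel(sc0))
  v <- variantInfo(simulatePanel(sc0))
  r2 <- numeric()
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    C <- cor(G[, idx])
    r2 <- c(r2, C[upper.tri(C)]^2)
  }
  expect_lt(mean(r2), 3 / 2000)

  # Monte-Carlo check of the haplotype-copy model: >= 10,000 haplotypes
  sc9 <- simScenario(seed = 4, nGenes = 2, mPerGene = 20, blockSize = 10,
                     rho = 0.9, nPanel = 5000)
  p9 <- simulatePanel(sc9)
  G9 <- panelGenotypes(p9)
  v9 <- variantInfo(p9)
  adj <- numeric()
  for (ch in unique(v9$chrom)) {
    idx <- which(v9$chrom == ch)
    for (b in 0:1) {
      blk <- idx[(b * 10 + 1):(b * 10 + 10)]
      for (j in 1:9)
        adj <- c(adj, cor(G9[, blk[j]], G9[, blk[j + 1]])^2)
    }
  }
  expect_equal(mean(adj), 0.81, tolerance = 0.03)
})

test_that("marginal eQTL statistics are consistent with the planted effects", {
  sc <- simScenario(seed = 6, nGenes = 1, mPerGene = 10, blockSize = 5,
                    nCausal = 1, eqtlH2 = 0.5, nEqtl = 10000,
                    tissues = "placenta", sharedFrac = 0,
                    trueGenes = data.frame(gene_id = character(),
                                           alpha = numeric(),
                                           exclusive = logical()))
  eq <- simulateEqtlSumstats(sc, "placenta")
  tr <- truthEqtls(simulateTruth(sc))
  causal <- eq[eq$variant_id == tr$variant_id[1], ]
  expect_lt(abs(causal$beta - tr$b[1]), 3 * causal$se)
  expect_identical(eq, simulateEqtlSumstats(sc, "placenta"))
  expect_error(simulateEqtlSumstats(sc, "kidney"), "unknown tissue")
})

test_that("null genes give uniform eQTL p-values at the nominal 5% rate", {
  # 200 genes with no causal cis variants
  sc <- simScenario(seed = 8, nGenes = 200, mPerGene = 5, blockSize = 5,
                    nCausal = 0, nEqtl = 300, tissues = "placenta",
                    trueGenes = data.frame(gene_id = character(),
                                           alpha = numeric(),
                                           exclusive = logical()))
  eq <- simulateEqtlSumstats(sc, "placenta")
  frac <- mean(eq$pvalue < 0.05)
  expect_equal(frac, 0.05, tolerance = 3 * sqrt(0.05 * 0.95 / nrow(eq)) / 0.05)
})

test_that("GWAS under the global null has nominal type-I error at variants", {
  sc <- simScenario(seed = 9, nGenes = 40, mPerGene = 10, nGwas = 2000,
                    tissues = "placenta",
                    trueGenes = data.frame(gene_id = character(),
                                           alpha = numeric(),
                                           exclusive = logical()))
  gw <- simulateGwasSumstats(sc)
  expect_equal(mean(gw$pvalue < 0.05), 0.05, tolerance = 0.5)
  expect_identical(gw, simulateGwasSumstats(sc))
})

test_that("causal-SNP marginal GWAS effect matches its closed-form expectation", {
  # one gene, one causal SNP carrying all GReX: expected marginal beta on the
  # unit-variance trait is alpha * sign(b) / sigma_snp, which is also what
  # the ground-truth table reports
  sc <- simScenario(seed = 10, nGenes = 1, mPerGene = 10, blockSize = 5,
                    nCausal = 1, sharedFrac = 0, nGwas = 20000,
                    tissues = "placenta",
                    trueGenes = data.frame(gene_id = "SIMG0001", alpha = 0.3,
                                           exclusive = FALSE))
  truth <- simulateTruth(sc)
  tr <- truthEqtls(truth)
  v <- variantInfo(simulatePanel(sc))
  f <- v$freq[v$variant_id == tr$variant_id[1]]
  expected <- 0.3 * sign(tr$b[1]) / sqrt(2 * f * (1 - f))
  tg <- truthGwasEffects(truth)
  expect_equal(tg$true_beta[tg$variant_id == tr$variant_id[1]], expected,
               tolerance = 1e-12)
  gw <- simulateGwasSumstats(sc)
  obs <- gw[gw$variant_id == tr$variant_id[1], ]
  expect_lt(abs(obs$beta - expected), 4 * obs$se)
})

test_that("generated study files parse losslessly through the io readers", {
  sc <- simScenario(seed = 12, nGenes = 3, nEqtl = 60, nPanel = 40,
                    nGwas = 200, tissues = c("placenta", "tissue1"))
  dir <- tempfile()
  st <- simulateStudy(sc, dir = dir)
  gw <- readGwasSumstats(file.path(dir, "gwas.tsv"))
  expect_equal(attr(gw, "n_skipped"), 0)
  expect_equal(gw$beta, st$gwas$beta)
  expect_equal(gw$z, st$gwas$z)
  eq <- readEqtlSumstats(file.path(dir, "eqtl_placenta.tsv"))
  expect_equal(attr(eq, "n_skipped"), 0)
  expect_equal(eq$beta, st$eqtl$placenta$beta)
  panel <- readLDPanel(file.path(dir, "panel_variants.tsv"),
                       file.path(dir, "panel_genotypes.tsv"))
  expect_equal(panelGenotypes(panel), panelGenotypes(st$panel),
               ignore_attr = TRUE)

  # same seed, second run: byte-identical files
  dir2 <- tempfile()
  simulateStudy(sc, dir = dir2)
  for (f in list.files(dir)) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
})

test_that("exclusive true genes get disjoint causal sets across tissues", {
  sc <- simScenario(seed = 13, nGenes = 6, mPerGene = 30, nCausal = 2)
  tr <- truthEqtls(simulateTruth(sc))
  for (g in c("SIMG0001", "SIMG0002", "SIMG0003")) {
    sets <- split(tr$variant_id[tr$gene_id == g], tr$tissue[tr$gene_id == g])
    expect_equal(anyDuplicated(unlist(sets)), 0)
  }
  # non-exclusive genes share sharedFrac of their causal set
  g4 <- tr[tr$gene_id == "SIMG0004", ]
  shared <- unique(g4$variant_id[g4$shared])
  expect_equal(length(shared), 1)   # round(0.5 * 2)
  expect_true(all(table(g4$variant_id[g4$shared]) == 5))
})
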