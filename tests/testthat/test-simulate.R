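test_that("identical configs give byte-identical output from all generators", {
  cfg <- smallConfig(seed = 11)
  a <- simulateStudy(cfg)
  b <- simulateStudy(cfg)
  expect_identical(exprsMatrix(a$experiment), exprsMatrix(b$experiment))
  expect_identical(sampleData(a$experiment), sampleData(b$experiment))
  expect_identical(setMembers(a$collection), setMembers(b$collection))
  expect_identical(a$annotation@assignments, b$annotation@assignments)
  expect_identical(a$cytokines, b$cytokines)
  expect_identical(a$truth, b$truth)
})

test_that("expression generator plants the designed structure", {
  cfg <- smallConfig(seed = 5, nGenes = 800L, moduleSizes = c(100L, 100L))
  sim <- simulateExpression(cfg)
  ex <- exprsMatrix(sim$experiment)
  md <- sampleData(sim$experiment)
  expect_equal(ncol(ex), 2L * sum(cfg@nSubjects))
  expect_setequal(unique(paste(md$subject_id, md$stimulation)),
                  paste(rep(unique(md$subject_id), each = 2), c("EW", "M")))

  # planted DE genes shift EW - M by ~deLog2FC in the designated groups only
  ewBer <- md$sample_id[md$stimulation == "EW" & md$group == "BER"]
  mBer <- md$sample_id[md$stimulation == "M" & md$group == "BER"]
  ewAc <- md$sample_id[md$stimulation == "EW" & md$group == "AC"]
  mAc <- md$sample_id[md$stimulation == "M" & md$group == "AC"]
  de <- sim$truth$de_genes
  shiftBer <- mean(rowMeans(ex[de, ewBer]) - rowMeans(ex[de, mBer]))
  shiftAc <- mean(rowMeans(ex[de, ewAc]) - rowMeans(ex[de, mAc]))
  expect_lt(abs(shiftBer - cfg@deLog2FC), 0.15)
  expect_lt(abs(shiftAc), 0.15)

  # within-module pairwise correlation lands near the target
  m1 <- names(sim$truth$module_assignment)[sim$truth$module_assignment == 1L]
  r <- cor(t(ex[m1, ]))
  meanR <- mean(r[upper.tri(r)])
  expect_gt(meanR, 0.7)
  expect_lt(meanR, 0.9)
})

test_that("zero planted effect leaves no group-dependent stimulation shift", {
  cfg <- smallConfig(seed = 9, deLog2FC = 0)
  sim <- simulateExpression(cfg)
  ex <- exprsMatrix(sim$experiment)
  md <- sampleData(sim$experiment)
  de <- sim$truth$de_genes
  d <- function(g) {
    ew <- md$sample_id[md$stimulation == "EW" & md$group == g]
    m <- md$sample_id[md$stimulation == "M" & md$group == g]
    mean(rowMeans(ex[de, ew]) - rowMeans(ex[de, m]))
  }
  expect_lt(abs(d("BER") - d("AC")), 0.2)
})

test_that("invalid configs are rejected", {
  expect_error(simulationConfig(moduleSizes = c(300L, 300L), nGenes = 500L),
               "module sizes")
  expect_error(simulationConfig(moduleCor = 1.2), "moduleCor")
  expect_error(
    simulateGeneSets(smallConfig(seed = 1, plantedOverlap = 1,
                                 signatureSize = 400L, nDEGenes = 10L),
                     list(de_genes = sprintf("GENE%05d", 1:10)),
                     sprintf("GENE%05d", 1:500)),
    "more planted-overlap genes")
})

test_that("planted signatures are hypergeometrically enriched in the true-positive signature", {
  study <- simulateStudy(simulationConfig(seed = 21))
  deg <- fitContrast(study$experiment,
                     contrastSpec("difference_of_differences", "BER", "AC"))
  sig <- signatureGenes(standardizeSignature(deg, "up"))
  universe <- rownames(study$experiment)
  sets <- setMembers(study$collection)
  for (nm in study$planted_signatures) {
    expect_gte(length(intersect(sets[[nm]], study$truth$de_genes)),
               0.5 * length(sets[[nm]]))
    a <- length(intersect(sig, sets[[nm]]))
    p <- hyperTailOracle(a, length(sets[[nm]]), length(sig),
                         length(universe))
    expect_lt(p, 1e-4)
  }
})

test_that("cytokine generator respects the detection floor and planted shifts", {
  cfg <- smallConfig(seed = 13, detectionFloor = 1.0)
  cy <- simulateCytokines(cfg)
  expect_gte(min(cy$concentration), 1.0)
  expect_setequal(unique(cy$cytokine), names(cfg@cytokineEffects))
  expect_equal(anyDuplicated(paste(cy$subject_id, cy$cytokine,
                                   cy$condition)), 0L)

  # a planted BER IL-9 shift yields a positive recovered BER coefficient
  hits <- 0L
  for (s in 1:10) {
    cyS <- simulateCytokines(smallConfig(
      seed = s, cytokineEffects = list(`IL-9` = c(BER = 1.0))))
    fit <- fitCytokineGroups(cyS)
    if (fit$estimate[fit$cytokine == "IL-9" & fit$term == "BER"] > 0)
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("null cytokine effects leave group medians within noise", {
  cfg <- smallConfig(seed = 17,
                     cytokineEffects = list(A = numeric(), B = numeric()))
  cy <- simulateCytokines(cfg)
  d <- computeDelta(cy)
  d$tdelta <- log10TransformDelta(d$delta)
  med <- tapply(d$tdelta, d$group, median)
  expect_lt(max(med) - min(med), 0.5)
})
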