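test_that("soft adjacency is |r|^beta with unit diagonal", {
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)   # cor(x, y) = 0.8 exactly
  ex <- rbind(g1 = x, g2 = y)
  colnames(ex) <- paste0("s", 1:4)
  a <- softAdjacency(ex, beta = 7)
  expect_equal(a["g1", "g2"], 0.8^7, tolerance = 1e-12)
  expect_equal(diag(a), c(g1 = 1, g2 = 1))

  perf <- rbind(g1 = x, g2 = 2 * x + 1)
  colnames(perf) <- paste0("s", 1:4)
  expect_equal(softAdjacency(perf, 7)["g1", "g2"], 1)

  orth <- rbind(g1 = c(1, -1, 1, -1), g2 = c(1, 1, -1, -1))
  colnames(orth) <- paste0("s", 1:4)
  expect_equal(softAdjacency(orth, 7)["g1", "g2"], 0)

  expect_error(softAdjacency(ex, beta = 0), "positive")
  withVar0 <- rbind(ex, g3 = rep(5, 4))
  expect_message(a3 <- softAdjacency(withVar0, 7), "zero-variance")
  expect_equal(nrow(a3), 2)
})

test_that("TOM matches the hand example and the triple-loop oracle", {
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  tom <- topologicalOverlap(a)
  expect_equal(tom[1, 2], 0.5, tolerance = 1e-12)

  expect_equal(topologicalOverlap(diag(4)), diag(4))

  set.seed(19)
  ex <- matrix(rnorm(50 * 20), 50, 20,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:20)))
  adj <- softAdjacency(ex, 7)
  tom <- topologicalOverlap(adj)
  expect_lt(max(abs(tom - tomOracle(adj))), 1e-10)
  expect_equal(tom, t(tom))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))

  bad <- adj; bad[1, 2] <- bad[1, 2] + 1e-6
  expect_error(topologicalOverlap(bad), "symmetric")
})

test_that("module detection recovers planted blocks and handles degenerate cuts", {
  cfg <- smallConfig(seed = 51, nGenes = 600L, nDEGenes = 0L,
                     nSubjects = c(AC = 5L, BET = 10L, BER = 15L),
                     moduleSizes = c(100L, 100L, 100L))
  sim <- simulateExpression(cfg)
  ex <- exprsMatrix(sim$experiment)
  tom <- topologicalOverlap(softAdjacency(ex, 7))
  part <- detectModules(1 - tom, 50L)
  expect_equal(length(moduleSizes(part)), 3L)
  expect_true(all(moduleSizes(part) >= 50L))
  ok <- moduleAssignment(part) > 0
  ari <- mclust::adjustedRandIndex(
    moduleAssignment(part)[ok],
    sim$truth$module_assignment[names(which(ok))])
  expect_gte(ari, 0.8)

  expect_identical(moduleAssignment(part),
                   moduleAssignment(detectModules(1 - tom, 50L)))

  expect_warning(none <- detectModules(1 - tom, 601L), "unassigned")
  expect_equal(length(moduleSizes(none)), 0L)
})

test_that("eigengenes summarize their modules with proper orientation", {
  cfg <- smallConfig(seed = 53, nGenes = 300L, nDEGenes = 0L,
                     nSubjects = c(AC = 5L, BET = 10L, BER = 15L),
                     moduleSizes = c(100L))
  sim <- simulateExpression(cfg)
  ex <- exprsMatrix(sim$experiment)
  part <- modulePartition(sim$truth$module_assignment)
  eg <- moduleEigengene(ex, part, 1L)
  expect_equal(sum(eg^2), 1, tolerance = 1e-12)
  expect_gte(abs(cor(eg, sim$truth$latent_factors[1, ])), 0.9)
  expect_gte(mean(cor(eg, t(ex[moduleGenes(part, 1L), ]))), 0)

  # PC1 variance share at least moduleCor - 0.1
  z <- t(scale(t(ex[moduleGenes(part, 1L), ])))
  sv <- svd(z)
  expect_gte(sv$d[1]^2 / sum(sv$d^2), cfg@moduleCor - 0.1)

  # flipping every member row flips the eigengene to its mirror image,
  # leaving member |correlations| unchanged
  exFlip <- ex
  exFlip[moduleGenes(part, 1L), ] <- -exFlip[moduleGenes(part, 1L), ]
  egFlip <- moduleEigengene(exFlip, part, 1L)
  expect_equal(abs(cor(eg, egFlip)), 1, tolerance = 1e-10)

  # identical member profiles: |r| = 1 with every member
  const <- matrix(rep(rnorm(10), each = 3), 3, 10, byrow = FALSE,
                  dimnames = list(paste0("g", 1:3), paste0("s", 1:10)))
  constPart <- modulePartition(setNames(rep(1L, 3), rownames(const)))
  egC <- moduleEigengene(const, constPart, 1L)
  expect_equal(abs(cor(egC, const[1, ])), 1, tolerance = 1e-10)
})

test_that("module merging joins split factors and respects the cutoff", {
  cfg <- smallConfig(seed = 57, nGenes = 300L, nDEGenes = 0L,
                     nSubjects = c(AC = 5L, BET = 10L, BER = 15L),
                     moduleSizes = c(120L))
  sim <- simulateExpression(cfg)
  ex <- exprsMatrix(sim$experiment)
  truthMod <- sim$truth$module_assignment
  # artificially split the planted module in two
  split <- truthMod
  g <- names(split)[split == 1L]
  split[g[1:60]] <- 1L; split[g[61:120]] <- 2L
  part <- modulePartition(split)
  merged <- mergeModules(ex, part, cutoff = 0.29)
  expect_equal(length(moduleSizes(merged)), 1L)
  expect_equal(unname(moduleSizes(merged)[1]), 120L)
  expect_gte(min(moduleSizes(merged)), min(moduleSizes(part)))

  # distinct factors stay apart: dissimilarity >= cutoff leaves the
  # partition unchanged
  cfg2 <- smallConfig(seed = 59, nGenes = 300L, nDEGenes = 0L,
                      nSubjects = c(AC = 5L, BET = 10L, BER = 15L),
                      moduleSizes = c(80L, 80L))
  sim2 <- simulateExpression(cfg2)
  part2 <- modulePartition(sim2$truth$module_assignment)
  merged2 <- mergeModules(exprsMatrix(sim2$experiment), part2, cutoff = 0.29)
  expect_equal(moduleSizes(merged2), moduleSizes(part2))
})

test_that("module-trait regression finds planted associations and handles degenerate traits", {
  cfg <- smallConfig(seed = 61, nGenes = 400L, nDEGenes = 0L,
                     nSubjects = c(AC = 5L, BET = 10L, BER = 15L),
                     moduleSizes = c(80L, 80L, 80L))
  sim <- simulateExpression(cfg)
  ex <- exprsMatrix(sim$experiment)
  part <- modulePartition(sim$truth$module_assignment)
  me <- moduleEigengenes(ex, part)

  # trait equal to an eigengene: slope 1, p ~ 0
  tr <- data.frame(self = me[1, ], noise = rnorm(ncol(me)),
                   flat = rep(1, ncol(me)))
  rownames(tr) <- colnames(me)
  expect_warning(res <- moduleTraitAssociation(me, tr), "constant trait")
  self1 <- res[res$module == 1 & res$trait == "self", ]
  expect_equal(self1$slope, 1, tolerance = 1e-8)
  expect_lt(self1$p_value, 1e-20)
  expect_true(all(res$p_value[res$trait == "flat"] == 1))

  # planted: trait built from module 1's latent factor tops the table
  set.seed(101)
  planted <- 2 * sim$truth$latent_factors[1, ] + rnorm(ncol(me), sd = 0.5)
  tr2 <- data.frame(cyto = planted, n1 = rnorm(ncol(me)),
                    n2 = rnorm(ncol(me)))
  rownames(tr2) <- colnames(me)
  res2 <- moduleTraitAssociation(me, tr2)
  top <- res2[which.min(res2$p_value), ]
  expect_equal(top$module, 1L)
  expect_equal(top$trait, "cyto")
})

test_that("eigengene deltas align EW minus M per subject", {
  me <- matrix(1:8, 2, 4,
               dimnames = list(c("1", "2"),
                               c("S1_EW", "S1_M", "S2_EW", "S2_M")))
  samples <- data.frame(sample_id = colnames(me),
                        subject_id = rep(c("S1", "S2"), each = 2),
                        stimulation = rep(c("EW", "M"), 2))
  d <- eigengeneDeltas(me, samples)
  expect_equal(dim(d), c(2L, 2L))
  expect_equal(unname(d[, "S1"]), c(1 - 3, 2 - 4))
})
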