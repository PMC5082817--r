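test_that("detection filter keeps probes at or above the 20% boundary", {
  m <- matrix(rnorm(100 * 10, 8), 100, 10,
              dimnames = list(sprintf("p%03d", 1:100), paste0("s", 1:10)))
  det <- matrix(TRUE, 100, 10, dimnames = dimnames(m))
  det["p001", ] <- FALSE                       # 0/10 detected
  det["p002", ] <- c(TRUE, TRUE, rep(FALSE, 8)) # exactly 2/10 = boundary
  det["p003", ] <- c(TRUE, rep(FALSE, 9))       # 1/10, below
  out <- filterProbesByDetection(m, det)
  expect_false("p001" %in% rownames(out))
  expect_true("p002" %in% rownames(out))
  expect_false("p003" %in% rownames(out))
  expect_equal(nrow(filterProbesByDetection(m, matrix(TRUE, 100, 10))), 100)
  expect_error(filterProbesByDetection(m, det[, 1:5]), "conformal")
})

test_that("probe collapse keeps the highest-mean probe per gene with a stable tie rule", {
  m <- rbind(pA = rep(5.0, 4), pB = rep(7.2, 4),
             pC = rep(6.0, 4), pZ = rep(6.0, 4), pLone = rep(3.0, 4))
  colnames(m) <- paste0("s", 1:4)
  map <- c(pA = "G1", pB = "G1", pC = "G2", pZ = "G2", pLone = "G3",
           pUnseen = "G4")
  out <- collapseProbesToGenes(m, map)
  expect_equal(rownames(out), c("G1", "G2", "G3"))
  expect_equal(unname(out["G1", 1]), 7.2)        # max-mean rule
  expect_equal(unname(out["G2", 1]), 6.0)        # tie -> pC (lexicographic)
  expect_equal(unname(out["G3", 1]), 3.0)        # single probe passes through
  expect_message(collapseProbesToGenes(m, map[c("pA", "pB")]),
                 "unmapped probe")
})

test_that("Benjamini-Hochberg adjustment matches hand-computed step-up values", {
  expect_equal(benjaminiHochberg(0.01), 0.01)
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_identical(benjaminiHochberg(numeric()), numeric())
  p <- sort(runif(50))
  expect_true(all(diff(benjaminiHochberg(p)) >= 0))
  expect_error(benjaminiHochberg(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("difference-of-differences on an exact toy recovers log2FC = 1", {
  ex <- toyPairedExperiment(list(AC = c(0, 0, 0, 0), BER = c(1, 1, 1, 1)))
  deg <- fitContrast(ex, contrastSpec("difference_of_differences",
                                      "BER", "AC"))
  expect_equal(deg$log2FC, 1)
  expect_equal(deg$contrast_id, "dd_BERvsAC")
})

test_that("within-group fit reproduces the hand-computed paired t statistic", {
  deltas <- c(0.8, 1.3, 0.2, 1.9, 0.6)
  ex <- toyPairedExperiment(list(BER = deltas))
  deg <- fitContrast(ex, contrastSpec("within_group_EW_vs_M", "BER"))
  tHand <- mean(deltas) / (sd(deltas) / sqrt(length(deltas)))
  expect_equal(deg$t, tHand, tolerance = 1e-12)
  expect_equal(deg$log2FC, mean(deltas), tolerance = 1e-12)
  expect_equal(deg$p_value, 2 * pt(-abs(tHand), length(deltas) - 1),
               tolerance = 1e-12)
})

test_that("between-group fit agrees with limma's ordinary statistics", {
  skip_if_not_installed("limma")
  sim <- simulateExpression(smallConfig(seed = 31, nGenes = 200L))
  ct <- contrastSpec("between_group_within_condition", "BER", "AC", "EW")
  deg <- fitContrast(sim$experiment, ct)

  md <- sampleData(sim$experiment)
  sel <- md$stimulation == "EW" & md$group %in% c("AC", "BER")
  y <- exprsMatrix(sim$experiment)[, md$sample_id[sel]]
  info <- md[sel, ]
  design <- model.matrix(~ factor(group, c("AC", "BER")) + gender + batch,
                         info)
  fit <- limma::lmFit(y, design)
  ord <- match(deg$gene_id, rownames(y))
  expect_equal(deg$log2FC, unname(fit$coefficients[ord, 2]),
               tolerance = 1e-10)
  tOrd <- fit$coefficients[ord, 2] /
    (fit$stdev.unscaled[ord, 2] * fit$sigma[ord])
  expect_equal(deg$t, unname(tOrd), tolerance = 1e-10)
})

test_that("aliased covariates are dropped with a warning", {
  set.seed(1)
  subj <- sprintf("S%02d", 1:12)
  groups <- rep(c("AC", "BER"), each = 6)
  samples <- data.frame(
    sample_id = paste0(rep(subj, each = 2), "_", c("EW", "M")),
    subject_id = rep(subj, each = 2),
    group = rep(groups, each = 2),
    stimulation = rep(c("EW", "M"), 12),
    gender = rep(c("F", "M"), 12),
    batch = rep(ifelse(groups == "AC", "B1", "B2"), each = 2))
  m <- matrix(rnorm(5 * 24, 8), 5, 24,
              dimnames = list(paste0("G", 1:5), samples$sample_id))
  ex <- StimExperiment(m, samples)
  expect_warning(
    fitContrast(ex, contrastSpec("difference_of_differences", "BER", "AC")),
    "aliased")
})

test_that("signature standardization applies the two-stage 500/200 rule", {
  set.seed(42)
  n <- 1200
  deg <- data.frame(
    gene_id = sprintf("G%04d", 1:n),
    log2FC = c(runif(1000, 0.1, 3), -runif(200, 0.1, 3)),
    p_value = sample(seq(1e-6, 0.9, length.out = n)),
    contrast_id = "toy", stringsAsFactors = FALSE)
  deg$fdr_p <- benjaminiHochberg(deg$p_value)

  up <- standardizeSignature(deg, "up")
  expect_length(signatureGenes(up), 200)
  # top 200 |FC| drawn only from the 500 smallest up-gene p-values
  upDeg <- deg[deg$log2FC > 0, ]
  top500 <- upDeg$gene_id[order(upDeg$p_value)][1:500]
  expect_true(all(signatureGenes(up) %in% top500))
  # the gene ranked 501 by p is excluded even with the largest |FC|
  rank501 <- upDeg$gene_id[order(upDeg$p_value)][501]
  deg2 <- deg
  deg2$log2FC[deg2$gene_id == rank501] <- 99
  expect_false(rank501 %in%
                 signatureGenes(standardizeSignature(deg2, "up")))
  # ordering is by |log2FC| descending
  fc <- deg$log2FC[match(signatureGenes(up), deg$gene_id)]
  expect_true(all(diff(abs(fc)) <= 0))

  down <- standardizeSignature(deg, "down")
  expect_length(signatureGenes(down), 200)
  expect_true(all(deg$log2FC[match(signatureGenes(down), deg$gene_id)] < 0))

  # fewer genes than the cap: truncation returns everything in the direction
  small <- deg[c(which(deg$log2FC > 0)[1:150], which(deg$log2FC < 0)), ]
  expect_length(signatureGenes(standardizeSignature(small, "up")), 150)

  # invariance to input row order
  shuffled <- deg[sample(nrow(deg)), ]
  expect_identical(signatureGenes(standardizeSignature(shuffled, "up")),
                   signatureGenes(up))
})

test_that("genes with log2FC exactly zero join neither direction", {
  deg <- data.frame(gene_id = c("A", "B", "C"),
                    log2FC = c(0, 1, -1),
                    p_value = c(1e-6, 0.01, 0.01),
                    contrast_id = "toy")
  expect_identical(signatureGenes(standardizeSignature(deg, "up")), "B")
  expect_identical(signatureGenes(standardizeSignature(deg, "down")), "C")
})

test_that("null simulations give calibrated type-I error", {
  fracs <- vapply(1:10, function(s) {
    sim <- simulateExpression(smallConfig(
      seed = 100 + s, nGenes = 400L, deLog2FC = 0, moduleSizes = integer()))
    deg <- fitContrast(sim$experiment,
                       contrastSpec("difference_of_differences", "BER", "AC"))
    mean(deg$p_value < 0.05)
  }, numeric(1))
  expect_gte(mean(fracs), 0.03)
  expect_lte(mean(fracs), 0.07)
})
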