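test_that("the score formula matches the published arithmetic", {
  expect_identical(immuneAnnotationScore(0.01, 0.01), 4)
  expect_identical(immuneAnnotationScore(1e-3, 1e-2), 6)
  expect_identical(immuneAnnotationScore(1, 1e-8), 0)
  expect_identical(immuneAnnotationScore(1e-8, 1), 0)
  expect_warning(s <- immuneAnnotationScore(0, 0.01), "clamped")
  expect_gt(s, 100)

  # strictly decreasing in each argument on (0,1)
  ps <- c(0.9, 0.5, 0.1, 0.01, 1e-4)
  expect_true(all(diff(immuneAnnotationScore(ps, 0.05)) > 0))
  expect_true(all(diff(immuneAnnotationScore(0.05, ps)) > 0))
})

test_that("category test equals the hypergeometric oracle and degenerates to p = 1", {
  sigs <- sprintf("SIG%04d", 1:1000)
  map <- annotationMap(data.frame(
    level = 1L, signature = sigs,
    category = rep(sprintf("K%03d", 1:100), each = 10)))
  enriched <- c(sigs[1:10], sigs[101:190])  # all of K001 + 90 others
  ct <- categoryTest("K001", enriched, map, 1L)
  expect_equal(ct$p_value, hyperTailOracle(10, 10, 100, 1000),
               tolerance = 1e-12)

  # category holding exactly its proportional share is not enriched
  propEnr <- sigs[seq(1, 1000, by = 10)]  # 1 of each category's 10
  ctProp <- categoryTest("K002", propEnr, map, 1L)
  expect_gte(ctProp$p_value, 0.5)

  # enriched set = all signatures: no discrimination possible
  ctAll <- categoryTest("K003", sigs, map, 1L)
  expect_equal(ctAll$p_value, 1)

  expect_error(categoryTest("missing", enriched, map, 1L), "absent")
})

test_that("first-stage gate behaves at the threshold extremes", {
  study <- simulateStudy(smallConfig(seed = 41))
  deg <- fitContrast(study$experiment,
                     contrastSpec("difference_of_differences", "BER", "AC"))
  sig <- standardizeSignature(deg, "up")
  u <- rownames(study$experiment)
  all <- firstStageEnrichment(sig, study$collection, study$annotation, 1L,
                              u, fdrThreshold = 1.0)
  expect_equal(nrow(all$enriched), nrow(all$results))
  none <- firstStageEnrichment(sig, study$collection, study$annotation, 1L,
                               u, fdrThreshold = 1e-300)
  expect_equal(nrow(none$enriched), 0L)
  emptyTab <- runAnnotationLevel(sig, study$collection, study$annotation, 1L,
                                 u, fdrThreshold = 1e-300)
  expect_equal(nrow(emptyTab), 0L)
})

test_that("a level run reports only categories with enriched signatures, sorted by score", {
  study <- simulateStudy(smallConfig(seed = 43))
  deg <- fitContrast(study$experiment,
                     contrastSpec("difference_of_differences", "BER", "AC"))
  sig <- standardizeSignature(deg, "up")
  u <- rownames(study$experiment)
  tab <- runAnnotationLevel(sig, study$collection, study$annotation, 1L, u)
  expect_true(all(tab$n_enriched >= 1L))
  expect_true(all(diff(tab$score) <= 0))
  expect_equal(tab$score,
               (-log10(tab$median_fdr_p)) * (-log10(tab$category_p)))
  expect_equal(tab$category[1], "C01")
  # deterministic
  tab2 <- runAnnotationLevel(sig, study$collection, study$annotation, 1L, u)
  expect_identical(tab, tab2)
})

test_that("one category holding every signature scores zero", {
  u <- sprintf("g%04d", 1:800)
  set.seed(5)
  query <- sample(u, 100)
  sets <- lapply(1:12, function(i)
    c(sample(query, 40), sample(setdiff(u, query), 20)))
  names(sets) <- sprintf("SIG%02d", 1:12)
  map <- annotationMap(data.frame(level = 1L, signature = names(sets),
                                  category = "ALL"))
  tab <- runAnnotationLevel(query, geneSets(sets), map, 1L, u)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$category_p, 1)
  expect_equal(tab$score, 0)
})

test_that("null queries rarely produce a category score above 2", {
  # equal enrichment rate everywhere (here: none) calibrates the score-over-2
  # significance reading
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    u <- sprintf("g%04d", 1:2000)
    query <- sample(u, 200)
    sets <- lapply(1:60, function(i) sample(u, 60))
    names(sets) <- sprintf("SIG%03d", 1:60)
    map <- annotationMap(data.frame(level = 1L, signature = names(sets),
                                    category = rep(sprintf("K%02d", 1:12),
                                                   each = 5)))
    tab <- runAnnotationLevel(query, geneSets(sets), map, 1L, u)
    mx <- if (nrow(tab)) max(tab$score) else 0
    if (mx < 2) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("annotation levels restrict the signature universe", {
  study <- simulateStudy(smallConfig(seed = 47))
  u <- rownames(study$experiment)
  map <- study$annotation
  # drop half the signatures from level 2's map
  a <- map@assignments
  keep <- a$level != 2L | seq_len(nrow(a)) %% 2L == 0L
  map2 <- annotationMap(a[keep, ])
  deg <- fitContrast(study$experiment,
                     contrastSpec("difference_of_differences", "BER", "AC"))
  sig <- standardizeSignature(deg, "up")
  st <- firstStageEnrichment(sig, study$collection, map2, 2L, u)
  expect_true(all(st$results$set_name %in%
                    names(levelAssignments(map2, 2L))))
  expect_lt(nrow(st$results), nSets(study$collection))
})
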