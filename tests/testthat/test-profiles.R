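test_that("hit filtering applies strict inequalities per threshold set", {
  hits <- data.frame(
    read_id = sprintf("r%d", 1:4), sample_id = "S01",
    feature_id = c("A", "A", "B", "B"),
    identity_pct = c(70, 70, 65, 90),
    coverage_pct = c(80, 85, 95, 95),
    alignment_length = c(100, 200, 300, 75),
    stringsAsFactors = FALSE)
  taxa <- abundanceValues(filterHits(hits, taxaHitThresholds()))
  expect_equal(taxa["A", "S01"], 2)   # both A rows exceed 65/70/75
  expect_equal(taxa["B", "S01"], 0)   # identity at 65 / alen at 75: strict
  fun <- abundanceValues(filterHits(hits, functionalHitThresholds()))
  expect_equal(fun["A", "S01"], 0)    # coverage 80/85 does not exceed 90
  expect_equal(fun["B", "S01"], 1)    # no length filter for functional hits
  expect_error(filterHits(hits[, -4], taxaHitThresholds()), "identity_pct")
  expect_error(hitThresholds(0, 70), "minIdentity")
})

test_that("normalisation divides by whole-metagenome totals", {
  counts <- makeTable(rbind(a = c(500, 30), b = c(0, 0)))
  totals <- c(S01 = 10000, S02 = 1000)
  norm <- normalizeAbundance(counts, totals)
  expect_identical(tableState(norm), "normalized")
  expect_equal(abundanceValues(norm)["a", ], c(S01 = 0.05, S02 = 0.03))
  expect_equal(unname(abundanceValues(norm)["b", ]), c(0, 0))
  # scale invariance: doubling counts and totals changes nothing
  norm2 <- normalizeAbundance(makeTable(rbind(a = c(1000, 60), b = c(0, 0))),
                              2 * totals)
  expect_equal(abundanceValues(norm2), abundanceValues(norm))
  expect_error(normalizeAbundance(counts, c(S01 = 0, S02 = 1000)), "positive")
  expect_error(normalizeAbundance(norm, totals), "counts-state")
  # column sums never exceed 1 on valid inputs
  co <- generateCohort(syntheticConfig(seed = 31L))
  for (ft in co@functionalTables)
    expect_true(all(colSums(abundanceValues(
      normalizeAbundance(ft, co@metadata))) <= 1 + 1e-12))
})

test_that("rank normalisation assigns ascending average ranks within rows", {
  norm <- makeTable(rbind(a = c(10, 20, 30), b = c(5, 5, 10),
                          c = c(7, 7, 7)), state = "normalized")
  ranked <- rankNormalize(norm)
  expect_identical(tableState(ranked), "ranked")
  v <- abundanceValues(ranked)
  expect_equal(unname(v["a", ]), c(1, 2, 3))
  expect_equal(unname(v["b", ]), c(1.5, 1.5, 3))
  expect_equal(unname(v["c", ]), c(2, 2, 2))
  # invariance under strictly monotone per-row transforms
  set.seed(4)
  x <- matrix(runif(60), nrow = 5)
  r1 <- abundanceValues(rankNormalize(makeTable(x, state = "normalized")))
  r2 <- abundanceValues(rankNormalize(makeTable(exp(3 * x),
                                                state = "normalized")))
  expect_equal(r1, r2)
  expect_error(rankNormalize(makeTable(x)), "normalized-state")
})

test_that("core features require > 0.01 abundance in at least half the samples", {
  norm <- makeTable(rbind(core2of3 = c(0.02, 0.02, 0.0),
                          rare = c(0.005, 0.005, 0.005),
                          boundary = c(0.01, 0.01, 0.01),
                          high = c(0.5, 0.4, 0.3)),
                    state = "normalized")
  expect_setequal(coreFeatures(norm), c("core2of3", "high"))
  # prevalence is a ceiling: 3 samples at 50% needs 2
  expect_setequal(coreFeatures(norm, minPrevalence = 1), "high")
  expect_error(coreFeatures(makeTable(matrix(1, 1, 3))), "normalized-state")
})

test_that("pattern clustering groups features by rank-correlation distance", {
  up <- seq(1, 20)
  down <- rev(up)
  set.seed(9)
  tab <- makeTable(rbind(u1 = up, u2 = up + 0.01 * runif(20),
                         d1 = down, d2 = down + 0.01 * runif(20)),
                   state = "normalized")
  ranked <- rankNormalize(tab)
  groups <- clusterAbundancePatterns(ranked, 2)
  labs <- groupLabels(groups)
  expect_identical(labs[["u1"]], labs[["u2"]])
  expect_identical(labs[["d1"]], labs[["d2"]])
  expect_false(labs[["u1"]] == labs[["d1"]])
  # as many groups as features: singletons
  singl <- clusterAbundancePatterns(ranked, 4)
  expect_identical(length(unique(groupLabels(singl))), 4L)
  expect_error(clusterAbundancePatterns(ranked, 5), "exceeds")

  # planted 4-group structure is recovered exactly
  set.seed(11)
  centers <- matrix(rnorm(4 * 30), nrow = 4)
  rows <- lapply(1:20, function(i)
    10 + centers[(i - 1) %/% 5 + 1, ] + rnorm(30, 0, 0.01))
  planted <- makeTable(do.call(rbind, rows), state = "normalized")
  got <- groupLabels(clusterAbundancePatterns(rankNormalize(planted), 4))
  truth <- rep(1:4, each = 5)
  # perfect agreement up to label permutation
  expect_identical(length(unique(paste(got, truth))), 4L)
  # clustering is invariant to row scaling (rank distance)
  scaled <- makeTable(do.call(rbind, rows) * 100, state = "normalized")
  got2 <- groupLabels(clusterAbundancePatterns(rankNormalize(scaled), 4))
  expect_identical(got, got2)
})

test_that("group cumulative abundance pools member rows", {
  tab <- makeTable(rbind(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)),
                   state = "normalized")
  groups <- clusterAbundancePatterns(tab, 2)
  labs <- groupLabels(groups)
  one <- names(labs)[labs == labs[["c"]]]
  if (length(one) == 1L)
    expect_equal(unname(groupCumulativeAbundance(tab, groups, labs[["c"]])),
                 unname(abundanceValues(tab)[one, ]))
  expect_equal(
    unname(groupCumulativeAbundance(tab, groups, unique(labs))),
    unname(colSums(abundanceValues(tab))))
  expect_error(groupCumulativeAbundance(tab, groups, integer()), "at least one")
  expect_error(groupCumulativeAbundance(tab, groups, 99L), "unknown group")
})

test_that("feature tables round-trip through TSV and validate their state", {
  co <- generateCohort(syntheticConfig(seed = 13L))
  norm <- normalizeAbundance(co@genusCounts, co@metadata)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeFeatureTable(norm, path)
  back <- readFeatureTable(path, kind = "taxon-genus", state = "normalized")
  expect_equal(abundanceValues(back), abundanceValues(norm),
               tolerance = 1e-12)
  expect_error(FeatureTable(matrix(-1, 2, 2,
                                   dimnames = list(c("a", "b"), c("x", "y"))),
                            kind = "taxon-genus"),
               "non-negative")
  expect_error(FeatureTable(matrix(5, 2, 2,
                                   dimnames = list(c("a", "b"), c("x", "y"))),
                            kind = "taxon-genus", state = "ranked"),
               "average ranks")
})
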