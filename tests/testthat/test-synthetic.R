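test_that("cohort generation is deterministic for a fixed seed", {
  a <- generateCohort(syntheticConfig(seed = 7L))
  b <- generateCohort(syntheticConfig(seed = 7L))
  expect_identical(abundanceValues(a@genusCounts),
                   abundanceValues(b@genusCounts))
  expect_identical(a@metadata, b@metadata)
  expect_identical(lapply(a@functionalTables, abundanceValues),
                   lapply(b@functionalTables, abundanceValues))
  expect_identical(a@truth, b@truth)
  c <- generateCohort(syntheticConfig(seed = 8L))
  expect_false(identical(abundanceValues(a@genusCounts),
                         abundanceValues(c@genusCounts)))
})

test_that("generated counts close exactly to the drawn library sizes", {
  co <- generateCohort(syntheticConfig(seed = 3L))
  counts <- abundanceValues(co@genusCounts)
  expect_identical(unname(colSums(counts)),
                   as.numeric(co@metadata$total_reads))
  norm <- normalizeAbundance(co@genusCounts, co@metadata)
  expect_equal(unname(colSums(abundanceValues(norm))), rep(1, ncol(counts)),
               tolerance = 1e-12)
  # functional tables are assigned-read subsets of the metagenome
  for (ft in co@functionalTables) {
    fn <- normalizeAbundance(ft, co@metadata)
    expect_true(all(colSums(abundanceValues(fn)) <= 1))
  }
})

test_that("truth covers every planted feature and the index span is honoured", {
  cfg <- syntheticConfig(seed = 5L)
  co <- generateCohort(cfg)
  expect_setequal(
    co@truth$feature[co@truth$table == "taxon-genus"],
    featureIds(co@genusCounts))
  for (kind in names(co@functionalTables))
    expect_setequal(co@truth$feature[co@truth$table == kind],
                    featureIds(co@functionalTables[[kind]]))
  expect_true(all(co@metadata$cumulative_index >= cfg@indexRange[1L]))
  expect_true(all(co@metadata$cumulative_index <= cfg@indexRange[2L]))
  expect_identical(co@metadata$cumulative_index,
                   co@metadata$z1 + co@metadata$z2 + co@metadata$z3)
})

test_that("invalid configurations are rejected", {
  expect_error(syntheticConfig(nSamples = 3L), "nSamples")
  expect_error(syntheticConfig(effectSize = -1), "effectSize")
  expect_error(syntheticConfig(dominantFraction = 1.2), "dominantFraction")
  expect_error(syntheticConfig(librarySizeRange = c(0, 10)), "librarySizeRange")
  expect_error(syntheticConfig(indexRange = c(-1, -5)), "indexRange")
})

test_that("anthropometrics invert the LMS transform exactly", {
  ref <- toyGrowthReference()
  # target Z = 0 on all axes: measurements sit on the reference medians
  sk0 <- data.frame(sample_id = "Z0", sex = "F", z1 = 0, z2 = 0, z3 = 0,
                    stringsAsFactors = FALSE)
  md0 <- generateAnthropometrics(sk0, ref)
  p <- lookupLMS(ref, "F", "height-for-age", md0$age_months)
  expect_equal(md0$height_cm, unname(p["M"]), tolerance = 1e-6)
  scored0 <- computeZScores(md0, ref)
  expect_equal(scored0$z1 + scored0$z2 + scored0$z3, 0, tolerance = 1e-9)

  # round-trip across cohorts: recovered Z equals planted Z to 1e-9
  for (s in c(21L, 22L)) {
    co <- generateCohort(syntheticConfig(seed = s))
    md <- co@metadata
    scored <- computeZScores(md, ref)
    expect_lt(max(abs(scored$z1 - md$z1), abs(scored$z2 - md$z2),
                  abs(scored$z3 - md$z3)), 1e-9)
  }
  expect_error(
    generateAnthropometrics(
      data.frame(sample_id = "bad", sex = "M", z1 = 40, z2 = -40, z3 = 40),
      ref))
})

test_that("hit-table fixtures carry exact pass/fail truth", {
  co <- generateCohort(syntheticConfig(seed = 2L))
  hits <- generateHitTable(co, seed = 9L)
  truth <- attr(hits, "truth")
  expect_identical(nrow(hits), nrow(truth))

  taxa <- filterHits(hits, taxaHitThresholds(),
                     sampleIds = co@metadata$sample_id)
  expect_identical(sum(abundanceValues(taxa)), as.numeric(sum(truth$pass_taxa)))
  fun <- filterHits(hits, functionalHitThresholds(),
                    sampleIds = co@metadata$sample_id)
  expect_identical(sum(abundanceValues(fun)),
                   as.numeric(sum(truth$pass_functional)))

  # strata edge rows: boundary values fail both filters (strict >)
  b <- hits[hits$identity_pct == 65 & hits$coverage_pct == 70, ]
  expect_gt(nrow(b), 0)
  both <- filterHits(b, taxaHitThresholds())
  expect_identical(sum(abundanceValues(both)), 0)

  # same seed reproduces the same fixture
  expect_identical(generateHitTable(co, seed = 9L), hits)
})

test_that("a cohort round-trips through its on-disk TSV representation", {
  co <- generateCohort(syntheticConfig(seed = 4L))
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  md <- readMetadata(file.path(dir, "metadata.tsv"))
  expect_equal(md$cumulative_index, co@metadata$cumulative_index,
               tolerance = 1e-9)
  genus <- readFeatureTable(file.path(dir, "genus_counts.tsv"),
                            kind = "taxon-genus")
  expect_equal(abundanceValues(genus), abundanceValues(co@genusCounts))
})

test_that("null cohorts plant no structure: pooled Spearman p-values are uniform", {
  ps <- numeric()
  for (s in seq_len(87L)) {
    co <- generateCohort(syntheticConfig(effectSize = 0, hubCouplingSlope = 0,
                                         seed = 6000L + s))
    md <- co@metadata
    v <- abundanceValues(normalizeAbundance(co@genusCounts, md))
    ps <- c(ps, apply(v, 1L, function(row)
      suppressWarnings(cor.test(row, md$cumulative_index,
                                method = "spearman", exact = FALSE)$p.value)))
  }
  ps <- ps[!is.na(ps)]
  expect_gte(length(ps), 2000L)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
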