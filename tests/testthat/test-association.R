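test_that("spearmanRho matches hand values and the brute-force oracle", {
  expect_equal(spearmanRho(1:5, 5:1), -1)
  expect_equal(spearmanRho(c(1, 2, 3), c(2, 1, 3)), 0.5)
  # rank invariance: any strictly increasing transform gives rho = 1
  x <- c(0.2, 1.5, 3.1, 7.9, 8)
  expect_equal(spearmanRho(x, exp(x)), 1)
  expect_warning(r <- spearmanRho(c(1, 1, 1), 1:3), "constant")
  expect_true(is.na(r))
  expect_error(spearmanRho(1:2, 1:2), "length")
  set.seed(2)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    x <- sample(rnorm(n), n, replace = TRUE)  # allow ties
    y <- sample(rnorm(n), n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearmanRho(x, y), bruteSpearman(x, y), tolerance = 1e-12)
  }
})

test_that("arctanh power formula behaves at its anchors", {
  expect_equal(correlationPower(0, 20), 0.05)
  expect_equal(correlationPower(0, 20, alpha = 0.01), 0.01)
  expect_equal(correlationPower(0.8, 20), 0.995, tolerance = 5e-4)
  expect_identical(correlationPower(1, 10), 1)
  pw <- vapply(c(10, 20, 40, 80), function(n) correlationPower(0.5, n),
               numeric(1))
  expect_true(all(diff(pw) > 0))
})

test_that("BH adjustment reproduces the step-up oracle", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.37), 0.37)
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  set.seed(3)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bhFdr(p), bruteBH(p), tolerance = 1e-12)
  }
  # q >= p for the largest p; sorted q is monotone in sorted p
  p <- runif(30)
  q <- bhFdr(p)
  expect_gte(q[which.max(p)], max(p) - 1e-15)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(bhFdr(c(0.5, 1.2)))
})

test_that("group comparison matches hand formulas for every statistic", {
  # hand-checkable two-group anchors for the oracles themselves:
  # A = (1,2), B = (3,4) gives eta^2 = 4/5 and H = 2.4
  y <- c(1, 2, 3, 4); g <- factor(c("A", "A", "B", "B"))
  expect_equal(bruteEta2(y, g), 0.8)
  expect_equal(bruteKW(y, g), 2.4)

  set.seed(5)
  classes <- setNames(rep(c("AH", "BL", "SM"), times = c(8, 6, 6)),
                      sprintf("S%02d", 1:20))
  v <- matrix(rnorm(20 * 15), nrow = 15,
              dimnames = list(sprintf("f%02d", 1:15), names(classes)))
  v <- v - min(v)
  v[1, ] <- 1 + rep(c(0, 2, 6), times = c(8, 6, 6)) + rnorm(20, 0, 0.1)
  v[2, ] <- 0.7  # constant feature
  tab <- makeTable(v, state = "normalized")
  cmp <- groupCompare(tab, classes)
  g <- factor(classes)
  for (f in rownames(v)) {
    row <- cmp$tests[cmp$tests$feature_id == f, ]
    if (sd(v[f, ]) == 0) {
      expect_identical(row$anova_F, 0)
      expect_identical(row$eta_squared, 0)
      next
    }
    expect_equal(row$anova_F, bruteF(v[f, ], g), tolerance = 1e-10)
    expect_equal(row$kw_H, bruteKW(v[f, ], g), tolerance = 1e-10)
    expect_equal(row$eta_squared, bruteEta2(v[f, ], g), tolerance = 1e-10)
  }
  expect_equal(cmp$tests$anova_q, bruteBH(cmp$tests$anova_p),
               tolerance = 1e-12)
  expect_equal(cmp$tests$kw_q, bruteBH(cmp$tests$kw_p), tolerance = 1e-12)

  # Tukey-Kramer: q for the planted feature against the hand formula
  tk <- cmp$tukey[cmp$tukey$feature_id == "f01", ]
  ns <- table(g); msw <- NULL
  fit <- anova(aov(v[1, ] ~ g)); msw <- fit$`Mean Sq`[2]
  pair <- tk[tk$group_a == "AH" & tk$group_b == "SM", ]
  se <- sqrt(msw / 2 * (1 / ns[["AH"]] + 1 / ns[["SM"]]))
  expect_equal(pair$q_statistic,
               abs(mean(v[1, g == "AH"]) - mean(v[1, g == "SM"])) / se,
               tolerance = 1e-10)
  expect_true(pair$significant)  # planted 6-unit separation
  expect_error(groupCompare(tab, classes[classes != "SM"]))
})

test_that("PC/NC classification splits on the z threshold", {
  res <- data.frame(feature_id = c("a", "b", "c", "d"),
                    reboot_z = c(2.5, -2.5, 1.0, NA))
  sets <- classifyPcNc(res)
  expect_identical(sets$pc, "a")
  expect_identical(sets$nc, "b")
  expect_length(intersect(sets$pc, sets$nc), 0)
  wide <- classifyPcNc(res, zThreshold = 3)
  expect_length(wide$pc, 0)
})

test_that("category composition yields percentages closing to 100", {
  cmap <- c(f1 = "X", f2 = "X", f3 = "Y", f4 = "Y")
  comp <- categoryComposition(c("f1", "f2", "f3", "f4"), cmap)
  expect_equal(sort(comp$percent), c(50, 50))
  one <- categoryComposition(c("f1", "f2"), cmap)
  expect_equal(one$percent, 100)
  # planted 3:1 split
  comp31 <- categoryComposition(c("f1", "f2", "u1", "f3"),
                                c(f1 = "A", f2 = "A", f3 = "B", u1 = "A"))
  expect_equal(comp31$percent[comp31$category == "A"], 75)
  expect_equal(comp31$percent[comp31$category == "B"], 25)
  # unmapped features fall into "unknown"
  unk <- categoryComposition(c("f1", "zzz"), cmap)
  expect_true("unknown" %in% unk$category)
  expect_warning(empty <- categoryComposition(character(), cmap), "empty")
  expect_identical(nrow(empty), 0L)
  expect_equal(sum(comp$percent), 100)
})

test_that("ReBoot flags a duplicated feature as maximally significant", {
  set.seed(8)
  base <- runif(20, 0.01, 0.2)
  v <- rbind(a = base, b = base, c = runif(20, 0.01, 0.2),
             d = runif(20, 0.01, 0.2))
  v <- sweep(v, 2, colSums(v) * 2, "/")  # half-assigned composition
  tab <- makeTable(v, state = "normalized")
  r <- rebootSignificance("a", "b", tab, rebootParams(seed = 1L))
  expect_equal(r$rho, 1)
  expect_lt(r$p_value, 0.001)
  expect_gt(r$reboot_z, 0)
  # two-sided normal tail links z and p
  expect_equal(r$p_value, 2 * pnorm(-abs(r$reboot_z)))
})

test_that("ReBoot is deterministic for a fixed seed and rejects rank input", {
  co <- generateCohort(syntheticConfig(seed = 17L))
  norm <- normalizeAbundance(co@genusCounts, co@metadata)
  p <- rebootParams(200, 200, seed = 42L)
  r1 <- rebootSignificance("g1_taxon_01", "g4_taxon_01", norm, p)
  r2 <- rebootSignificance("g1_taxon_01", "g4_taxon_01", norm, p)
  expect_identical(r1, r2)
  expect_error(
    rebootSignificance("a", "b", rankNormalize(norm), p), "not ranks")
  expect_error(rebootSignificance(1:20, 1:20, norm, p), "composition")
  expect_error(rebootParams(5, 5), "10")
})

test_that("associateWithIndex recovers planted directions and excludes constants", {
  co <- generateCohort(syntheticConfig(nSamples = 40L, effectSize = 1,
                                       hubCouplingSlope = 0, seed = 19L))
  md <- co@metadata
  norm <- normalizeAbundance(co@genusCounts, md)
  res <- suppressWarnings(
    associateWithIndex(norm, md, rebootParams(200, 200, seed = 1L)))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1, na.rm = TRUE))
  expect_true(all(res$power >= 0 & res$power <= 1, na.rm = TRUE))
  # direction consistent with the sign of rho whenever significant
  sig <- res[res$direction != "none", ]
  expect_true(all(ifelse(sig$direction == "positive", sig$rho > 0,
                         sig$rho < 0)))
  g1 <- res[grepl("^g1_", res$feature_id), ]
  g4 <- res[grepl("^g4_", res$feature_id), ]
  expect_true(all(g1$rho > 0))
  expect_true(all(g4$rho < 0))
  # a constant feature is dropped with a warning
  v <- abundanceValues(norm)
  v <- rbind(v, flat = rep(0.001, ncol(v)))
  expect_warning(
    res2 <- associateWithIndex(makeTable(v, state = "normalized"),
                               md, rebootParams(100, 100, seed = 1L)),
    "constant")
  expect_false("flat" %in% res2$feature_id)
})
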