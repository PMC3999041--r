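## Feature-vs-index association with ReBoot significance and power,
## three-group comparisons, FDR control and PC/NC classification.

#' Spearman rank correlation
#'
#' Pearson correlation of average-tie ranks.  Constant inputs have no
#' defined rank correlation; `NA` is returned with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Power of a correlation test (Fisher arctanh approximation)
#'
#' Two-sided power of the test of `rho = 0` at level `alpha` for a true
#' correlation `rho` and sample size `n`, via the Fisher transform:
#' noncentrality `delta = atanh(|rho|) * sqrt(n - 3)`, power
#' `Phi(delta - z) + Phi(-delta - z)` with `z` the upper `alpha/2`
#' normal quantile.  `|rho| = 1` gives power 1 by convention.
#'
#' @param rho true correlation in \[-1, 1\].
#' @param n sample size (>= 4).
#' @param alpha test level.
#' @export
correlationPower <- function(rho, n, alpha = 0.05) {
  stopifnot(n >= 4, alpha > 0, alpha < 1, abs(rho) <= 1)
  if (abs(rho) == 1) return(1)
  delta <- atanh(abs(rho)) * sqrt(n - 3)
  zc <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(delta - zc) + stats::pnorm(-delta - zc)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, order-preserving with the input.
#'
#' @param p numeric p-values in \[0, 1\].
#' @export
bhFdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Correlate every feature with the nutritional index
#'
#' For each (non-constant) feature of a normalized table, computes the
#' Spearman correlation with the cumulative nutritional index, its ReBoot
#' z and p (see [rebootSignificance()]), the arctanh power at the
#' observed rho, and a direction call at level `alpha`.
#'
#' @param table a normalized-state [FeatureTable-class].
#' @param index named numeric vector of cumulative indices (names =
#'   sample ids) or a scored metadata data.frame.
#' @param params a [RebootParams-class]; its seed (when set) governs the
#'   whole scan.
#' @param alpha level for the direction call.
#' @return data.frame with one row per feature: `feature_id`, `rho`,
#'   `reboot_z`, `p_value`, `power`, `direction`.  Constant features are
#'   dropped with a warning.
#' @export
associateWithIndex <- function(table, index, params = rebootParams(),
                               alpha = 0.05) {
  stopifnot(methods::is(table, "FeatureTable"))
  if (tableState(table) == "ranked")
    stop("ReBoot needs the relative-abundance composition, not ranks; ",
         "pass the normalized-state table (Spearman rho is identical)")
  if (is.data.frame(index))
    index <- stats::setNames(index$cumulative_index, index$sample_id)
  index <- index[sampleIds(table)]
  if (anyNA(index)) stop("index missing for some samples")
  v <- abundanceValues(table)
  constant <- apply(v, 1L, function(r) stats::sd(r) == 0)
  if (any(constant))
    warning("excluding constant feature(s): ",
            paste(rownames(v)[constant], collapse = ", "))
  feats <- rownames(v)[!constant]
  n <- ncol(v)
  totals <- colSums(v)
  .withSeed(params@seed, function() {
    rows <- lapply(feats, function(f) {
      r <- .rebootRaw(v[f, ], TRUE, unname(index), FALSE, totals,
                      params@nPermutations, params@nBootstraps)
      data.frame(feature_id = f, rho = r$rho, reboot_z = r$reboot_z,
                 p_value = r$p_value,
                 power = correlationPower(r$rho, n, alpha),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$direction <- ifelse(out$p_value < alpha,
                            ifelse(out$rho > 0, "positive", "negative"),
                            "none")
    rownames(out) <- NULL
    out
  })
}

#' Compare feature abundances across the AH/BL/SM classes
#'
#' Per feature: one-way ANOVA (F, p), tie-corrected Kruskal-Wallis
#' (H, p), effect size `eta^2 = SS_between / SS_total`, and Tukey-Kramer
#' post-hoc q statistics for all class pairs with the unequal-n standard
#' error `sqrt(MS_within / 2 * (1/n_i + 1/n_j))`, judged against the
#' studentized-range quantile at family-wise level 0.05 with
#' `df = N - k`.  Benjamini-Hochberg q-values are computed across
#' features separately within the ANOVA and the Kruskal-Wallis families.
#'
#' All three classes must be present with at least 2 samples each.
#'
#' @param table a [FeatureTable-class] (normalized or ranked).
#' @param classes named character vector of class labels per sample, or a
#'   scored metadata data.frame (uses `nutrition_class`).
#' @return list with `tests` (per-feature data.frame: `feature_id`,
#'   `anova_F`, `anova_p`, `anova_q`, `kw_H`, `kw_p`, `kw_q`,
#'   `eta_squared`) and `tukey` (per feature x class pair).
#' @export
groupCompare <- function(table, classes) {
  stopifnot(methods::is(table, "FeatureTable"))
  if (is.data.frame(classes))
    classes <- stats::setNames(classes$nutrition_class, classes$sample_id)
  classes <- classes[sampleIds(table)]
  if (anyNA(classes)) stop("class labels missing for some samples")
  g <- factor(classes)
  if (nlevels(g) < 3L)
    stop("groupCompare needs all three classes present")
  sizes <- tabulate(g, nbins = nlevels(g))
  if (any(sizes < 2L))
    stop("every class needs >= 2 samples (",
         paste(levels(g)[sizes < 2L], collapse = ", "), " too small)")
  v <- abundanceValues(table)
  k <- nlevels(g); N <- length(g)
  qcrit <- stats::qtukey(0.95, nmeans = k, df = N - k)

  testRows <- list(); tukeyRows <- list(); skipped <- list()
  for (f in rownames(v)) {
    y <- v[f, ]
    sst <- sum((y - mean(y))^2)
    if (sst == 0) {
      testRows[[f]] <- data.frame(feature_id = f, anova_F = 0, anova_p = 1,
                                  kw_H = 0, kw_p = 1, eta_squared = 0,
                                  stringsAsFactors = FALSE)
      next
    }
    fit <- stats::aov(y ~ g)
    an <- stats::anova(fit)
    ssb <- an$`Sum Sq`[1L]
    msw <- an$`Mean Sq`[2L]
    kw <- suppressWarnings(stats::kruskal.test(y, g))
    testRows[[f]] <- data.frame(
      feature_id = f,
      anova_F = unname(an$`F value`[1L]), anova_p = unname(an$`Pr(>F)`[1L]),
      kw_H = unname(kw$statistic), kw_p = unname(kw$p.value),
      eta_squared = ssb / sst, stringsAsFactors = FALSE)
    means <- tapply(y, g, mean)
    ns <- tapply(y, g, length)
    pairs <- utils::combn(levels(g), 2L)
    qs <- apply(pairs, 2L, function(pr) {
      se <- sqrt(msw / 2 * (1 / ns[pr[1L]] + 1 / ns[pr[2L]]))
      if (se == 0) return(ifelse(means[pr[1L]] == means[pr[2L]], 0, Inf))
      abs(means[pr[1L]] - means[pr[2L]]) / se
    })
    tukeyRows[[f]] <- data.frame(
      feature_id = f, group_a = pairs[1L, ], group_b = pairs[2L, ],
      q_statistic = unname(qs), significant = unname(qs > qcrit),
      stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, testRows)
  rownames(tests) <- NULL
  tests$anova_q <- bhFdr(tests$anova_p)
  tests$kw_q <- bhFdr(tests$kw_p)
  tests <- tests[, c("feature_id", "anova_F", "anova_p", "anova_q",
                     "kw_H", "kw_p", "kw_q", "eta_squared")]
  tukey <- if (length(tukeyRows)) do.call(rbind, tukeyRows) else
    data.frame(feature_id = character(), group_a = character(),
               group_b = character(), q_statistic = numeric(),
               significant = logical())
  rownames(tukey) <- NULL
  list(tests = tests, tukey = tukey)
}

#' Split association results into PC and NC sets
#'
#' Positively correlated (PC) features have `reboot_z > zThreshold`;
#' negatively correlated (NC) features `reboot_z < -zThreshold`.  With
#' the default threshold 1.97 the two-sided normal p at the boundary is
#' just below 0.05.
#'
#' @param results data.frame from [associateWithIndex()] (needs
#'   `feature_id` and `reboot_z`).
#' @param zThreshold |z| cut-off.
#' @return list with character vectors `pc` and `nc` (disjoint).
#' @export
classifyPcNc <- function(results, zThreshold = 1.97) {
  stopifnot(all(c("feature_id", "reboot_z") %in% names(results)))
  list(pc = results$feature_id[!is.na(results$reboot_z) &
                                 results$reboot_z > zThreshold],
       nc = results$feature_id[!is.na(results$reboot_z) &
                                 results$reboot_z < -zThreshold])
}

#' Functional-category composition of a feature set
#'
#' Maps each feature to its higher-level category and tabulates the
#' percentage each category contributes (summing to 100 within the set).
#' Unmapped features fall into an `"unknown"` bucket.
#'
#' @param features character vector (e.g. the PC or NC set).
#' @param categoryMap named character vector, feature -> category.
#' @return data.frame with columns `category`, `n`, `percent`.
#' @export
categoryComposition <- function(features, categoryMap) {
  if (length(features) == 0L) {
    warning("empty feature set: no composition to report")
    return(data.frame(category = character(), n = integer(),
                      percent = numeric()))
  }
  cats <- categoryMap[features]
  cats[is.na(cats)] <- "unknown"
  tab <- sort(table(cats), decreasing = TRUE)
  data.frame(category = names(tab), n = as.integer(tab),
             percent = 100 * as.numeric(tab) / length(features),
             stringsAsFactors = FALSE)
}
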