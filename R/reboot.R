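## ReBoot: permutation-with-renormalisation null vs bootstrap confidence
## distribution for correlations on compositional data.
##
## Relative abundances are closed (they share a per-sample denominator),
## which induces spurious correlations that a naive permutation test
## misreads.  ReBoot scores an observed association by comparing a
## bootstrap distribution of the correlation (resampling samples with
## replacement) against a null in which the target feature's values are
## permuted across samples and the composition is renormalised to restore
## closure, so the null retains the compositional coupling.

#' ReBoot parameters
#'
#' @param nPermutations permutation-null draws.
#' @param nBootstraps bootstrap draws.
#' @param seed RNG seed (`NA` = use the current RNG stream).
#' @param zThreshold |z| cut-off used by [classifyPcNc()].
#' @return a [RebootParams-class].
#' @export
rebootParams <- function(nPermutations = 1000L, nBootstraps = 1000L,
                         seed = NA_integer_, zThreshold = 1.97) {
  methods::new("RebootParams",
               nPermutations = as.integer(nPermutations),
               nBootstraps = as.integer(nBootstraps),
               seed = as.integer(seed), zThreshold = zThreshold)
}

## Column-wise average-tie ranks via one global rank() call: columns are
## shifted onto disjoint value ranges, ranked jointly, and the per-column
## offset removed.  Ties only ever occur within a column, so average
## ranks are preserved.
.colRanks <- function(m) {
  n <- nrow(m); B <- ncol(m)
  if (B == 1L) return(matrix(rank(m[, 1L]), nrow = n))
  rng <- range(m)
  K <- (rng[2L] - rng[1L]) + 1
  r <- rank(m + rep(seq_len(B) - 1L, each = n) * K)
  matrix(r - (rep(seq_len(B), each = n) - 1L) * n, nrow = n)
}

## Spearman rho of each column of M against Y (matrix of matching
## dimensions, or a single vector).  Average-rank ties; returns NA for
## constant columns.
.colSpearman <- function(M, Y) {
  n <- nrow(M)
  RM <- .colRanks(M) - (n + 1) / 2
  if (is.matrix(Y)) {
    RY <- .colRanks(Y) - (n + 1) / 2
    num <- colSums(RM * RY)
    den <- sqrt(colSums(RM^2) * colSums(RY^2))
  } else {
    ry <- rank(Y) - (n + 1) / 2
    num <- colSums(RM * ry)
    den <- sqrt(colSums(RM^2) * sum(ry^2))
  }
  ifelse(den > 0, num / den, NA_real_)
}

## Run fn with a locally-seeded RNG stream, restoring the caller's stream.
.withSeed <- function(seed, fn) {
  if (is.na(seed)) return(fn())
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  fn()
}

.resolveRow <- function(x, composition) {
  if (is.character(x) && length(x) == 1L) {
    if (!x %in% featureIds(composition))
      stop(sprintf("feature '%s' not found in the composition table", x))
    list(values = abundanceValues(composition)[x, ], inComposition = TRUE)
  } else {
    list(values = as.numeric(x), inComposition = FALSE)
  }
}

#' ReBoot significance of a correlation
#'
#' Scores the Spearman correlation between `featureA` and
#' `featureB` (a second feature of the composition, or an external
#' covariate such as the cumulative nutritional index) against a
#' compositionality-aware null:
#'
#' 1. *bootstrap*: samples are resampled with replacement
#'    `nBootstraps` times and rho recomputed;
#' 2. *null*: the values of the permuted feature are shuffled across
#'    samples and every sample's composition renormalised to restore its
#'    original total, `nPermutations` times;
#' 3. `reboot_z = (mean(bootstrap) - mean(null)) / sd(null)`;
#' 4. two-sided p from the standard normal tail at `reboot_z`.
#'
#' @param featureA feature id in `composition` (or a numeric per-sample
#'   vector).  When both arguments are features, `featureA` is the
#'   permuted one.
#' @param featureB second feature id or numeric per-sample vector (e.g.
#'   the nutritional index, which is not part of the composition and is
#'   neither permuted nor renormalised).
#' @param composition a normalized-state [FeatureTable-class] supplying
#'   the per-sample closure totals.
#' @param params a [RebootParams-class]; a non-`NA` seed makes the result
#'   deterministic.
#' @return list with elements `rho`, `reboot_z`, `p_value`.
#' @export
rebootSignificance <- function(featureA, featureB, composition,
                               params = rebootParams()) {
  stopifnot(methods::is(composition, "FeatureTable"),
            methods::is(params, "RebootParams"))
  if (tableState(composition) == "ranked")
    stop("ReBoot needs the relative-abundance composition, not ranks; ",
         "pass the normalized-state table")
  a <- .resolveRow(featureA, composition)
  b <- .resolveRow(featureB, composition)
  if (length(a$values) != length(b$values))
    stop("featureA and featureB must have matching lengths")
  if (!a$inComposition && !b$inComposition)
    stop("at least one argument must be a feature of the composition")
  totals <- colSums(abundanceValues(composition))
  .withSeed(params@seed, function() {
    .rebootRaw(a$values, a$inComposition, b$values, b$inComposition,
               totals, params@nPermutations, params@nBootstraps)
  })
}

## core ReBoot computation on raw vectors (RNG state of the caller)
.rebootRaw <- function(aVals, aIn, bVals, bIn, totals, nPerm, nBoot) {
  n <- length(aVals)
  ## permute a if it lives in the composition, otherwise b
  if (aIn) { x <- aVals; y <- bVals; yIn <- bIn }
  else { x <- bVals; y <- aVals; yIn <- aIn }

  rho <- .colSpearman(matrix(aVals, ncol = 1L), bVals)
  if (is.na(rho)) {
    warning("constant input: correlation undefined")
    return(list(rho = NA_real_, reboot_z = NA_real_, p_value = NA_real_))
  }

  ## null: permute x, renormalise each sample's composition
  P <- matrix(0L, nrow = n, ncol = nPerm)
  for (k in seq_len(nPerm)) P[, k] <- sample.int(n)
  XP <- matrix(x[P], nrow = n)
  f <- totals / (totals - x + XP)             # renormalisation factors
  Xnull <- XP * f
  nullRho <- if (yIn) .colSpearman(Xnull, y * f) else .colSpearman(Xnull, y)

  ## bootstrap: resample samples with replacement
  I <- matrix(sample.int(n, n * nBoot, replace = TRUE), nrow = n)
  bootRho <- .colSpearman(matrix(aVals[I], nrow = n),
                          matrix(bVals[I], nrow = n))

  sdNull <- stats::sd(nullRho, na.rm = TRUE)
  if (!is.finite(sdNull) || sdNull == 0)
    stop("degenerate ReBoot null: permutation distribution has zero spread")
  z <- (mean(bootRho, na.rm = TRUE) - mean(nullRho, na.rm = TRUE)) / sdNull
  list(rho = unname(rho), reboot_z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}
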