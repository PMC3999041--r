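## Synthetic cohort generator.  Produces cohorts with the statistical
## structure the downstream analysis assumes — a nutritional-index
## gradient, planted gradient-positive (G1-like) and gradient-negative
## (G4-like) genera, a dominant Prevotella-like genus, compositional
## closure at realistic library sizes, and within-group co-occurrence
## hubs whose coupling strengthens as nutrition worsens — so that every
## stage of the pipeline is testable without external sequencing data.

#' Synthetic cohort configuration
#'
#' Defaults describe the cohort design the package targets: 20 samples spanning
#' cumulative indices -11.58..-2.18, five gradient-positive and five
#' gradient-negative genera, twelve neutral genera plus one dominant
#' genus (23 core-scale genera in total), library sizes of 100k-200k
#' synthetic reads, and hub coupling that grows linearly as the index
#' falls.
#'
#' @param nSamples samples to generate (>= 4).
#' @param indexRange (low, high) cumulative-index endpoints; indices are
#'   drawn uniformly over this range.
#' @param nG1Taxa,nG4Taxa,nNeutralTaxa planted taxon counts.
#' @param effectSize per-unit-index slope of latent log-abundance for
#'   gradient taxa (gradient-positive get `+effectSize`,
#'   gradient-negative `-effectSize`).
#' @param dominantFraction mean share of the dominant genus, in (0, 1).
#' @param hubCouplingSlope shared-factor loading per unit of
#'   `(index_high - index)`; 0 disables hub structure.
#' @param latentSd sd of latent log-abundance noise.
#' @param librarySizeRange (min, max) per-sample read totals.
#' @param overdispersion Dirichlet-multinomial overdispersion; the DM
#'   concentration is `library_size / overdispersion`.
#' @param seed RNG seed (`NA` = current stream).
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nSamples = 20L, indexRange = c(-11.58, -2.18),
                            nG1Taxa = 5L, nG4Taxa = 5L, nNeutralTaxa = 12L,
                            effectSize = 0.35, dominantFraction = 0.35,
                            hubCouplingSlope = 0.35, latentSd = 1,
                            librarySizeRange = c(1e5, 2e5),
                            overdispersion = 1, seed = NA_integer_) {
  methods::new("SyntheticConfig", nSamples = as.integer(nSamples),
               indexRange = as.numeric(indexRange),
               nG1Taxa = as.integer(nG1Taxa), nG4Taxa = as.integer(nG4Taxa),
               nNeutralTaxa = as.integer(nNeutralTaxa),
               effectSize = effectSize, dominantFraction = dominantFraction,
               hubCouplingSlope = hubCouplingSlope, latentSd = latentSd,
               librarySizeRange = as.numeric(librarySizeRange),
               overdispersion = overdispersion, seed = as.integer(seed))
}

#' Bundled synthetic growth reference
#'
#' A smooth, monotone LMS reference (both sexes, ages 0-120 months,
#' heights 55-140 cm) built in code for tests and synthetic cohorts.  It
#' is a synthetic stand-in, not WHO data: the three axes are mutually
#' consistent at the median (a child on the height-for-age median and the
#' weight-for-age median also sits on the weight-for-height median).
#'
#' @return a [GrowthReference-class].
#' @export
toyGrowthReference <- function() {
  ages <- seq(0, 120, by = 6)
  build <- function(sex, off) {
    hfa <- data.frame(sex = sex, axis = "height-for-age", key = ages,
                      L = 1, M = 65 + off + 0.55 * ages, S = 0.04)
    ## S shrinks with age so the weight-for-height Z implied by a
    ## (height-for-age, weight-for-age) target pair sweeps a wide range
    ## as age varies — this keeps the three-axis inversion solvable
    wfa <- data.frame(sex = sex, axis = "weight-for-age", key = ages,
                      L = 1, M = 7 + 0.18 * ages + off / 10,
                      S = 0.20 - 0.001 * ages)
    hkeys <- seq(55, 140, by = 5)
    wfh <- data.frame(sex = sex, axis = "weight-for-height", key = hkeys,
                      L = 0.9,
                      M = 7 + 0.18 * (hkeys - (65 + off)) / 0.55 + off / 10,
                      S = 0.09)
    rbind(hfa, wfa, wfh)
  }
  GrowthReference(rbind(build("M", 0), build("F", -1)))
}

#' Generate anthropometrics from target Z-scores
#'
#' Inverts the LMS transform so that [computeZScores()] recovers the
#' targets exactly.  A single (height, weight) pair cannot in general
#' satisfy three Z-score targets at a fixed age, so age is treated as the
#' free variable: for each sample the height implied by the
#' height-for-age target and the weight implied by the weight-for-age
#' target are functions of age, and the age at which that weight also
#' attains the weight-for-height target is found by root-finding over the
#' reference's age range.
#'
#' @param skeleton data.frame with columns `sample_id`, `sex` and target
#'   Z-scores `z1`, `z2`, `z3` (plus any extra columns, carried through).
#' @param reference a [GrowthReference-class] covering the implied keys.
#' @param seed unused reserved argument (the inversion is deterministic).
#' @return the skeleton with `age_months`, `height_cm`, `weight_kg`,
#'   `cumulative_index` and `nutrition_class` filled in.
#' @export
generateAnthropometrics <- function(skeleton, reference = toyGrowthReference(),
                                    seed = NA_integer_) {
  need <- c("sample_id", "sex", "z1", "z2", "z3")
  if (!all(need %in% names(skeleton)))
    stop("skeleton must have columns ", paste(need, collapse = ", "))
  t <- reference@table
  ## cache linear interpolators per (sex, axis) — the root search below
  ## evaluates the curves thousands of times
  curves <- lapply(split(t, list(t$sex, t$axis), drop = TRUE), function(rows)
    list(L = stats::approxfun(rows$key, rows$L),
         M = stats::approxfun(rows$key, rows$M),
         S = stats::approxfun(rows$key, rows$S),
         lo = min(rows$key), hi = max(rows$key)))
  out <- skeleton
  out$age_months <- out$height_cm <- out$weight_kg <- NA_real_
  for (i in seq_len(nrow(skeleton))) {
    sex <- skeleton$sex[i]
    hfa <- curves[[paste(sex, "height-for-age", sep = ".")]]
    wfa <- curves[[paste(sex, "weight-for-age", sep = ".")]]
    wfh <- curves[[paste(sex, "weight-for-height", sep = ".")]]
    if (is.null(hfa) || is.null(wfa) || is.null(wfh))
      stop("missing reference rows for sex ", sex)
    ageKeys <- c(hfa$lo, hfa$hi)
    hKeys <- c(wfh$lo, wfh$hi)
    heightAt <- function(a)
      lmsMeasurement(skeleton$z1[i], hfa$L(a), hfa$M(a), hfa$S(a))
    weightAt <- function(a)
      lmsMeasurement(skeleton$z2[i], wfa$L(a), wfa$M(a), wfa$S(a))
    gap <- function(a) {
      h <- heightAt(a)
      lmsZScore(weightAt(a), wfh$L(h), wfh$M(h), wfh$S(h)) -
        skeleton$z3[i]
    }
    ## search only ages whose implied height stays inside the
    ## weight-for-height key range
    grid <- seq(min(ageKeys), max(ageKeys), length.out = 241L)
    h <- vapply(grid, heightAt, numeric(1))
    grid <- grid[h >= min(hKeys) & h <= max(hKeys)]
    if (length(grid) < 2L)
      stop("targets for sample ", skeleton$sample_id[i],
           " leave no feasible age in the reference range")
    gv <- vapply(grid, function(a)
      tryCatch(gap(a), error = function(e) NA_real_), numeric(1))
    fin <- is.finite(gv)
    sc <- which(fin[-length(fin)] & fin[-1L] &
                  diff(sign(gv)) != 0 & !is.na(diff(sign(gv))))
    if (length(sc)) {
      age <- stats::uniroot(gap, lower = grid[sc[1L]],
                            upper = grid[sc[1L] + 1L],
                            tol = 1e-12)$root
    } else {
      ## no sign change on the grid: the root may be tangent (the gap
      ## touches zero at its minimum) — polish the best grid point
      best <- which.min(abs(gv))
      lo <- grid[max(1L, best - 1L)]
      hi <- grid[min(length(grid), best + 1L)]
      opt <- stats::optimize(function(a)
        abs(tryCatch(gap(a), error = function(e) Inf)),
        lower = lo, upper = hi, tol = 1e-12)
      if (!is.finite(opt$objective) || opt$objective > 1e-9)
        stop("cannot reconcile the three Z-score targets for sample ",
             skeleton$sample_id[i], " within the reference age range")
      age <- opt$minimum
    }
    out$age_months[i] <- age
    out$height_cm[i] <- heightAt(age)
    out$weight_kg[i] <- weightAt(age)
  }
  out$cumulative_index <- cumulativeIndex(out$z1, out$z2, out$z3)
  out$nutrition_class <- classifyNutrition(out$cumulative_index)
  out
}

## latent log-abundance block for one feature set; returns a proportions
## matrix (features x samples) closed to 1 per sample
.latentProportions <- function(featNames, slopes, hubOf, idx, indexHigh,
                               config, baseMean = NULL, baseSd = NULL) {
  n <- length(idx)
  idxc <- idx - mean(config@indexRange)
  if (is.null(baseMean)) baseMean <- rep(0, length(featNames))
  if (is.null(baseSd)) baseSd <- rep(1, length(featNames))
  base <- stats::rnorm(length(featNames), baseMean, baseSd)
  l <- outer(base, rep(1, n)) + outer(slopes, idxc)
  noise <- matrix(stats::rnorm(length(featNames) * n, 0, 1),
                  nrow = length(featNames))
  if (config@hubCouplingSlope > 0 && any(!is.na(hubOf))) {
    ## hub members share a per-sample latent factor.  The raw loading
    ## lambda = slope * (index_high - index) is normalised to
    ## lambda / sqrt(1 + lambda^2) with a matching residual scale, so the
    ## within-hub correlation is lambda^2 / (1 + lambda^2) while every
    ## taxon keeps unit marginal noise variance — otherwise the inflated
    ## E[exp(noise)] at low indices would push a systematic closure trend
    ## into the *neutral* taxa
    lam <- config@hubCouplingSlope * (indexHigh - idx)
    w <- lam / sqrt(1 + lam^2)
    for (h in unique(stats::na.omit(hubOf))) {
      fac <- stats::rnorm(n)
      members <- which(hubOf == h)
      m <- length(members)
      noise[members, ] <- rep(w * fac, each = m) +
        rep(sqrt(1 - w^2), each = m) * noise[members, , drop = FALSE]
    }
  }
  l <- l + config@latentSd * noise
  e <- exp(l)
  p <- sweep(e, 2L, colSums(e), "/")
  rownames(p) <- featNames
  p
}

## Two-tier closure of the non-dominant composition.  The planted
## (gradient/hub) block holds a fixed expected share of the whole
## (logit-normal noise around `plantedShare`), with softmax closure
## applied *within* the planted and neutral tiers separately.  A single
## softmax over all taxa would give the planted block a cosh-shaped
## total mass along the gradient and push a spurious V-shaped
## compositional trend into every neutral taxon; pinning the block share
## keeps neutral proportions genuinely index-free while leaving the
## within-block gradient and hub-coupling structure untouched.
.twoTierProportions <- function(plantedNames, plantedSlopes, plantedHubs,
                                neutralNames, idx, indexHigh, config,
                                plantedShare = 0.45) {
  n <- length(idx)
  if (length(plantedNames) == 0L) {
    return(.latentProportions(neutralNames, rep(0, length(neutralNames)),
                              rep(NA_character_, length(neutralNames)),
                              idx, indexHigh, config))
  }
  pPlanted <- .latentProportions(plantedNames, plantedSlopes, plantedHubs,
                                 idx, indexHigh, config,
                                 baseMean = rep(0, length(plantedNames)),
                                 baseSd = rep(0.3, length(plantedNames)))
  if (length(neutralNames) == 0L) return(pPlanted)
  pNeutral <- .latentProportions(neutralNames,
                                 rep(0, length(neutralNames)),
                                 rep(NA_character_, length(neutralNames)),
                                 idx, indexHigh, config)
  share <- stats::plogis(stats::qlogis(plantedShare) +
                           stats::rnorm(n, 0, 0.25))
  rbind(sweep(pPlanted, 2L, share, "*"),
        sweep(pNeutral, 2L, 1 - share, "*"))
}

## Dirichlet-multinomial draw of counts at the given library sizes
.dmCounts <- function(p, libSizes, overdispersion) {
  n <- ncol(p)
  counts <- vapply(seq_len(n), function(s) {
    conc <- libSizes[s] / overdispersion
    w <- stats::rgamma(nrow(p), shape = p[, s] * conc)
    if (sum(w) == 0) w <- p[, s]
    stats::rmultinom(1L, libSizes[s], w / sum(w))[, 1L]
  }, numeric(nrow(p)))
  dimnames(counts) <- dimnames(p)
  counts
}

#' Generate a synthetic cohort
#'
#' Draws cumulative nutritional indices uniformly over the configured
#' range, builds anthropometrics that reproduce them exactly (see
#' [generateAnthropometrics()]), and generates genus, COG-like,
#' CAZyme-like and virulence-factor-like count tables from latent
#' Gaussian log-abundances closed by exponentiate-and-normalise and
#' sampled with Dirichlet-multinomial noise.  Gradient-positive taxa have
#' latent slope `+effectSize` in the index, gradient-negative
#' `-effectSize`; the members of each planted hub share a latent factor
#' whose loading is `hubCouplingSlope * (index_high - index)`.  The
#' result is bit-identical for a fixed seed.
#'
#' @param config a [SyntheticConfig-class].
#' @return a [SyntheticCohort-class].
#' @export
generateCohort <- function(config = syntheticConfig()) {
  methods::validObject(config)
  .withSeed(config@seed, function() .generateCohortImpl(config))
}

.generateCohortImpl <- function(config) {
  n <- config@nSamples
  ids <- sprintf("S%02d", seq_len(n))
  idx <- stats::runif(n, config@indexRange[1L], config@indexRange[2L])
  indexHigh <- config@indexRange[2L]
  libRange <- round(config@librarySizeRange)
  libSizes <- libRange[1L] +
    sample.int(libRange[2L] - libRange[1L] + 1L, n, replace = TRUE) - 1L

  ## anthropometrics consistent with the drawn indices: draw sex, an age
  ## and the height-for-age target, then solve for the weight-for-age
  ## target at which the implied weight-for-height Z closes the triple to
  ## the drawn cumulative index — the three targets are then mutually
  ## reconcilable by construction and round-trip exactly
  ref <- toyGrowthReference()
  sex <- sample(c("M", "F"), n, replace = TRUE)
  age0 <- stats::runif(n, 6, 60)
  z1 <- idx / 3 + stats::rnorm(n, 0, 0.3)
  z2 <- vapply(seq_len(n), function(i) {
    pH <- lookupLMS(ref, sex[i], "height-for-age", age0[i])
    h <- lmsMeasurement(z1[i], pH["L"], pH["M"], pH["S"])
    pW <- lookupLMS(ref, sex[i], "weight-for-age", age0[i])
    pWH <- lookupLMS(ref, sex[i], "weight-for-height", h)
    g <- function(z) {
      w <- lmsMeasurement(z, pW["L"], pW["M"], pW["S"])
      z + lmsZScore(w, pWH["L"], pWH["M"], pWH["S"]) - (idx[i] - z1[i])
    }
    lo <- -1 / (pW["L"] * pW["S"]) + 1e-6
    stats::uniroot(g, lower = lo, upper = 6, tol = 1e-12)$root
  }, numeric(1))
  skeleton <- data.frame(
    sample_id = ids, sex = sex, z1 = z1, z2 = z2, z3 = idx - z1 - z2,
    stringsAsFactors = FALSE)
  metadata <- generateAnthropometrics(skeleton, ref)
  metadata$total_reads <- libSizes
  metadata <- metadata[, c("sample_id", "age_months", "sex", "height_cm",
                           "weight_kg", "z1", "z2", "z3",
                           "cumulative_index", "nutrition_class",
                           "total_reads")]

  ## genus table: dominant genus + planted gradient/neutral taxa
  g1 <- if (config@nG1Taxa) sprintf("g1_taxon_%02d", seq_len(config@nG1Taxa))
        else character()
  g4 <- if (config@nG4Taxa) sprintf("g4_taxon_%02d", seq_len(config@nG4Taxa))
        else character()
  neu <- if (config@nNeutralTaxa)
    sprintf("neutral_taxon_%02d", seq_len(config@nNeutralTaxa)) else character()
  feats <- c(g1, g4, neu)
  if (length(feats) < 2L)
    stop("need at least 2 non-dominant taxa")
  slopes <- c(rep(config@effectSize, length(g1)),
              rep(-config@effectSize, length(g4)), rep(0, length(neu)))
  hubOf <- c(rep(if (length(g1) >= 2L) "hub-G1" else NA_character_,
                 length(g1)),
             rep(if (length(g4) >= 2L) "hub-G4" else NA_character_,
                 length(g4)),
             rep(NA_character_, length(neu)))
  ## planted gradient taxa sit at core-genus abundance (the reference
  ## gradient groups are subsets of the core genera); neutral taxa span a
  ## wider abundance range
  nPlanted <- length(g1) + length(g4)
  pSub <- .twoTierProportions(
    plantedNames = c(g1, g4), plantedSlopes = slopes[seq_len(nPlanted)],
    plantedHubs = hubOf[seq_len(nPlanted)], neutralNames = neu,
    idx = idx, indexHigh = indexHigh, config = config)
  domShare <- stats::plogis(stats::qlogis(config@dominantFraction) +
                              stats::rnorm(n, 0, 0.25))
  p <- rbind(Prevotella_like = domShare,
             sweep(pSub, 2L, 1 - domShare, "*"))
  genusCounts <- .dmCounts(p, libSizes, config@overdispersion)
  colnames(genusCounts) <- ids
  genusTable <- FeatureTable(genusCounts, kind = "taxon-genus",
                             state = "counts")

  truth <- data.frame(
    table = "taxon-genus",
    feature = c("Prevotella_like", feats),
    role = c("dominant", rep("gradient-positive", length(g1)),
             rep("gradient-negative", length(g4)),
             rep("neutral", length(neu))),
    hub = c(NA_character_, hubOf), stringsAsFactors = FALSE)

  ## functional tables (assigned-read subsets of the metagenome)
  funKinds <- list(
    cog = list(nPos = 10L, nNeg = 10L, nNeut = 20L, frac = 0.5,
               slopeScale = 1),
    cazyme = list(nPos = 12L, nNeg = 0L, nNeut = 16L, frac = 0.2,
                  slopeScale = 0.5),
    vf = list(nPos = 0L, nNeg = 8L, nNeut = 7L, frac = 0.1,
              slopeScale = 0.5))
  functionalTables <- list()
  for (kind in names(funKinds)) {
    spec <- funKinds[[kind]]
    fn <- c(if (spec$nPos) sprintf("%s_pos_%02d", kind, seq_len(spec$nPos)),
            if (spec$nNeg) sprintf("%s_neg_%02d", kind, seq_len(spec$nNeg)),
            if (spec$nNeut) sprintf("%s_neutral_%02d", kind,
                                    seq_len(spec$nNeut)))
    nPl <- spec$nPos + spec$nNeg
    sl <- c(rep(config@effectSize * spec$slopeScale, spec$nPos),
            rep(-config@effectSize * spec$slopeScale, spec$nNeg))
    pf <- .twoTierProportions(
      plantedNames = fn[seq_len(nPl)], plantedSlopes = sl,
      plantedHubs = rep(NA_character_, nPl),
      neutralNames = fn[nPl + seq_len(spec$nNeut)],
      idx = idx, indexHigh = indexHigh, config = config,
      plantedShare = 0.4)
    assigned <- round(spec$frac * libSizes)
    cf <- .dmCounts(pf, assigned, config@overdispersion)
    colnames(cf) <- ids
    functionalTables[[kind]] <- FeatureTable(cf, kind = kind,
                                             state = "counts")
    truth <- rbind(truth, data.frame(
      table = kind, feature = fn,
      role = c(rep("gradient-positive", spec$nPos),
               rep("gradient-negative", spec$nNeg),
               rep("neutral", spec$nNeut)),
      hub = NA_character_, stringsAsFactors = FALSE))
  }

  categories <- c("carbohydrate transport and metabolism",
                  "amino acid transport and metabolism",
                  "energy production and conversion",
                  "lipid transport and metabolism",
                  "cell motility",
                  "intracellular trafficking and secretion",
                  "inorganic ion transport and metabolism",
                  "function unknown")
  cogFeats <- featureIds(functionalTables$cog)
  categoryMap <- stats::setNames(
    sample(categories, length(cogFeats), replace = TRUE), cogFeats)

  methods::new("SyntheticCohort", metadata = metadata,
               genusCounts = genusTable,
               functionalTables = functionalTables, truth = truth,
               categoryMap = categoryMap, config = config)
}

#' Generate a read-level hit-table fixture
#'
#' Emits read rows whose identity / coverage / alignment-length values
#' are drawn from designed strata straddling the filtering thresholds,
#' with the pass/fail truth of each stratum fixed at generation time:
#'
#' * `clear_pass` — passes the taxa (65/70/75) and functional (65/90)
#'   filters;
#' * `taxa_only` — coverage in (70, 90), passes taxa but not functional;
#' * `short_alignment` — alignment <= 75 bp, fails taxa, passes
#'   functional;
#' * `low_identity` — identity <= 65, fails both;
#' * `boundary` — values exactly at the thresholds, fails both (strict
#'   inequalities).
#'
#' @param cohort a [SyntheticCohort-class] providing sample and feature
#'   ids.
#' @param strataCounts named integer vector of rows per stratum.
#' @param seed RNG seed (`NA` = current stream).
#' @return data.frame with columns `read_id`, `sample_id`, `feature_id`,
#'   `identity_pct`, `coverage_pct`, `alignment_length`, and a `"truth"`
#'   attribute data.frame carrying per-row `pass_taxa` /
#'   `pass_functional` flags assigned from the strata.
#' @export
generateHitTable <- function(cohort,
                             strataCounts = c(clear_pass = 40L,
                                              taxa_only = 15L,
                                              short_alignment = 10L,
                                              low_identity = 20L,
                                              boundary = 5L),
                             seed = NA_integer_) {
  stopifnot(methods::is(cohort, "SyntheticCohort"))
  .withSeed(seed, function() {
    strata <- list(
      clear_pass = function(m) data.frame(
        identity_pct = stats::runif(m, 80, 99),
        coverage_pct = stats::runif(m, 91, 99),
        alignment_length = round(stats::runif(m, 100, 400)),
        pass_taxa = TRUE, pass_functional = TRUE),
      taxa_only = function(m) data.frame(
        identity_pct = stats::runif(m, 70, 99),
        coverage_pct = stats::runif(m, 71, 89),
        alignment_length = round(stats::runif(m, 100, 400)),
        pass_taxa = TRUE, pass_functional = FALSE),
      short_alignment = function(m) data.frame(
        identity_pct = stats::runif(m, 80, 99),
        coverage_pct = stats::runif(m, 91, 99),
        alignment_length = round(stats::runif(m, 30, 74)),
        pass_taxa = FALSE, pass_functional = TRUE),
      low_identity = function(m) data.frame(
        identity_pct = stats::runif(m, 30, 64),
        coverage_pct = stats::runif(m, 71, 99),
        alignment_length = round(stats::runif(m, 100, 400)),
        pass_taxa = FALSE, pass_functional = FALSE),
      boundary = function(m) data.frame(
        identity_pct = rep(65, m), coverage_pct = rep(70, m),
        alignment_length = rep(75, m),
        pass_taxa = FALSE, pass_functional = FALSE))
    used <- strataCounts[strataCounts > 0L]
    blocks <- lapply(names(used), function(s) strata[[s]](used[[s]]))
    rows <- do.call(rbind, blocks)
    m <- nrow(rows)
    samples <- sample(cohort@metadata$sample_id, m, replace = TRUE)
    features <- sample(featureIds(cohort@genusCounts), m, replace = TRUE)
    hits <- data.frame(read_id = sprintf("read_%05d", seq_len(m)),
                       sample_id = samples, feature_id = features,
                       identity_pct = rows$identity_pct,
                       coverage_pct = rows$coverage_pct,
                       alignment_length = rows$alignment_length,
                       stringsAsFactors = FALSE)
    attr(hits, "truth") <- data.frame(read_id = hits$read_id,
                                      pass_taxa = rows$pass_taxa,
                                      pass_functional = rows$pass_functional,
                                      stringsAsFactors = FALSE)
    hits
  })
}

#' Write a synthetic cohort to a directory
#'
#' Emits `metadata.tsv`, one counts TSV per feature table, `truth.tsv`
#' and `cog_categories.tsv`; all round-trip through [readMetadata()] and
#' [readFeatureTable()].
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(methods::is(cohort, "SyntheticCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeMetadata(cohort@metadata, file.path(dir, "metadata.tsv"))
  writeFeatureTable(cohort@genusCounts, file.path(dir, "genus_counts.tsv"))
  for (kind in names(cohort@functionalTables))
    writeFeatureTable(cohort@functionalTables[[kind]],
                      file.path(dir, sprintf("%s_counts.tsv", kind)))
  utils::write.table(cohort@truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(feature_id = names(cohort@categoryMap),
               category = unname(cohort@categoryMap)),
    file.path(dir, "cog_categories.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
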