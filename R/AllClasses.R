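## S4 class definitions for the package's central data objects.

#' Feature-by-sample abundance table
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay
#' (`"abundance"`) of non-negative values, tagged with the kind of feature
#' it profiles and the state of its values.  `state` tracks the
#' normalisation pipeline: raw assigned-read `counts`, `normalized`
#' (divided by each sample's total sequenced reads) or `ranked`
#' (per-feature average ranks `1..n` across samples).
#'
#' @slot kind one of `"taxon-genus"`, `"taxon-phylum"`, `"cog"`,
#'   `"cazyme"`, `"vf"`.
#' @slot state one of `"counts"`, `"normalized"`, `"ranked"`.
#' @export
setClass("FeatureTable",
  contains = "SummarizedExperiment",
  slots = c(kind = "character", state = "character"))

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !object@kind %in% .FEATURE_KINDS)
    msg <- c(msg, sprintf("kind must be one of %s",
                          paste(.FEATURE_KINDS, collapse = ", ")))
  if (length(object@state) != 1L || !object@state %in% .TABLE_STATES)
    msg <- c(msg, sprintf("state must be one of %s",
                          paste(.TABLE_STATES, collapse = ", ")))
  v <- SummarizedExperiment::assay(object)
  if (anyNA(v) || any(v < 0))
    msg <- c(msg, "abundance values must be non-negative and non-missing")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "feature (row) and sample (column) names are required")
  if (length(msg) == 0L && identical(object@state, "ranked")) {
    ok <- apply(v, 1L, function(r) isTRUE(all.equal(unname(rank(r)),
                                                    unname(r))))
    if (!all(ok))
      msg <- c(msg, "ranked state requires each row to be average ranks of 1..n")
  }
  if (length(msg)) msg else TRUE
})

#' Hit-filtering thresholds
#'
#' Alignment-quality thresholds applied with *strict* inequalities: a hit
#' survives only if its value exceeds the threshold.  `minAlignmentLength`
#' may be `NA` to disable the length filter (as for functional
#' annotation).
#'
#' @slot minIdentity minimum percent identity, in (0, 100].
#' @slot minCoverage minimum percent query coverage, in (0, 100].
#' @slot minAlignmentLength minimum alignment length in bp, or `NA`.
#' @export
setClass("HitThresholds",
  slots = c(minIdentity = "numeric", minCoverage = "numeric",
            minAlignmentLength = "numeric"))

setValidity("HitThresholds", function(object) {
  msg <- character()
  for (s in c("minIdentity", "minCoverage")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v <= 0 || v > 100)
      msg <- c(msg, sprintf("%s must be a single value in (0, 100]", s))
  }
  if (length(object@minAlignmentLength) != 1L ||
      (!is.na(object@minAlignmentLength) && object@minAlignmentLength < 0))
    msg <- c(msg, "minAlignmentLength must be a single non-negative value or NA")
  if (length(msg)) msg else TRUE
})

#' Abundance-pattern groups
#'
#' Result of agglomerative clustering of feature abundance patterns:
#' an integer group label per feature plus the `hclust` linkage record.
#'
#' @slot labels named integer vector, one label in `1..k` per feature.
#' @slot linkage the `hclust` object the labels were cut from.
#' @export
setClass("PatternGroups",
  slots = c(labels = "integer", linkage = "ANY"))

setValidity("PatternGroups", function(object) {
  if (is.null(names(object@labels)) || anyNA(object@labels))
    return("labels must be a named, complete integer vector")
  TRUE
})

#' ReBoot resampling parameters
#'
#' @slot nPermutations permutation-null draws (default 1000).
#' @slot nBootstraps bootstrap draws (default 1000).
#' @slot seed RNG seed, or `NA` to use the current RNG stream.
#' @slot zThreshold |z| cut-off used when classifying positively /
#'   negatively correlated features (default 1.97, the two-sided 5% point).
#' @export
setClass("RebootParams",
  slots = c(nPermutations = "integer", nBootstraps = "integer",
            seed = "integer", zThreshold = "numeric"))

setValidity("RebootParams", function(object) {
  msg <- character()
  if (object@nPermutations < 10L || object@nBootstraps < 10L)
    msg <- c(msg, "nPermutations and nBootstraps must each be >= 10")
  if (length(object@zThreshold) != 1L || object@zThreshold < 0)
    msg <- c(msg, "zThreshold must be a single non-negative value")
  if (length(msg)) msg else TRUE
})

#' Co-occurrence network
#'
#' Undirected signed graph over features.  Edges connect feature pairs
#' whose ReBoot-validated correlation is significant at `alpha`; each edge
#' carries the Spearman rho, the ReBoot z and p, and the correlation sign.
#' The node set consists of edge endpoints only (a feature with no
#' significant partner does not appear).
#'
#' @slot nodes character vector of feature ids appearing in >= 1 edge.
#' @slot edges data.frame with columns `a`, `b` (canonical `a < b`),
#'   `rho`, `reboot_z`, `p_value`, `sign`.
#' @slot alpha the edge-calling significance level.
#' @slot context label of the sample set the network was built on
#'   (e.g. `"whole-cohort"`, `"AH"`, `"window-03"`).
#' @export
setClass("CooccurrenceNetwork",
  slots = c(nodes = "character", edges = "data.frame",
            alpha = "numeric", context = "character"))

setValidity("CooccurrenceNetwork", function(object) {
  msg <- character()
  e <- object@edges
  need <- c("a", "b", "rho", "reboot_z", "p_value", "sign")
  if (!all(need %in% names(e)))
    return(sprintf("edges must have columns %s", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (any(e$a >= e$b))
      msg <- c(msg, "edges must be canonical (a < b, no self-loops)")
    if (any(e$p_value >= object@alpha))
      msg <- c(msg, "every edge must satisfy p < alpha")
    if (!setequal(object@nodes, union(e$a, e$b)))
      msg <- c(msg, "nodes must be exactly the edge endpoints")
  }
  if (length(msg)) msg else TRUE
})

#' Sliding-window series of network properties
#'
#' Ordered windows of samples (ascending mean cumulative nutritional
#' index), each with its co-occurrence network's graph properties, plus
#' Spearman trend statistics of each property against the mean index.
#'
#' @slot windows list of per-window records (sample ids, mean index,
#'   network).
#' @slot properties data.frame, one row per window: `window`,
#'   `mean_index`, then the graph-property columns.
#' @slot trends data.frame with columns `property`, `rho`, `p_value`,
#'   `n_windows`.
#' @slot windowSize,step the windowing parameters.
#' @export
setClass("WindowSeries",
  slots = c(windows = "list", properties = "data.frame",
            trends = "data.frame", windowSize = "integer", step = "integer"))

#' Growth reference table (LMS)
#'
#' Per-(sex, axis) LMS curves: rows keyed by age in months
#' (height-for-age, weight-for-age) or height in cm (weight-for-height),
#' carrying the skewness `L`, median `M` and coefficient of variation `S`.
#'
#' @slot table data.frame with columns `sex`, `axis`, `key`, `L`, `M`, `S`.
#' @export
setClass("GrowthReference", slots = c(table = "data.frame"))

setValidity("GrowthReference", function(object) {
  t <- object@table
  need <- c("sex", "axis", "key", "L", "M", "S")
  if (!all(need %in% names(t)))
    return(sprintf("reference needs columns %s", paste(need, collapse = ", ")))
  msg <- character()
  if (!all(t$sex %in% c("M", "F")))
    msg <- c(msg, "sex must be M or F")
  if (!all(t$axis %in% .GROWTH_AXES))
    msg <- c(msg, sprintf("axis must be one of %s",
                          paste(.GROWTH_AXES, collapse = ", ")))
  if (any(t$M <= 0) || any(t$S <= 0))
    msg <- c(msg, "M and S must be strictly positive")
  for (grp in split(t, list(t$sex, t$axis), drop = TRUE))
    if (is.unsorted(grp$key, strictly = TRUE))
      msg <- c(msg, "keys must be strictly increasing within each (sex, axis)")
  if (length(msg)) unique(msg) else TRUE
})

#' Synthetic cohort configuration
#'
#' Parameters of the synthetic cohort generator.  Defaults emulate the
#' study conditions the pipeline targets: 20 samples spanning cumulative
#' nutritional indices -11.58..-2.18, a dominant Prevotella-like genus,
#' five gradient-positive and five gradient-negative planted genera,
#' neutral genera, and within-group co-occurrence hubs whose coupling
#' strengthens as nutrition worsens.
#'
#' @slot nSamples cohort size.
#' @slot indexRange low/high cumulative-index endpoints.
#' @slot nG1Taxa,nG4Taxa,nNeutralTaxa planted gradient-positive (G1-like),
#'   gradient-negative (G4-like) and neutral genus counts.
#' @slot effectSize per-unit-index slope of latent log-abundance for
#'   planted gradient taxa (>= 0).
#' @slot dominantFraction mean relative-abundance share of the dominant
#'   genus, in (0, 1).
#' @slot hubCouplingSlope loading of the shared hub factor per unit of
#'   (index_high - index); 0 disables hub structure.
#' @slot latentSd standard deviation of latent log-abundance noise.
#' @slot librarySizeRange min/max per-sample synthetic read totals.
#' @slot overdispersion Dirichlet-multinomial overdispersion; the DM
#'   concentration is library_size / overdispersion.
#' @slot seed RNG seed.
#' @export
setClass("SyntheticConfig",
  slots = c(nSamples = "integer", indexRange = "numeric",
            nG1Taxa = "integer", nG4Taxa = "integer",
            nNeutralTaxa = "integer", effectSize = "numeric",
            dominantFraction = "numeric", hubCouplingSlope = "numeric",
            latentSd = "numeric", librarySizeRange = "numeric",
            overdispersion = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nSamples < 4L)
    msg <- c(msg, "nSamples must be >= 4")
  if (length(object@indexRange) != 2L ||
      object@indexRange[1L] >= object@indexRange[2L])
    msg <- c(msg, "indexRange must be (low, high) with low < high")
  if (object@nG1Taxa < 0L || object@nG4Taxa < 0L || object@nNeutralTaxa < 0L)
    msg <- c(msg, "taxon counts must be >= 0")
  if (object@effectSize < 0)
    msg <- c(msg, "effectSize must be >= 0")
  if (object@dominantFraction <= 0 || object@dominantFraction >= 1)
    msg <- c(msg, "dominantFraction must lie in (0, 1)")
  if (object@hubCouplingSlope < 0)
    msg <- c(msg, "hubCouplingSlope must be >= 0")
  if (object@latentSd <= 0)
    msg <- c(msg, "latentSd must be > 0")
  if (length(object@librarySizeRange) != 2L ||
      any(object@librarySizeRange < 1) ||
      object@librarySizeRange[1L] > object@librarySizeRange[2L])
    msg <- c(msg, "librarySizeRange must be positive with min <= max")
  if (object@overdispersion <= 0)
    msg <- c(msg, "overdispersion must be > 0")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort
#'
#' The generator's output: per-sample metadata (anthropometrics,
#' Z-scores, cumulative index, class, total reads), a genus count table,
#' functional count tables (COG-, CAZyme- and virulence-factor-like), a
#' truth table recording every planted feature's role, and a COG-to-
#' functional-category map.
#'
#' @slot metadata per-sample data.frame (see [computeZScores()]).
#' @slot genusCounts [FeatureTable-class] of genus counts.
#' @slot functionalTables named list of [FeatureTable-class] objects
#'   (`cog`, `cazyme`, `vf`).
#' @slot truth data.frame with columns `table`, `feature`, `role`, `hub`.
#' @slot categoryMap named character: COG feature -> functional category.
#' @slot config the [SyntheticConfig-class] used.
#' @export
setClass("SyntheticCohort",
  slots = c(metadata = "data.frame", genusCounts = "FeatureTable",
            functionalTables = "list", truth = "data.frame",
            categoryMap = "character", config = "SyntheticConfig"))

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  counts <- SummarizedExperiment::assay(object@genusCounts)
  if (!isTRUE(all.equal(unname(colSums(counts)),
                        as.numeric(object@metadata$total_reads))))
    msg <- c(msg, "genus counts must sum to total_reads per sample")
  planted <- object@truth$feature[object@truth$table == "taxon-genus"]
  if (!all(planted %in% rownames(counts)))
    msg <- c(msg, "truth must cover only features present in the tables")
  if (length(msg)) msg else TRUE
})
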