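## Building, normalising, ranking, filtering and clustering
## feature-by-sample abundance tables.

#' Construct a FeatureTable
#'
#' @param values numeric matrix, features as rows (named), samples as
#'   columns (named); all values non-negative.
#' @param kind feature kind: `"taxon-genus"`, `"taxon-phylum"`, `"cog"`,
#'   `"cazyme"` or `"vf"`.
#' @param state `"counts"` (default), `"normalized"` or `"ranked"`.
#' @param sampleData optional per-sample data.frame (stored as `colData`).
#' @return a [FeatureTable-class].
#' @export
FeatureTable <- function(values, kind, state = "counts", sampleData = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  cd <- if (is.null(sampleData)) {
    S4Vectors::DataFrame(row.names = colnames(values))
  } else {
    S4Vectors::DataFrame(sampleData, row.names = colnames(values))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = values), colData = cd)
  methods::new("FeatureTable", se, kind = kind, state = state)
}

#' Read / write a feature table TSV
#'
#' Features as rows, samples as columns; first column holds feature ids,
#' the header row holds sample ids.
#'
#' @param path file path.
#' @param kind,state see [FeatureTable()].
#' @param table a [FeatureTable-class].
#' @export
readFeatureTable <- function(path, kind, state = "counts") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  FeatureTable(m, kind = kind, state = state)
}

#' @rdname readFeatureTable
#' @export
writeFeatureTable <- function(table, path) {
  stopifnot(methods::is(table, "FeatureTable"))
  v <- abundanceValues(table)
  df <- data.frame(feature_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Hit-filtering threshold presets
#'
#' `taxaHitThresholds()` returns the taxonomic-assignment preset
#' (identity > 65%, query coverage > 70%, alignment length > 75 bp);
#' `functionalHitThresholds()` the functional-annotation preset
#' (identity > 65%, query coverage > 90%, no length filter).
#'
#' @param minIdentity,minCoverage percent thresholds in (0, 100].
#' @param minAlignmentLength bp threshold or `NA` for none.
#' @return a [HitThresholds-class].
#' @export
hitThresholds <- function(minIdentity, minCoverage,
                          minAlignmentLength = NA_real_) {
  methods::new("HitThresholds",
               minIdentity = as.numeric(minIdentity),
               minCoverage = as.numeric(minCoverage),
               minAlignmentLength = as.numeric(minAlignmentLength))
}

#' @rdname hitThresholds
#' @export
taxaHitThresholds <- function() hitThresholds(65, 70, 75)

#' @rdname hitThresholds
#' @export
functionalHitThresholds <- function() hitThresholds(65, 90, NA_real_)

#' Filter a read-level hit table into per-sample feature counts
#'
#' Rows survive only if they *strictly exceed* every threshold
#' (`identity_pct > minIdentity`, `coverage_pct > minCoverage`, and
#' `alignment_length > minAlignmentLength` when that threshold is set).
#'
#' @param hits data.frame with columns `read_id`, `sample_id`,
#'   `feature_id`, `identity_pct`, `coverage_pct`, `alignment_length`.
#' @param thresholds a [HitThresholds-class].
#' @param kind feature kind attached to the returned table.
#' @param sampleIds optional sample ids fixing the output columns (samples
#'   with no surviving hit get a zero column).
#' @return a counts-state [FeatureTable-class].
#' @export
filterHits <- function(hits, thresholds, kind = "taxon-genus",
                       sampleIds = NULL) {
  stopifnot(methods::is(thresholds, "HitThresholds"))
  need <- c("sample_id", "feature_id", "identity_pct", "coverage_pct")
  if (!is.na(thresholds@minAlignmentLength))
    need <- c(need, "alignment_length")
  miss <- setdiff(need, names(hits))
  if (length(miss))
    stop("hit table is missing required column(s): ",
         paste(miss, collapse = ", "))
  keep <- hits$identity_pct > thresholds@minIdentity &
    hits$coverage_pct > thresholds@minCoverage
  if (!is.na(thresholds@minAlignmentLength))
    keep <- keep & hits$alignment_length > thresholds@minAlignmentLength
  passed <- hits[keep, , drop = FALSE]
  samples <- if (is.null(sampleIds)) sort(unique(hits$sample_id)) else sampleIds
  features <- sort(unique(hits$feature_id))
  m <- matrix(0, nrow = length(features), ncol = length(samples),
              dimnames = list(features, samples))
  if (nrow(passed)) {
    tab <- table(factor(passed$feature_id, levels = features),
                 factor(passed$sample_id, levels = samples))
    m[] <- as.numeric(tab)
  }
  FeatureTable(m, kind = kind, state = "counts")
}

#' Normalise assigned-read counts by total sequenced reads
#'
#' Divides each count by the *whole-metagenome* read total of its sample
#' (not by the assigned-read total), so per-sample column sums are at
#' most 1.
#'
#' @param table a counts-state [FeatureTable-class].
#' @param totalReads named numeric vector of per-sample totals (names =
#'   sample ids), or a metadata data.frame with `sample_id` and
#'   `total_reads` columns.
#' @return a normalized-state [FeatureTable-class].
#' @export
normalizeAbundance <- function(table, totalReads) {
  stopifnot(methods::is(table, "FeatureTable"))
  if (tableState(table) != "counts")
    stop("normalizeAbundance expects a counts-state table")
  if (is.data.frame(totalReads))
    totalReads <- stats::setNames(totalReads$total_reads,
                                  totalReads$sample_id)
  totals <- totalReads[sampleIds(table)]
  if (anyNA(totals))
    stop("totalReads missing for sample(s): ",
         paste(setdiff(sampleIds(table), names(totalReads)), collapse = ", "))
  if (any(totals <= 0)) stop("total reads must be strictly positive")
  v <- sweep(abundanceValues(table), 2L, totals, "/")
  FeatureTable(v, kind = featureKind(table), state = "normalized",
               sampleData = as.data.frame(SummarizedExperiment::colData(table)))
}

#' Rank-normalise a feature table
#'
#' Within each feature row, samples receive ranks `1..n` ascending by
#' abundance, ties resolved by average ranks.
#'
#' @param table a normalized-state [FeatureTable-class].
#' @return a ranked-state [FeatureTable-class].
#' @export
rankNormalize <- function(table) {
  stopifnot(methods::is(table, "FeatureTable"))
  if (tableState(table) != "normalized")
    stop("rankNormalize expects a normalized-state table")
  v <- t(apply(abundanceValues(table), 1L, rank))
  dimnames(v) <- dimnames(abundanceValues(table))
  FeatureTable(v, kind = featureKind(table), state = "ranked",
               sampleData = as.data.frame(SummarizedExperiment::colData(table)))
}

#' Core features
#'
#' A feature is *core* when its normalized abundance strictly exceeds
#' `minAbundance` in at least `ceiling(minPrevalence * n_samples)`
#' samples (default: > 0.01 in at least half the samples).
#'
#' @param table a normalized-state [FeatureTable-class].
#' @param minAbundance abundance floor (strict inequality).
#' @param minPrevalence required sample fraction.
#' @return character vector of core feature ids.
#' @export
coreFeatures <- function(table, minAbundance = 0.01, minPrevalence = 0.5) {
  stopifnot(methods::is(table, "FeatureTable"))
  if (tableState(table) != "normalized")
    stop("coreFeatures expects a normalized-state table")
  v <- abundanceValues(table)
  needed <- ceiling(minPrevalence * ncol(v))
  hits <- rowSums(v > minAbundance)
  rownames(v)[hits >= needed]
}

#' Cluster features by abundance pattern
#'
#' Agglomerative (average-linkage) clustering of feature rows under the
#' distance `1 - Spearman correlation`, cut into `nGroups` groups.
#' Features are processed in feature-id order so the result is
#' deterministic for a given table.
#'
#' @param table a ranked-state (or normalized) [FeatureTable-class] with
#'   at least `nGroups` features.
#' @param nGroups number of groups to cut the tree into.
#' @return a [PatternGroups-class].
#' @export
clusterAbundancePatterns <- function(table, nGroups) {
  stopifnot(methods::is(table, "FeatureTable"))
  v <- abundanceValues(table)
  v <- v[order(rownames(v)), , drop = FALSE]
  if (nGroups > nrow(v))
    stop("nGroups exceeds the number of features")
  rho <- suppressWarnings(stats::cor(t(v), method = "spearman"))
  rho[is.na(rho)] <- 0  # constant rows carry no pattern information
  d <- stats::as.dist(1 - rho)
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = nGroups)
  methods::new("PatternGroups", labels = as.integer(labels) |>
                 stats::setNames(names(labels)), linkage = hc)
}

#' Cumulative abundance of a feature group
#'
#' Per-sample sum of the rows belonging to the selected group label(s) —
#' e.g. the combined abundance of all gradient-negative taxa, or the
#' union of several CAZyme pattern groups.
#'
#' @param table a [FeatureTable-class] (any state).
#' @param groups a [PatternGroups-class].
#' @param members one or more group labels to pool.
#' @return named numeric vector of per-sample totals.
#' @export
groupCumulativeAbundance <- function(table, groups, members) {
  stopifnot(methods::is(table, "FeatureTable"),
            methods::is(groups, "PatternGroups"))
  if (length(members) == 0L) stop("members must name at least one group")
  labs <- groupLabels(groups)
  if (!all(members %in% labs))
    stop("unknown group label(s): ",
         paste(setdiff(members, labs), collapse = ", "))
  feats <- names(labs)[labs %in% members]
  feats <- intersect(feats, featureIds(table))
  if (length(feats) == 0L) stop("selected groups have no member features")
  colSums(abundanceValues(table)[feats, , drop = FALSE])
}
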