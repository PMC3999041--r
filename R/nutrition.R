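## WHO-style LMS Z-scores, the cumulative nutritional index and the
## AH/BL/SM classification.

#' Construct a growth reference
#'
#' @param table data.frame with columns `sex` ("M"/"F"), `axis`
#'   ("height-for-age", "weight-for-age", "weight-for-height"), `key`
#'   (age in months for the age axes, height in cm for weight-for-height)
#'   and the LMS parameters `L`, `M`, `S`.
#' @return a [GrowthReference-class].
#' @export
GrowthReference <- function(table) {
  table <- as.data.frame(table)
  table <- table[order(table$sex, table$axis, table$key), , drop = FALSE]
  rownames(table) <- NULL
  methods::new("GrowthReference", table = table)
}

#' Read / write a growth reference TSV
#'
#' Plain tab-separated columns `sex`, `axis`, `key`, `L`, `M`, `S`.
#'
#' @param path file path.
#' @param reference a [GrowthReference-class].
#' @export
readGrowthReference <- function(path) {
  GrowthReference(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname readGrowthReference
#' @export
writeGrowthReference <- function(reference, path) {
  stopifnot(methods::is(reference, "GrowthReference"))
  utils::write.table(reference@table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' LMS Z-score
#'
#' The Box-Cox (LMS) Z-score of a measurement `x` against reference
#' skewness `L`, median `M` and coefficient of variation `S`:
#' `((x/M)^L - 1) / (L * S)`, with the `L -> 0` limit `log(x/M) / S`.
#'
#' @param x positive measurement.
#' @param L,M,S LMS parameters (`M`, `S` strictly positive).
#' @return the Z-score (vectorised over its arguments).
#' @export
lmsZScore <- function(x, L, M, S) {
  stopifnot(all(x > 0), all(M > 0), all(S > 0))
  ifelse(abs(L) > 1e-9, ((x / M)^L - 1) / (L * S), log(x / M) / S)
}

#' Invert an LMS Z-score
#'
#' The measurement whose [lmsZScore()] equals `z`:
#' `M * (1 + L*S*z)^(1/L)` (or `M * exp(S*z)` as `L -> 0`).
#'
#' @param z target Z-score.
#' @inheritParams lmsZScore
#' @export
lmsMeasurement <- function(z, L, M, S) {
  stopifnot(all(M > 0), all(S > 0))
  base <- 1 + L * S * z
  if (any(base[abs(L) > 1e-9] <= 0))
    stop("target z is outside the LMS-representable range (1 + L*S*z <= 0)")
  ifelse(abs(L) > 1e-9, M * base^(1 / L), M * exp(S * z))
}

#' Interpolated LMS parameters
#'
#' Looks up `L`, `M`, `S` for a (sex, axis) curve at `key`, linearly
#' interpolating between the bracketing reference rows.  Keys outside the
#' tabulated range raise an error (no extrapolation).
#'
#' @param reference a [GrowthReference-class].
#' @param sex "M" or "F".
#' @param axis one of the three growth axes.
#' @param key age in months (age axes) or height in cm (weight-for-height).
#' @return named numeric vector with elements `L`, `M`, `S`.
#' @export
lookupLMS <- function(reference, sex, axis, key) {
  stopifnot(methods::is(reference, "GrowthReference"))
  t <- reference@table
  rows <- t[t$sex == sex & t$axis == axis, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop(sprintf("no reference rows for sex=%s axis=%s", sex, axis))
  if (key < min(rows$key) || key > max(rows$key))
    stop(sprintf(
      "key %.6g outside reference range [%g, %g] for sex=%s axis=%s",
      key, min(rows$key), max(rows$key), sex, axis))
  c(L = stats::approx(rows$key, rows$L, xout = key)$y,
    M = stats::approx(rows$key, rows$M, xout = key)$y,
    S = stats::approx(rows$key, rows$S, xout = key)$y)
}

#' Cumulative nutritional index
#'
#' Sum of the three growth Z-scores (height-for-age, weight-for-age,
#' weight-for-height), used as a single severity axis.
#'
#' @param z1,z2,z3 the three Z-scores.
#' @export
cumulativeIndex <- function(z1, z2, z3) {
  stopifnot(all(is.finite(z1)), all(is.finite(z2)), all(is.finite(z3)))
  z1 + z2 + z3
}

#' Nutrition class from the cumulative index
#'
#' Apparently healthy (`AH`) for indices above -6, borderline (`BL`) for
#' (-9, -6], severely malnourished (`SM`) at or below -9.  The defining
#' inequalities are open at both cut-points; the exact boundaries are
#' closed downward-inclusive (-6 into `BL`, -9 into `SM`) so the three
#' classes partition the line.
#'
#' @param index cumulative nutritional index (vectorised).
#' @return character vector of class labels.
#' @export
classifyNutrition <- function(index) {
  stopifnot(all(is.finite(index)))
  ifelse(index > -6, "AH", ifelse(index > -9, "BL", "SM"))
}

#' Score a metadata table
#'
#' Computes the three Z-scores, the cumulative nutritional index and the
#' AH/BL/SM class for every sample: height-for-age from (`height_cm`,
#' `age_months`), weight-for-age from (`weight_kg`, `age_months`) and
#' weight-for-height from (`weight_kg`, `height_cm`).
#'
#' @param metadata data.frame with columns `sample_id`, `age_months`,
#'   `sex`, `height_cm`, `weight_kg` (and typically `total_reads`).
#' @param reference a [GrowthReference-class].
#' @return the metadata with columns `z1`, `z2`, `z3`,
#'   `cumulative_index`, `nutrition_class` added/overwritten.
#' @export
computeZScores <- function(metadata, reference) {
  need <- c("sample_id", "age_months", "sex", "height_cm", "weight_kg")
  if (!all(need %in% names(metadata)))
    stop("metadata must have columns ", paste(need, collapse = ", "))
  z <- function(measure, axis, key) {
    vapply(seq_len(nrow(metadata)), function(i) {
      p <- lookupLMS(reference, metadata$sex[i], axis, key[i])
      lmsZScore(measure[i], p["L"], p["M"], p["S"])
    }, numeric(1))
  }
  metadata$z1 <- z(metadata$height_cm, "height-for-age", metadata$age_months)
  metadata$z2 <- z(metadata$weight_kg, "weight-for-age", metadata$age_months)
  metadata$z3 <- z(metadata$weight_kg, "weight-for-height", metadata$height_cm)
  metadata$cumulative_index <-
    cumulativeIndex(metadata$z1, metadata$z2, metadata$z3)
  metadata$nutrition_class <- classifyNutrition(metadata$cumulative_index)
  metadata
}

#' Read / write scored metadata TSV
#'
#' @param path file path.
#' @param metadata a metadata data.frame.
#' @export
readMetadata <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname readMetadata
#' @export
writeMetadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
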