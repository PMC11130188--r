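# Feature registry: the eight in-silico predictor scores the model knows
# about, their admissible ranges for validation, and the empirical score
# ranges used to clip synthetic data.
#
# Validation ranges are the defining ranges of each score: SIFT,
# PolyPhen-2, REVEL, MetaLR and MutationAssessor live on [0, 1];
# Grantham's distance, the Sneath index and CADD (PHRED-like) are
# nonnegative. Clip ranges are the observed min/max of each score over
# NAGLU missense variants and bound the synthetic generator.

.FEATURE_INFO <- list(
  grantham          = list(label = "Grantham's distance", min = 0, max = Inf, clip = c(5, 215)),
  sneath            = list(label = "Sneath index",        min = 0, max = Inf, clip = c(5, 43)),
  sift              = list(label = "SIFT",                min = 0, max = 1,   clip = c(0, 1)),
  polyphen2         = list(label = "PolyPhen-2",          min = 0, max = 1,   clip = c(0, 1)),
  cadd              = list(label = "CADD",                min = 0, max = Inf, clip = c(0, 32)),
  revel             = list(label = "REVEL",               min = 0, max = 1,   clip = c(0.124, 0.995)),
  metalr            = list(label = "MetaLR",              min = 0, max = 1,   clip = c(0, 0.997)),
  mutation_assessor = list(label = "MutationAssessor",    min = 0, max = 1,   clip = c(0, 0.951))
)

.LABEL_LEVELS <- c("VUS", "benign", "likely_benign", "pathogenic",
                   "likely_pathogenic", "unknown")

#' Canonical predictor score feature names
#'
#' The eight in-silico predictor scores recognized by the package, in
#' canonical order: Grantham's distance, Sneath index, SIFT, PolyPhen-2,
#' CADD, REVEL, MetaLR and MutationAssessor. All variant tables and
#' models use (subsets of) these snake_case names.
#'
#' @return Character vector of the eight canonical feature names.
#' @export
#' @examples
#' sanfilippoFeatures()
sanfilippoFeatures <- function() {
  names(.FEATURE_INFO)
}

#' Features used by the SanfilippoPred scoring rule
#'
#' The pathogenicity calculator consumes the six predictor scores SIFT,
#' PolyPhen-2, CADD, REVEL, MetaLR and MutationAssessor (the two
#' amino-acid substitution distances are not part of the scoring rule).
#'
#' @return Character vector of six feature names.
#' @export
predictionFeatures <- function() {
  c("sift", "polyphen2", "cadd", "revel", "metalr", "mutation_assessor")
}

#' Admissible value ranges per feature
#'
#' @param features Character vector of canonical feature names.
#' @return A 2-row matrix (`min`, `max`) with one column per feature.
#' @export
featureRanges <- function(features = sanfilippoFeatures()) {
  .check_features(features)
  vapply(features, function(f) {
    c(min = .FEATURE_INFO[[f]]$min, max = .FEATURE_INFO[[f]]$max)
  }, numeric(2))
}

#' Empirical clip ranges per feature
#'
#' Observed score bounds used by the synthetic data generator to keep
#' simulated values on realistic scales.
#'
#' @inheritParams featureRanges
#' @return A 2-row matrix (`min`, `max`) with one column per feature.
#' @export
clipRanges <- function(features = sanfilippoFeatures()) {
  .check_features(features)
  vapply(features, function(f) {
    r <- .FEATURE_INFO[[f]]$clip
    c(min = r[1], max = r[2])
  }, numeric(2))
}

.check_features <- function(features) {
  if (length(features) < 1L) {
    stop("at least one feature must be named", call. = FALSE)
  }
  bad <- setdiff(features, names(.FEATURE_INFO))
  if (length(bad)) {
    stop("unknown feature name(s): ", paste(bad, collapse = ", "),
         "; recognized features are: ",
         paste(names(.FEATURE_INFO), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(features)) {
    stop("duplicated feature name(s)", call. = FALSE)
  }
  invisible(features)
}

# Map raw label text onto the clinical assertion enum; anything
# unrecognized becomes "unknown" (with a warning at the call site).
.normalize_label <- function(x) {
  raw <- trimws(as.character(x))
  key <- tolower(gsub("[ /-]+", "_", raw))
  map <- c(vus = "VUS",
           uncertain_significance = "VUS",
           benign = "benign",
           likely_benign = "likely_benign",
           pathogenic = "pathogenic",
           likely_pathogenic = "likely_pathogenic",
           unknown = "unknown")
  out <- unname(map[key])
  out[is.na(out)] <- "unknown"
  attr(out, "unrecognized") <- is.na(unname(map[key])) & nzchar(key)
  out
}
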