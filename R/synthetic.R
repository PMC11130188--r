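# Model-faithful synthetic variant-score data. The generator draws from
# a two-component multivariate Gaussian mixture over the predictor
# scores, clips to realistic per-score ranges, optionally attaches
# clinical labels (component 1 -> benign-side assertions, component 2 ->
# pathogenic-side) and injects missing-completely-at-random cells. The
# default centroids mimic the score profiles of benign-like and
# pathogenic-like NAGLU missense variants (pathogenic variants: low
# SIFT, high PolyPhen-2/CADD/REVEL/MetaLR/MutationAssessor); the default
# within-cluster spreads are documented constants chosen to give a
# clearly bimodal but realistically overlapping mixture.

.DEFAULT_WEIGHTS <- c(benign = 0.43, pathogenic = 0.57)

.DEFAULT_CENTROIDS <- rbind(
  benign     = c(grantham = 63.4, sneath = 19.7, sift = 0.38, polyphen2 = 0.22,
                 cadd = 15.0, revel = 0.39, metalr = 0.81, mutation_assessor = 0.40),
  pathogenic = c(grantham = 82.4, sneath = 24.6, sift = 0.03, polyphen2 = 0.77,
                 cadd = 24.4, revel = 0.75, metalr = 0.95, mutation_assessor = 0.77)
)

.DEFAULT_SDS <- rbind(
  benign     = c(grantham = 15.0, sneath = 3.5, sift = 0.15, polyphen2 = 0.15,
                 cadd = 4.0, revel = 0.12, metalr = 0.06, mutation_assessor = 0.15),
  pathogenic = c(grantham = 18.0, sneath = 3.5, sift = 0.03, polyphen2 = 0.12,
                 cadd = 3.5, revel = 0.12, metalr = 0.025, mutation_assessor = 0.12)
)

#' Default generator centroids
#'
#' The 2 x 8 matrix of cluster means (rows `benign`, `pathogenic`) used
#' as generator defaults.
#' @return Numeric matrix.
#' @export
defaultCentroids <- function() .DEFAULT_CENTROIDS

#' Default within-cluster standard deviations
#'
#' @return Numeric 2 x 8 matrix (rows `benign`, `pathogenic`).
#' @export
defaultClusterSds <- function() .DEFAULT_SDS

#' Specification of a synthetic variant-score dataset
#'
#' @param n Number of variants to generate.
#' @param features Canonical feature names (subset of the eight).
#' @param weights Length-2 mixing weights (benign, pathogenic), summing
#'   to 1.
#' @param centroids 2 x p matrix of cluster means.
#' @param sds 2 x p matrix of within-cluster standard deviations
#'   (covariances are diagonal), or a list of two p x p covariance
#'   matrices via `covariances`.
#' @param covariances Optional list of two p x p covariance matrices
#'   overriding `sds`.
#' @param clip 2-row min/max matrix per feature (default
#'   [clipRanges()]); generated values are clipped into these ranges.
#' @param labelFraction Fraction of rows emitted with a clinical label
#'   drawn from their generating component; the rest are VUS.
#' @param missingRate MCAR cell masking probability in \[0, 1).
#' @param truncate If `TRUE`, sample each coordinate from the truncated
#'   normal on its clip range instead of clipping (diagonal covariances
#'   only).
#' @param seed Integer seed.
#' @return A list of class `GeneratorSpec`.
#' @export
generatorSpec <- function(n = 612L, features = sanfilippoFeatures(),
                          weights = .DEFAULT_WEIGHTS,
                          centroids = .DEFAULT_CENTROIDS[, features, drop = FALSE],
                          sds = .DEFAULT_SDS[, features, drop = FALSE],
                          covariances = NULL,
                          clip = clipRanges(features),
                          labelFraction = 0, missingRate = 0,
                          truncate = FALSE, seed = 1L) {
  .check_features(features)
  weights <- unname(weights)
  if (length(weights) != 2L || abs(sum(weights) - 1) > 1e-8 || any(weights < 0)) {
    stop("weights must be 2 nonnegative values summing to 1", call. = FALSE)
  }
  p <- length(features)
  centroids <- as.matrix(centroids)
  if (!identical(dim(centroids), c(2L, p))) stop("centroids must be 2 x p", call. = FALSE)
  if (is.null(covariances)) {
    sds <- as.matrix(sds)
    if (!identical(dim(sds), c(2L, p)) || any(sds <= 0)) {
      stop("sds must be a positive 2 x p matrix", call. = FALSE)
    }
    covariances <- lapply(1:2, function(k) diag(sds[k, ]^2, p))
    diagonal <- TRUE
  } else {
    if (length(covariances) != 2L) stop("covariances must be a list of 2", call. = FALSE)
    for (S in covariances) {
      if (!identical(dim(S), c(p, p))) stop("covariances must be p x p", call. = FALSE)
      if (inherits(try(chol(S), silent = TRUE), "try-error")) {
        stop("covariances must be positive definite", call. = FALSE)
      }
    }
    diagonal <- FALSE
    sds <- rbind(sqrt(diag(covariances[[1]])), sqrt(diag(covariances[[2]])))
  }
  if (truncate && !diagonal) {
    stop("truncated sampling requires diagonal covariances", call. = FALSE)
  }
  if (missingRate < 0 || missingRate >= 1) {
    stop("missingRate must be in [0, 1)", call. = FALSE)
  }
  if (labelFraction < 0 || labelFraction > 1) {
    stop("labelFraction must be in [0, 1]", call. = FALSE)
  }
  structure(list(n = as.integer(n), features = features, weights = weights,
                 centroids = centroids, sds = sds, covariances = covariances,
                 clip = clip, labelFraction = labelFraction,
                 missingRate = missingRate, truncate = truncate,
                 seed = as.integer(seed), diagonal = diagonal),
            class = "GeneratorSpec")
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic variant-score dataset
#'
#' Draws rows from the two-component Gaussian mixture of a
#' [generatorSpec()], clips (or truncates) to the per-feature ranges,
#' attaches labels to a `labelFraction` subset and MCAR missingness at
#' `missingRate`. Reproducible under the spec seed.
#'
#' @param spec A `GeneratorSpec`.
#' @return A list with `dataset` (a harmonized [VariantDataset-class]),
#'   `truth` (integer generating component, 1 benign / 2 pathogenic) and
#'   `unclipped` (the pre-clipping score matrix, for distributional
#'   checks).
#' @export
generateMixtureDataset <- function(spec) {
  stopifnot(inherits(spec, "GeneratorSpec"))
  set.seed(spec$seed)
  n <- spec$n; p <- length(spec$features)
  z <- 1L + (stats::runif(n) >= spec$weights[1])
  X <- matrix(NA_real_, n, p, dimnames = list(NULL, spec$features))
  for (k in 1:2) {
    idx <- which(z == k)
    if (!length(idx)) next
    if (spec$truncate) {
      for (j in seq_len(p)) {
        X[idx, j] <- .rtruncnorm(length(idx), spec$centroids[k, j],
                                 spec$sds[k, j], spec$clip["min", j],
                                 spec$clip["max", j])
      }
    } else {
      ch <- .chol_safe(spec$covariances[[k]])
      E <- matrix(stats::rnorm(length(idx) * p), length(idx), p) %*% ch
      X[idx, ] <- sweep(E, 2L, spec$centroids[k, ], "+")
    }
  }
  unclipped <- X
  for (j in seq_len(p)) {
    X[, j] <- pmin(pmax(X[, j], spec$clip["min", j]), spec$clip["max", j])
  }
  label <- rep("VUS", n)
  n_lab <- round(spec$labelFraction * n)
  if (n_lab > 0) {
    lab_idx <- sample.int(n, n_lab)
    pick <- function(opts, m) opts[1L + (stats::runif(m) < 0.3)]
    ben <- lab_idx[z[lab_idx] == 1L]
    pat <- lab_idx[z[lab_idx] == 2L]
    label[ben] <- pick(c("benign", "likely_benign"), length(ben))
    label[pat] <- pick(c("pathogenic", "likely_pathogenic"), length(pat))
  }
  ds <- variantDataset(X, gene = "NAGLU", label = label)
  if (spec$missingRate > 0) {
    ds <- injectMissingness(ds, spec$missingRate, seed = spec$seed + 1L)
  }
  list(dataset = harmonizeLabels(ds), truth = z, unclipped = unclipped)
}

#' Inject missing-completely-at-random cells
#'
#' Masks each score cell independently with probability `rate`; labels
#' and identifiers are never masked.
#'
#' @param ds A [VariantDataset-class].
#' @param rate Masking probability in \[0, 1).
#' @param seed Integer seed.
#' @return The dataset with masked score cells.
#' @export
injectMissingness <- function(ds, rate, seed = 1L) {
  stopifnot(is(ds, "VariantDataset"))
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)", call. = FALSE)
  if (rate == 0) return(ds)
  set.seed(as.integer(seed))
  mask <- matrix(stats::runif(length(ds@scores)) < rate, nrow(ds@scores))
  ds@scores[mask] <- NA_real_
  ds
}

#' Benchmark fixture emulating the study design
#'
#' Builds the three-way layout of the modelling study: 415 unlabelled
#' (VUS) variants as the training pool plus 197 labelled variants (101
#' benign-side, 96 pathogenic-side), the latter partitioned into a
#' stratified validation set (n = 99) and test set (n = 98). Scores come
#' from the default generator mixture; a small MCAR missingness rate
#' exercises the imputation stage.
#'
#' @param seed Integer seed.
#' @param missingRate MCAR rate applied to all three tables.
#' @param nTrain,nBenign,nPathogenic Layout sizes.
#' @return A list with `train`, `validation`, `test`
#'   ([VariantDataset-class]) and `truth` (list of generating components
#'   aligned with each table).
#' @export
makeBenchmarkFixture <- function(seed = 1L, missingRate = 0.05,
                                 nTrain = 415L, nBenign = 101L,
                                 nPathogenic = 96L) {
  set.seed(as.integer(seed))
  # training pool: mixture draw, unlabelled
  train_gen <- generateMixtureDataset(
    generatorSpec(n = nTrain, missingRate = 0, seed = .stage_seed(seed, "train")))
  # labelled pool: exact class counts, one component each
  gen_fixed <- function(n_k, k, stage) {
    sp <- generatorSpec(n = n_k, weights = if (k == 1) c(1, 0) else c(0, 1),
                        seed = .stage_seed(seed, stage))
    generateMixtureDataset(sp)
  }
  ben <- gen_fixed(nBenign, 1L, "benign")
  pat <- gen_fixed(nPathogenic, 2L, "pathogenic")
  lab_scores <- rbind(ben$dataset@scores, pat$dataset@scores)
  lab_label <- c(rep("benign", nBenign), rep("pathogenic", nPathogenic))
  # sprinkle likely_* assertions to exercise harmonization
  lk <- seq(1L, nBenign, by = 3L)
  lab_label[lk] <- "likely_benign"
  lab_label[nBenign + seq(1L, nPathogenic, by = 3L)] <- "likely_pathogenic"
  labelled <- harmonizeLabels(
    variantDataset(lab_scores,
                   variantId = paste0("lab", seq_len(nBenign + nPathogenic)),
                   gene = "NAGLU", label = lab_label))
  lab_truth <- c(rep(1L, nBenign), rep(2L, nPathogenic))
  perm <- sample.int(nBenign + nPathogenic)
  labelled <- labelled[perm]
  lab_truth <- lab_truth[perm]
  parts <- partitionValidationTest(labelled, seed = .stage_seed(seed, "partition"))
  val_idx <- match(parts$validation@variantId, labelled@variantId)
  test_idx <- match(parts$test@variantId, labelled@variantId)
  add_miss <- function(ds, stage) {
    if (missingRate > 0) injectMissingness(ds, missingRate, .stage_seed(seed, stage)) else ds
  }
  list(train = add_miss(train_gen$dataset, "miss-train"),
       validation = add_miss(parts$validation, "miss-val"),
       test = add_miss(parts$test, "miss-test"),
       truth = list(train = train_gen$truth,
                    validation = lab_truth[val_idx],
                    test = lab_truth[test_idx]))
}
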