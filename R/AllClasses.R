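#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' VariantDataset: a table of missense variants with predictor scores
#'
#' Central container of the package: one row per missense variant, one
#' column per in-silico predictor score, plus the variant identifier,
#' gene symbol and clinical assertion label. Missing scores are `NA`.
#' After [harmonizeLabels()] the binary class slot holds 0 (benign-side
#' assertions), 1 (pathogenic-side assertions) or `NA` (VUS/unknown).
#'
#' @slot variantId character, one identifier per variant (HGVS or
#'   chr:pos:ref:alt style strings).
#' @slot gene character, gene symbol per variant.
#' @slot label character, clinical assertion per variant; one of
#'   `VUS`, `benign`, `likely_benign`, `pathogenic`, `likely_pathogenic`,
#'   `unknown`.
#' @slot scores numeric matrix, variants x features, `NA` for missing;
#'   column names are canonical feature names.
#' @slot yClass integer, harmonized class per variant (0 benign,
#'   1 pathogenic, `NA` unlabelled).
#' @slot harmonized logical flag set by [harmonizeLabels()].
#' @export
setClass("VariantDataset",
  representation(
    variantId  = "character",
    gene       = "character",
    label      = "character",
    scores     = "matrix",
    yClass     = "integer",
    harmonized = "logical"
  )
)

setValidity("VariantDataset", function(object) {
  n <- nrow(object@scores)
  msg <- character(0)
  if (!is.numeric(object@scores)) {
    msg <- c(msg, "scores must be a numeric matrix")
  }
  feats <- colnames(object@scores)
  if (is.null(feats) || !all(feats %in% names(.FEATURE_INFO))) {
    msg <- c(msg, "score columns must be named with canonical feature names")
  } else if (anyDuplicated(feats)) {
    msg <- c(msg, "duplicated feature columns")
  } else {
    rng <- featureRanges(feats)
    for (j in seq_along(feats)) {
      v <- object@scores[, j]
      bad <- which(!is.na(v) & (v < rng["min", j] | v > rng["max", j]))
      if (length(bad)) {
        msg <- c(msg, sprintf("feature '%s' out of range [%g, %g] in row(s) %s",
                              feats[j], rng["min", j], rng["max", j],
                              paste(utils::head(bad, 5), collapse = ", ")))
      }
    }
  }
  if (length(object@variantId) != n) msg <- c(msg, "variantId length != nrow(scores)")
  if (length(object@gene) != n) msg <- c(msg, "gene length != nrow(scores)")
  if (length(object@label) != n) msg <- c(msg, "label length != nrow(scores)")
  if (!all(object@label %in% .LABEL_LEVELS)) {
    msg <- c(msg, paste0("labels must be in {", paste(.LABEL_LEVELS, collapse = ", "), "}"))
  }
  if (length(object@yClass) != n) msg <- c(msg, "yClass length != nrow(scores)")
  if (!all(is.na(object@yClass) | object@yClass %in% c(0L, 1L))) {
    msg <- c(msg, "yClass values must be 0, 1 or NA")
  }
  if (length(object@harmonized) != 1L) msg <- c(msg, "harmonized must be a single logical")
  if (length(msg)) msg else TRUE
})

#' Construct a VariantDataset
#'
#' @param scores Numeric matrix or data.frame of predictor scores with
#'   canonical feature names as column names; `NA` marks missing values.
#' @param variantId Character vector of variant identifiers (defaults to
#'   `var1..varn`).
#' @param gene Character vector (or scalar) of gene symbols.
#' @param label Character vector (or scalar) of clinical assertions.
#' @return A [VariantDataset-class] object (not yet label-harmonized).
#' @export
#' @examples
#' x <- matrix(runif(10), 5, 2, dimnames = list(NULL, c("sift", "revel")))
#' variantDataset(x, label = "VUS")
variantDataset <- function(scores, variantId = NULL, gene = NA_character_,
                           label = "unknown") {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  n <- nrow(scores)
  if (is.null(variantId)) variantId <- paste0("var", seq_len(n))
  new("VariantDataset",
      variantId = as.character(variantId),
      gene = rep_len(as.character(gene), n),
      label = rep_len(.normalize_label(label), n),
      scores = scores,
      yClass = rep(NA_integer_, n),
      harmonized = FALSE)
}

#' PriorSpec: conjugate prior hyperparameters for the mixture model
#'
#' Hyperparameters of the conjugate prior used by the Gibbs sampler: a
#' Dirichlet prior on cluster weights, a multivariate normal prior on
#' cluster means and an inverse-Wishart prior on cluster covariances.
#'
#' @slot alpha numeric length-K Dirichlet concentration (default c(1, 1)).
#' @slot eta numeric length-p prior mean of the cluster means.
#' @slot tau p x p prior covariance of the cluster means (symmetric
#'   positive definite).
#' @slot nu inverse-Wishart degrees of freedom (>= p).
#' @slot psi p x p inverse-Wishart scale matrix (symmetric positive
#'   definite).
#' @slot features character, feature names the prior was built for.
#' @export
setClass("PriorSpec",
  representation(
    alpha    = "numeric",
    eta      = "numeric",
    tau      = "matrix",
    nu       = "numeric",
    psi      = "matrix",
    features = "character"
  )
)

setValidity("PriorSpec", function(object) {
  p <- length(object@eta)
  msg <- character(0)
  if (any(object@alpha <= 0)) msg <- c(msg, "alpha must be strictly positive")
  if (!identical(dim(object@tau), c(p, p))) msg <- c(msg, "tau must be p x p")
  if (!identical(dim(object@psi), c(p, p))) msg <- c(msg, "psi must be p x p")
  if (length(object@nu) != 1L || object@nu < p) msg <- c(msg, "nu must be a scalar >= p")
  ok_spd <- function(S) {
    isTRUE(all.equal(S, t(S), tolerance = 1e-8)) &&
      !inherits(try(chol(S), silent = TRUE), "try-error")
  }
  if (identical(dim(object@tau), c(p, p)) && !ok_spd(object@tau)) {
    msg <- c(msg, "tau must be symmetric positive definite")
  }
  if (identical(dim(object@psi), c(p, p)) && !ok_spd(object@psi)) {
    msg <- c(msg, "psi must be symmetric positive definite")
  }
  if (length(object@features) && length(object@features) != p) {
    msg <- c(msg, "features length must match eta")
  }
  if (length(msg)) msg else TRUE
})

#' GibbsConfig: Markov chain settings for the Gibbs sampler
#'
#' @slot nIter total sweeps.
#' @slot burnIn discarded initial sweeps (< nIter).
#' @slot thin keep every `thin`-th retained sweep (>= 1).
#' @slot seed integer RNG seed.
#' @slot init initialization scheme, `"random"` or `"pca"`
#'   (k-means-like split along the first principal direction).
#' @export
setClass("GibbsConfig",
  representation(
    nIter  = "integer",
    burnIn = "integer",
    thin   = "integer",
    seed   = "integer",
    init   = "character"
  )
)

setValidity("GibbsConfig", function(object) {
  msg <- character(0)
  if (object@burnIn >= object@nIter) msg <- c(msg, "burnIn must be < nIter")
  if (object@burnIn < 0L) msg <- c(msg, "burnIn must be >= 0")
  if (object@thin < 1L) msg <- c(msg, "thin must be >= 1")
  if (!object@init %in% c("random", "pca")) msg <- c(msg, "init must be 'random' or 'pca'")
  if (length(msg)) msg else TRUE
})

#' Construct a GibbsConfig
#'
#' Defaults (20000 sweeps, 5000 burn-in, thinning 5, i.e. 3000 retained
#' draws) give posterior percentiles stable to about two decimals for
#' the problem sizes this package targets.
#'
#' @param nIter Total Gibbs sweeps.
#' @param burnIn Discarded initial sweeps.
#' @param thin Keep every `thin`-th sweep after burn-in.
#' @param seed Integer RNG seed.
#' @param init `"random"` or `"pca"`.
#' @return A [GibbsConfig-class] object.
#' @export
gibbsConfig <- function(nIter = 20000L, burnIn = 5000L, thin = 5L,
                        seed = 1L, init = c("random", "pca")) {
  new("GibbsConfig",
      nIter = as.integer(nIter), burnIn = as.integer(burnIn),
      thin = as.integer(thin), seed = as.integer(seed),
      init = match.arg(init))
}

#' PosteriorDraws: retained Gibbs samples of the mixture parameters
#'
#' After [enforceWeightOrder()] every draw satisfies the identifiability
#' constraint `omega[1] < omega[2]`: cluster 1 is the benign cluster and
#' cluster 2 the pathogenic cluster.
#'
#' @slot omega M x K matrix of cluster weight draws.
#' @slot mu M x K x p array of cluster mean draws.
#' @slot sigma M x K x p x p array of cluster covariance draws.
#' @slot features character length-p feature names.
#' @slot priors the [PriorSpec-class] used.
#' @slot config the [GibbsConfig-class] used.
#' @slot ordered logical, TRUE once the weight constraint was applied.
#' @export
setClass("PosteriorDraws",
  representation(
    omega    = "matrix",
    mu       = "array",
    sigma    = "array",
    features = "character",
    priors   = "PriorSpec",
    config   = "GibbsConfig",
    ordered  = "logical"
  )
)

setValidity("PosteriorDraws", function(object) {
  M <- nrow(object@omega)
  K <- ncol(object@omega)
  p <- length(object@features)
  msg <- character(0)
  if (K != 2L) msg <- c(msg, "only the two-cluster model is supported")
  if (!identical(dim(object@mu), c(M, K, p))) msg <- c(msg, "mu must be M x K x p")
  if (!identical(dim(object@sigma), c(M, K, p, p))) msg <- c(msg, "sigma must be M x K x p x p")
  if (any(abs(rowSums(object@omega) - 1) > 1e-8)) msg <- c(msg, "weights must sum to 1 per draw")
  if (any(object@omega <= 0)) msg <- c(msg, "weights must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' ClassificationResult: posterior-predictive classification of variants
#'
#' @slot variantId character identifiers, aligned with the classified rows.
#' @slot probPathogenic mean posterior-predictive pathogenic
#'   responsibility per variant (in \[0, 1\]).
#' @slot voteFraction fraction of retained draws whose argmax label was
#'   pathogenic.
#' @slot label final label per variant (`"benign"`/`"pathogenic"`), the
#'   mode of the per-draw labels.
#' @slot tie logical, TRUE where the per-draw vote was exactly split
#'   (resolved to pathogenic).
#' @slot nDraws number of retained draws used.
#' @export
setClass("ClassificationResult",
  representation(
    variantId      = "character",
    probPathogenic = "numeric",
    voteFraction   = "numeric",
    label          = "character",
    tie            = "logical",
    nDraws         = "integer"
  )
)

setValidity("ClassificationResult", function(object) {
  n <- length(object@probPathogenic)
  msg <- character(0)
  if (any(object@probPathogenic < -1e-12 | object@probPathogenic > 1 + 1e-12)) {
    msg <- c(msg, "probPathogenic must lie in [0, 1]")
  }
  if (length(object@label) != n || length(object@tie) != n ||
      length(object@voteFraction) != n || length(object@variantId) != n) {
    msg <- c(msg, "all per-variant slots must have equal length")
  }
  if (!all(object@label %in% c("benign", "pathogenic"))) {
    msg <- c(msg, "labels must be 'benign' or 'pathogenic'")
  }
  if (length(msg)) msg else TRUE
})

#' DICResult: deviance information criterion for one fitted model
#'
#' `dic = meanDeviance + pD` with `pD = meanDeviance - plugInDeviance`
#' (Spiegelhalter's effective number of parameters), where deviance is
#' minus twice the observed-data mixture log-likelihood.
#'
#' @slot meanDeviance posterior mean deviance.
#' @slot plugInDeviance deviance at the posterior-mean parameters.
#' @slot pD effective number of parameters.
#' @slot dic the criterion (lower is better).
#' @slot features feature set of the fitted model.
#' @export
setClass("DICResult",
  representation(
    meanDeviance   = "numeric",
    plugInDeviance = "numeric",
    pD             = "numeric",
    dic            = "numeric",
    features       = "character"
  )
)
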