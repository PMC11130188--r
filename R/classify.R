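# Posterior-predictive classification and the SanfilippoPred scoring
# rule. For each retained draw m the responsibility of cluster k for a
# variant x is
#   p_k = omega_k |2 pi Sigma_k|^(-1/2) exp(-(x - mu_k)' Sigma_k^-1 (x - mu_k)/2)
# normalized over k (computed in log space). Per draw the label is the
# argmax over clusters; the final label is the mode over draws.

# log responsibilities (n x K) for one draw
.draw_log_weights <- function(X, omega, mu, sigma) {
  l1 <- log(omega[1]) + .log_dmvnorm(X, mu[1, ], sigma[[1]])
  l2 <- log(omega[2]) + .log_dmvnorm(X, mu[2, ], sigma[[2]])
  cbind(l1, l2)
}

#' Posterior-predictive responsibilities for one draw
#'
#' Probability that each variant belongs to each cluster under a single
#' retained draw's parameters. Computed in log space: even when both
#' component densities underflow, the responsibilities are finite and
#' sum to one.
#'
#' @param X Numeric matrix (or single feature vector) on the model's
#'   feature set, complete.
#' @param draws A [PosteriorDraws-class].
#' @param m Draw index.
#' @return n x 2 matrix of responsibilities (columns benign,
#'   pathogenic), rows summing to 1.
#' @export
posteriorResponsibility <- function(X, draws, m = 1L) {
  stopifnot(is(draws, "PosteriorDraws"))
  X <- rbind(X)
  p <- length(draws@features)
  if (ncol(X) != p) {
    stop("dimension mismatch: model has ", p, " features, x has ", ncol(X),
         call. = FALSE)
  }
  sig <- list(draws@sigma[m, 1L, , ], draws@sigma[m, 2L, , ])
  lw <- .draw_log_weights(X, draws@omega[m, ], rbind(draws@mu[m, 1L, ], draws@mu[m, 2L, ]), sig)
  p1 <- 1 / (1 + exp(lw[, 2] - lw[, 1]))
  out <- cbind(benign = p1, pathogenic = 1 - p1)
  rownames(out) <- NULL
  out
}

#' Classify variants from the posterior predictive distribution
#'
#' For every retained draw the per-variant label is the cluster with the
#' larger responsibility; the final label is the mode of these per-draw
#' labels. The reported pathogenicity probability is the mean pathogenic
#' responsibility across draws. An exactly split vote (possible with an
#' even number of draws) is resolved to pathogenic and flagged, the
#' sensitive choice in a screening context.
#'
#' @param X A [VariantDataset-class] or complete numeric matrix on the
#'   model's feature set.
#' @param draws A weight-ordered [PosteriorDraws-class].
#' @return A [ClassificationResult-class].
#' @export
classifyVariants <- function(X, draws) {
  stopifnot(is(draws, "PosteriorDraws"))
  vid <- NULL
  if (is(X, "VariantDataset")) {
    vid <- X@variantId
    X <- X@scores[, draws@features, drop = FALSE]
  }
  X <- as.matrix(X)
  if (anyNA(X)) {
    stop("X contains missing values; impute first (see pmmImpute)", call. = FALSE)
  }
  p <- length(draws@features)
  if (ncol(X) != p) {
    stop("dimension mismatch: model has ", p, " features, X has ", ncol(X),
         call. = FALSE)
  }
  if (!draws@ordered) draws <- enforceWeightOrder(draws)
  n <- nrow(X)
  M <- nrow(draws@omega)
  sum_p2 <- numeric(n)
  votes_path <- numeric(n)
  for (m in seq_len(M)) {
    r <- posteriorResponsibility(X, draws, m)
    sum_p2 <- sum_p2 + r[, 2]
    votes_path <- votes_path + (r[, 2] >= r[, 1])
  }
  prob <- unname(sum_p2 / M)
  vote_frac <- unname(votes_path / M)
  tie <- unname(votes_path * 2 == M)
  label <- unname(ifelse(votes_path * 2 >= M, "pathogenic", "benign"))
  if (is.null(vid)) vid <- paste0("var", seq_len(n))
  new("ClassificationResult",
      variantId = vid,
      probPathogenic = pmin(pmax(prob, 0), 1),
      voteFraction = vote_frac,
      label = label,
      tie = tie,
      nDraws = as.integer(M))
}

#' SanfilippoPred pathogenicity score
#'
#' Scores one or more variants on the six-feature set SIFT, PolyPhen-2,
#' CADD, REVEL, MetaLR and MutationAssessor with a fitted mixture model,
#' returning a pathogenicity probability and a label with the decision
#' threshold at probability >= 0.50. `mode = "draws"` averages the
#' posterior-predictive responsibilities across all retained draws;
#' `mode = "plug_in"` evaluates a single responsibility at the
#' elementwise posterior medians of the parameters (a centroid-style
#' approximation mirroring a spreadsheet calculator that stores only
#' posterior percentiles).
#'
#' @param x Named feature vector or matrix covering the model's features
#'   (all six scores must be present and non-missing).
#' @param model A weight-ordered [PosteriorDraws-class] fitted on the
#'   prediction features.
#' @param mode `"draws"` or `"plug_in"`.
#' @return A data.frame with columns `probability`, `label` and `tie`.
#' @export
sanfilippoScore <- function(x, model, mode = c("draws", "plug_in")) {
  mode <- match.arg(mode)
  stopifnot(is(model, "PosteriorDraws"))
  X <- rbind(x)
  feats <- model@features
  if (!is.null(colnames(X))) {
    absent <- setdiff(feats, colnames(X))
    if (length(absent)) {
      stop("missing score(s): ", paste(absent, collapse = ", "), call. = FALSE)
    }
    X <- X[, feats, drop = FALSE]
  } else if (ncol(X) != length(feats)) {
    stop("x must cover the model features: ", paste(feats, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(X)) {
    bad <- feats[apply(is.na(X), 2, any)]
    stop("missing score(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!model@ordered) model <- enforceWeightOrder(model)
  if (mode == "draws") {
    res <- classifyVariants(X, model)
    prob <- res@probPathogenic
    tie <- res@tie
    label <- ifelse(prob >= 0.5, "pathogenic", "benign")
  } else {
    med <- .plug_in_parameters(model, stats::median)
    lw <- .draw_log_weights(X, med$omega, med$mu, med$sigma)
    prob <- 1 / (1 + exp(lw[, 1] - lw[, 2]))
    tie <- prob == 0.5
    label <- ifelse(prob >= 0.5, "pathogenic", "benign")
  }
  data.frame(probability = unname(prob), label = unname(label),
             tie = unname(tie), row.names = NULL, stringsAsFactors = FALSE)
}

# Collapse draws to a single parameter block by a columnwise statistic
# (mean for DIC, median for the plug-in score); weights renormalized,
# covariances symmetrized and projected to SPD if needed.
.plug_in_parameters <- function(draws, fun = mean) {
  p <- length(draws@features)
  omega <- apply(draws@omega, 2, fun)
  omega <- omega / sum(omega)
  mu <- rbind(apply(draws@mu[, 1L, , drop = FALSE], 3, fun),
              apply(draws@mu[, 2L, , drop = FALSE], 3, fun))
  sigma <- lapply(1:2, function(k) {
    S <- matrix(apply(draws@sigma[, k, , , drop = FALSE], c(3, 4), fun), p, p)
    .as_spd(S)
  })
  list(omega = omega, mu = mu, sigma = sigma)
}
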