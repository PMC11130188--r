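# Deviance information criterion and DIC-guided backward feature
# elimination. Deviance is minus twice the observed-data mixture
# log-likelihood; pD is Spiegelhalter's effective number of parameters
# (mean deviance minus deviance at the posterior-mean parameters).

#' Observed-data mixture deviance at one parameter block
#'
#' `D(theta) = -2 sum_i log( sum_k omega_k N(x_i; mu_k, Sigma_k) )`,
#' computed in log space.
#'
#' @param X Complete numeric matrix.
#' @param omega Length-2 weight vector.
#' @param mu 2 x p matrix of cluster means.
#' @param sigma List of 2 covariance matrices (positive definite).
#' @return Deviance (finite scalar).
#' @export
computeDeviance <- function(X, omega, mu, sigma) {
  X <- rbind(X)
  lw <- .draw_log_weights(X, omega, mu, sigma)
  -2 * sum(.logsumexp2(lw[, 1], lw[, 2]))
}

#' Deviance information criterion of a fitted mixture
#'
#' `DIC = Dbar + pD` where `Dbar` is the posterior mean deviance over
#' the retained draws and `pD = Dbar - D(thetabar)` with `thetabar` the
#' draw-wise elementwise posterior mean (weights renormalized,
#' covariance means symmetrized and projected to positive definite if
#' needed). Equivalently `DIC = 2 Dbar - D(thetabar)`. Lower is better.
#' Note that DIC values are only loosely comparable across feature sets
#' of different dimension, since the likelihood dimension itself
#' changes; the elimination trace records the values as computed.
#'
#' @param X Complete numeric matrix on the model's feature set.
#' @param draws A [PosteriorDraws-class] with at least 2 retained draws.
#' @return A [DICResult-class].
#' @export
computeDIC <- function(X, draws) {
  stopifnot(is(draws, "PosteriorDraws"))
  M <- nrow(draws@omega)
  if (M < 2L) stop("need at least 2 retained draws for DIC", call. = FALSE)
  X <- as.matrix(X)
  if (is(X, "matrix") && !is.null(colnames(X)) &&
      all(draws@features %in% colnames(X))) {
    X <- X[, draws@features, drop = FALSE]
  }
  dev <- vapply(seq_len(M), function(m) {
    computeDeviance(X, draws@omega[m, ],
                    rbind(draws@mu[m, 1L, ], draws@mu[m, 2L, ]),
                    list(draws@sigma[m, 1L, , ], draws@sigma[m, 2L, , ]))
  }, numeric(1))
  dbar <- mean(dev)
  pl <- .plug_in_parameters(draws, mean)
  dhat <- computeDeviance(X, pl$omega, pl$mu, pl$sigma)
  pd <- dbar - dhat
  new("DICResult", meanDeviance = dbar, plugInDeviance = dhat,
      pD = pd, dic = dbar + pd, features = draws@features)
}

#' Backward feature elimination guided by DIC
#'
#' Greedy backward search for a parsimonious mixture: at each step the
#' model is refitted on every subset obtained by dropping one feature
#' from the current set; the drop yielding the lowest DIC is accepted if
#' that DIC is lower than the current model's, otherwise the search
#' stops. The search also stops when only one feature remains. A refit
#' failure on a subset skips that subset with a warning. Each refit uses
#' a seed derived deterministically from the config seed and the feature
#' subset, so the trace is reproducible.
#'
#' @param X Complete numeric matrix with canonical feature column names.
#' @param features Starting feature set (>= 2 features, all columns of
#'   `X`).
#' @param priorsBuilder Function `X -> PriorSpec` used for every refit
#'   (default [defaultPriors()]).
#' @param config A [GibbsConfig-class] used for every refit.
#' @return An `EliminationTrace`: a list with `steps` (list of
#'   `features`, `dic` ([DICResult-class]), `removed`), `finalFeatures`,
#'   `finalDraws` (fit of the final model), plus a caveat note on
#'   cross-dimension DIC comparison.
#' @export
backwardEliminate <- function(X, features = colnames(X),
                              priorsBuilder = defaultPriors,
                              config = gibbsConfig()) {
  X <- as.matrix(X)
  if (length(features) < 2L) stop("need at least 2 features", call. = FALSE)
  if (!all(features %in% colnames(X))) {
    stop("all features must be columns of X", call. = FALSE)
  }
  fit_subset <- function(feats) {
    Xs <- X[, feats, drop = FALSE]
    cfg <- initialize(config,
                      seed = .stage_seed(config@seed, paste(sort(feats), collapse = "+")))
    draws <- runGibbs(Xs, priorsBuilder(Xs), cfg)
    list(draws = draws, dic = computeDIC(Xs, draws))
  }
  current <- fit_subset(features)
  steps <- list(list(features = features, dic = current$dic, removed = NA_character_))
  repeat {
    feats <- current$dic@features
    if (length(feats) <= 1L) break
    best <- NULL
    for (drop_f in feats) {
      sub <- setdiff(feats, drop_f)
      cand <- tryCatch(fit_subset(sub), error = function(e) {
        warning("refit failed for subset {", paste(sub, collapse = ", "),
                "}: ", conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(cand)) next
      if (is.null(best) || cand$dic@dic < best$dic@dic) {
        best <- cand
        best$removed <- drop_f
      }
    }
    if (is.null(best) || best$dic@dic >= current$dic@dic) break
    current <- best
    steps[[length(steps) + 1L]] <-
      list(features = best$dic@features, dic = best$dic, removed = best$removed)
  }
  structure(list(steps = steps,
                 finalFeatures = current$dic@features,
                 finalDraws = current$draws,
                 note = paste("DIC values are compared across feature sets of",
                              "different dimension; the likelihood dimension",
                              "changes with the set, which this trace records",
                              "but does not correct.")),
            class = "EliminationTrace")
}

#' @export
print.EliminationTrace <- function(x, ...) {
  cat("DIC backward elimination trace:\n")
  for (s in x$steps) {
    cat(sprintf("  {%s}: DIC = %.2f%s\n",
                paste(s$features, collapse = ", "), s$dic@dic,
                if (is.na(s$removed)) "" else paste0("  (removed ", s$removed, ")")))
  }
  cat("final set: {", paste(x$finalFeatures, collapse = ", "), "}\n", sep = "")
  invisible(x)
}
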