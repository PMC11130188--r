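# Predictive mean matching (PMM) by chained equations. Missing score
# cells are replaced by observed donor values whose OLS-predicted means
# are nearest, cycling over incomplete columns.

#' Match donors by predicted mean
#'
#' Inner step of PMM: for each incomplete row, find the `k` observed
#' rows whose regression-predicted means are closest to the incomplete
#' row's predicted mean (ties broken deterministically by row index) and
#' return the observed value of one of them chosen uniformly at random.
#'
#' @param predicted Predicted means for the rows to impute.
#' @param predictedObs Predicted means for the observed rows.
#' @param observed Observed values (same length/order as `predictedObs`).
#' @param k Number of candidate donors (>= 1).
#' @param seed Optional integer seed (set once before the draws).
#' @return Numeric vector of imputed values, one per element of
#'   `predicted`.
#' @export
matchDonors <- function(predicted, predictedObs, observed, k = 5L, seed = NULL) {
  if (length(predictedObs) != length(observed)) {
    stop("predictedObs and observed must have equal length", call. = FALSE)
  }
  if (k < 1L || k > length(observed)) {
    stop("k must be between 1 and the number of observed rows", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  vapply(predicted, function(pm) {
    d <- abs(predictedObs - pm)
    ord <- order(d, seq_along(d))     # tie-break by row index
    cand <- ord[seq_len(k)]
    observed[cand[sample.int(k, 1L)]]
  }, numeric(1))
}

# OLS fit robust to rank deficiency; returns predictions for newx.
.ols_predict <- function(y, x, newx) {
  X <- cbind(1, x)
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  drop(cbind(1, newx) %*% beta)
}

#' Impute missing scores by predictive mean matching
#'
#' Chained-equations imputation: incomplete columns are initialized at
#' their column means, then for a fixed number of cycles each incomplete
#' column is regressed (OLS) on all other columns using its observed
#' rows, and every missing cell is replaced by the observed value of a
#' near-donor via [matchDonors()]. Every imputed value is therefore an
#' actually observed value of its own column, and observed cells are
#' never changed. With `nImputations > 1` a list of completed datasets
#' is returned; downstream pooling is the caller's concern.
#'
#' @param ds A [VariantDataset-class] or numeric matrix.
#' @param donors Number of candidate donors per missing cell.
#' @param cycles Number of passes over the incomplete columns.
#' @param nImputations Number of completed datasets to generate.
#' @param seed Integer seed for reproducibility.
#' @return Completed object of the same type as `ds` (or a list of them
#'   when `nImputations > 1`).
#' @export
pmmImpute <- function(ds, donors = 5L, cycles = 5L, nImputations = 1L,
                      seed = 1L) {
  stopifnot(donors >= 1L, cycles >= 1L, nImputations >= 1L)
  is_vd <- is(ds, "VariantDataset")
  X <- if (is_vd) ds@scores else as.matrix(ds)
  miss <- is.na(X)
  n_obs <- colSums(!miss)
  dead <- colnames(X)[n_obs == 0L]
  if (length(dead)) {
    stop("column(s) entirely missing, cannot impute: ",
         paste(dead, collapse = ", "), call. = FALSE)
  }
  short <- colnames(X)[n_obs < donors & colSums(miss) > 0L]
  if (length(short)) {
    stop("fewer observed values than donors in column(s): ",
         paste(short, collapse = ", "), call. = FALSE)
  }
  set.seed(as.integer(seed))
  wrap <- function(Xc) {
    if (is_vd) { out <- ds; out@scores <- Xc; out } else Xc
  }
  if (!any(miss)) {
    res <- replicate(nImputations, wrap(X), simplify = FALSE)
    return(if (nImputations == 1L) res[[1L]] else res)
  }
  run_one <- function() {
    Xc <- X
    mu <- colMeans(X, na.rm = TRUE)
    for (j in which(colSums(miss) > 0L)) Xc[miss[, j], j] <- mu[j]
    target_cols <- which(colSums(miss) > 0L)
    for (cycle in seq_len(cycles)) {
      for (j in target_cols) {
        obs <- !miss[, j]
        others <- Xc[, -j, drop = FALSE]
        pred_obs <- .ols_predict(X[obs, j], others[obs, , drop = FALSE], others[obs, , drop = FALSE])
        pred_mis <- .ols_predict(X[obs, j], others[obs, , drop = FALSE], others[!obs, , drop = FALSE])
        Xc[!obs, j] <- matchDonors(pred_mis, pred_obs, X[obs, j], k = donors)
      }
    }
    Xc
  }
  res <- replicate(nImputations, wrap(run_one()), simplify = FALSE)
  if (nImputations == 1L) res[[1L]] else res
}
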