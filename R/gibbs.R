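# The two-component Bayesian Gaussian mixture and its Gibbs sampler.
#
# Model: x_i | z_i = k ~ N(mu_k, Sigma_k), z_i ~ Categorical(omega),
# with conjugate priors omega ~ Dirichlet(alpha), mu_k ~ N(eta, tau),
# Sigma_k ~ inverse-Wishart(nu, psi). The sampler cycles the full
# conditionals assignments -> weights -> means -> covariances. Label
# switching is resolved post hoc by the ordering constraint
# omega[1] < omega[2]; cluster 1 is interpreted as the benign cluster
# and cluster 2 as the pathogenic cluster.

.K <- 2L

#' Data-driven default priors
#'
#' Empirical-Bayes style defaults: the prior mean of the cluster means
#' is the overall mean vector of the data and its prior covariance is
#' the overall sample covariance scaled by `tauScale` (default 10, i.e.
#' a deliberately wide prior); the inverse-Wishart degrees of freedom
#' equal the number of features and its scale matrix is the sample
#' covariance of the whole data; cluster weights get a flat
#' Dirichlet(1, 1). A near-singular sample covariance (e.g. a constant
#' column) is regularized with a small relative ridge. Scores are
#' modelled on their raw scales; no standardization is applied.
#'
#' @param X Numeric matrix (variants x features), complete (imputed).
#' @param tauScale Multiplier applied to the sample covariance to form
#'   the prior covariance of the cluster means.
#' @param ridge Relative ridge used if the sample covariance is
#'   numerically singular.
#' @return A [PriorSpec-class].
#' @export
defaultPriors <- function(X, tauScale = 10, ridge = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (anyNA(X)) stop("X must be complete; impute first", call. = FALSE)
  if (n <= p) stop("need more rows than features to build default priors", call. = FALSE)
  S <- .as_spd(stats::cov(X), ridge)
  feats <- colnames(X)
  new("PriorSpec",
      alpha = c(1, 1),
      eta = colMeans(X),
      tau = .symmetrize(tauScale * S),
      nu = p,
      psi = S,
      features = if (is.null(feats)) character(0) else feats)
}

#' Initialize the Gibbs sampler state
#'
#' `init = "random"` assigns rows to the two clusters uniformly at
#' random; `init = "pca"` splits along the first principal direction by
#' 1-d k-means (useful when the clusters are well separated). If an
#' initial cluster is too small the assignment is re-drawn (up to 100
#' times). Parameters are then drawn from one conditional sweep given
#' the initial assignments.
#'
#' @param X Complete numeric matrix.
#' @param priors A [PriorSpec-class].
#' @param config A [GibbsConfig-class]; its seed is set before drawing.
#' @return A list with elements `z`, `omega`, `mu` (K x p), `sigma`
#'   (list of K covariance matrices).
#' @export
initState <- function(X, priors, config = gibbsConfig()) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  set.seed(config@seed)
  min_size <- min(p + 2L, n %/% 2L)
  if (min_size < 1L) stop("too few rows to initialize two clusters", call. = FALSE)
  if (config@init == "pca") {
    v1 <- svd(scale(X, scale = FALSE), nu = 0, nv = 1)$v[, 1]
    pc1 <- drop(scale(X, scale = FALSE) %*% v1)
    km <- stats::kmeans(pc1, centers = 2L, nstart = 5L)
    z <- as.integer(km$cluster)
    if (min(tabulate(z, .K)) < min_size) z <- NULL
  } else {
    z <- NULL
  }
  if (is.null(z)) {
    for (attempt in 1:100) {
      z <- sample.int(.K, n, replace = TRUE)
      if (min(tabulate(z, .K)) >= min_size) break
      z <- NULL
    }
    if (is.null(z)) {
      stop("could not initialize: a cluster had fewer than ", min_size,
           " members after 100 attempts", call. = FALSE)
    }
  }
  omega <- drop(.rdirichlet(1L, priors@alpha + tabulate(z, .K)))
  mu_plug <- rbind(colMeans(X[z == 1L, , drop = FALSE]),
                   colMeans(X[z == 2L, , drop = FALSE]))
  sigma <- sampleCovariances(X, z, mu_plug, priors)
  mu <- sampleMeans(X, z, sigma, priors)
  list(z = z, omega = omega, mu = mu, sigma = sigma)
}

#' Gibbs conditional: cluster assignments
#'
#' Draws each `z_i` categorically with probability proportional to
#' `omega_k * N(x_i; mu_k, Sigma_k)`, with responsibilities normalized
#' in log space so that simultaneous density underflow never produces
#' NaN. Consumes exactly `n` uniform variates, in row order.
#'
#' @param X Complete numeric matrix.
#' @param state List with `omega`, `mu` (K x p), `sigma` (list of K).
#' @return Integer assignment vector in {1, 2}.
#' @export
sampleAssignments <- function(X, state) {
  X <- as.matrix(X)
  l1 <- log(state$omega[1]) + .log_dmvnorm(X, state$mu[1, ], state$sigma[[1]])
  l2 <- log(state$omega[2]) + .log_dmvnorm(X, state$mu[2, ], state$sigma[[2]])
  p1 <- 1 / (1 + exp(l2 - l1))
  # both-underflow safety: log-space difference is always finite here
  ifelse(stats::runif(nrow(X)) < p1, 1L, 2L)
}

#' Gibbs conditional: cluster weights
#'
#' Draws the weight vector from its Dirichlet full conditional
#' `Dirichlet(alpha_1 + n_1, alpha_2 + n_2)`.
#'
#' @param z Integer assignment vector in {1, 2}.
#' @param alpha Dirichlet concentration (length 2).
#' @return Numeric weight vector summing to 1.
#' @export
sampleWeights <- function(z, alpha = c(1, 1)) {
  drop(.rdirichlet(1L, alpha + tabulate(z, .K)))
}

#' Gibbs conditional: cluster means
#'
#' Draws each cluster mean from its multivariate normal full
#' conditional, with posterior precision `tau^-1 + n_k Sigma_k^-1` and
#' matching mean. An empty cluster falls back to a draw from the prior.
#'
#' @param X Complete numeric matrix.
#' @param z Integer assignment vector.
#' @param sigma List of K current covariance matrices.
#' @param priors A [PriorSpec-class].
#' @return K x p matrix of cluster means.
#' @export
sampleMeans <- function(X, z, sigma, priors) {
  X <- as.matrix(X)
  p <- ncol(X)
  tau_inv <- .spd_inverse(priors@tau)
  mu <- matrix(0, .K, p)
  for (k in 1:.K) {
    idx <- which(z == k)
    n_k <- length(idx)
    if (n_k == 0L) {
      mu[k, ] <- .rmvn1(priors@eta, priors@tau)
      next
    }
    sig_inv <- .spd_inverse(sigma[[k]])
    prec <- tau_inv + n_k * sig_inv
    V <- .as_spd(.spd_inverse(prec))
    xbar <- colMeans(X[idx, , drop = FALSE])
    m <- V %*% (tau_inv %*% priors@eta + n_k * (sig_inv %*% xbar))
    mu[k, ] <- .rmvn1(drop(m), V)
  }
  mu
}

#' Gibbs conditional: cluster covariances
#'
#' Draws each cluster covariance from its inverse-Wishart full
#' conditional `IW(nu + n_k, psi + S_k)` where `S_k` is the centered
#' scatter of the cluster's rows around `mu_k`. An empty cluster yields
#' a draw from the prior. Every draw is symmetric positive definite.
#'
#' @param X Complete numeric matrix.
#' @param z Integer assignment vector.
#' @param mu K x p matrix of current cluster means.
#' @param priors A [PriorSpec-class].
#' @return List of K covariance matrices.
#' @export
sampleCovariances <- function(X, z, mu, priors) {
  X <- as.matrix(X)
  lapply(1:.K, function(k) {
    idx <- which(z == k)
    n_k <- length(idx)
    if (n_k == 0L) return(.rinvwishart(priors@nu, priors@psi))
    D <- sweep(X[idx, , drop = FALSE], 2L, mu[k, ])
    .rinvwishart(priors@nu + n_k, .symmetrize(priors@psi + crossprod(D)))
  })
}

#' Enforce the weight-ordering identifiability constraint
#'
#' Reorders every retained draw so that `omega[1] < omega[2]`, swapping
#' the full parameter block (weight, mean, covariance) where needed.
#' Under the model's a-priori assumption that benign variants are the
#' minority cluster among VUS, cluster 1 is benign and cluster 2
#' pathogenic. An exact weight tie is broken by the cluster mean of an
#' anchor feature (default REVEL; the benign cluster takes the lower
#' value).
#'
#' @param draws A [PosteriorDraws-class].
#' @param anchorFeature Feature used to break exact weight ties.
#' @return The reordered [PosteriorDraws-class] (`ordered` flag set).
#' @export
enforceWeightOrder <- function(draws, anchorFeature = "revel") {
  stopifnot(is(draws, "PosteriorDraws"))
  omega <- draws@omega; mu <- draws@mu; sigma <- draws@sigma
  a <- match(anchorFeature, draws@features)
  if (is.na(a)) a <- 1L  # anchor not in the model: first feature
  swap <- omega[, 1] > omega[, 2]
  tie <- omega[, 1] == omega[, 2]
  if (any(tie)) swap[tie] <- mu[tie, 1L, a] > mu[tie, 2L, a]
  for (m in which(swap)) {
    omega[m, ] <- omega[m, 2:1]
    mu[m, , ] <- mu[m, 2:1, ]
    sigma[m, , , ] <- sigma[m, 2:1, , ]
  }
  initialize(draws, omega = omega, mu = mu, sigma = sigma, ordered = TRUE)
}

#' Fit the Bayesian Gaussian mixture by Gibbs sampling
#'
#' Runs the full sampler on a complete (imputed) score matrix: one
#' conditional sweep per iteration in the order assignments -> weights
#' -> means -> covariances, discarding `burnIn` sweeps, thinning, and
#' finally applying the weight-ordering constraint. An empty cluster
#' makes the affected conditionals fall back to prior draws; if a
#' cluster stays empty for more than 50 consecutive sweeps a warning is
#' issued. Reproducible under the config seed.
#'
#' @param X Complete numeric matrix (variants x features) with canonical
#'   feature column names.
#' @param priors A [PriorSpec-class]; defaults to [defaultPriors()].
#' @param config A [GibbsConfig-class].
#' @param anchorFeature Tie-break anchor passed to [enforceWeightOrder()].
#' @return A weight-ordered [PosteriorDraws-class].
#' @export
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(200), ncol = 2), matrix(rnorm(200, 5), ncol = 2))
#' colnames(X) <- c("cadd", "revel")
#' X[, "revel"] <- pmin(pmax(X[, "revel"] / 10 + 0.5, 0), 1)
#' fit <- runGibbs(X, config = gibbsConfig(nIter = 200, burnIn = 100, seed = 1))
#' summarizePosterior(fit)
runGibbs <- function(X, priors = defaultPriors(X), config = gibbsConfig(),
                     anchorFeature = "revel") {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (anyNA(X)) stop("X must be complete; impute first", call. = FALSE)
  if (n <= 2 * (p + 2)) {
    stop("too few rows (need n > 2(p + 2)) for a stable two-cluster fit",
         call. = FALSE)
  }
  validObject(priors)
  validObject(config)
  state <- initState(X, priors, config)  # also sets the seed
  keep <- which(seq_len(config@nIter) > config@burnIn &
                (seq_len(config@nIter) - config@burnIn) %% config@thin == 0L)
  M <- length(keep)
  if (M < 1L) stop("no retained draws; increase nIter", call. = FALSE)
  omega <- matrix(NA_real_, M, .K)
  mu <- array(NA_real_, c(M, .K, p))
  sigma <- array(NA_real_, c(M, .K, p, p))
  m <- 0L
  empty_streak <- 0L
  warned <- FALSE
  for (it in seq_len(config@nIter)) {
    state$z <- sampleAssignments(X, state)
    counts <- tabulate(state$z, .K)
    if (any(counts == 0L)) {
      empty_streak <- empty_streak + 1L
      if (empty_streak > 50L && !warned) {
        warning("a cluster stayed empty for more than 50 consecutive sweeps; ",
                "its parameters are prior draws", call. = FALSE)
        warned <- TRUE
      }
    } else {
      empty_streak <- 0L
    }
    state$omega <- sampleWeights(state$z, priors@alpha)
    state$mu <- sampleMeans(X, state$z, state$sigma, priors)
    state$sigma <- sampleCovariances(X, state$z, state$mu, priors)
    if (it %in% keep) {
      m <- m + 1L
      omega[m, ] <- state$omega
      mu[m, , ] <- state$mu
      for (k in 1:.K) sigma[m, k, , ] <- state$sigma[[k]]
    }
  }
  feats <- colnames(X)
  if (is.null(feats)) feats <- paste0("f", seq_len(p))
  draws <- new("PosteriorDraws", omega = omega, mu = mu, sigma = sigma,
               features = feats, priors = priors, config = config,
               ordered = FALSE)
  enforceWeightOrder(draws, anchorFeature)
}

#' Summarize the posterior draws
#'
#' Per cluster and parameter (the cluster weight and each coordinate of
#' the cluster mean): posterior mean, SD, and empirical 2.5th, 50th and
#' 97.5th percentiles over the retained draws. Requires at least 40
#' retained draws for the extreme percentiles to be meaningful.
#'
#' @param draws A [PosteriorDraws-class].
#' @param minDraws Percentile stability floor.
#' @return A data.frame with columns `cluster` (`benign`/`pathogenic`),
#'   `parameter`, `mean`, `sd`, `q2.5`, `q50`, `q97.5`.
#' @export
summarizePosterior <- function(draws, minDraws = 40L) {
  stopifnot(is(draws, "PosteriorDraws"))
  M <- nrow(draws@omega)
  if (M < minDraws) {
    stop("need at least ", minDraws, " retained draws to summarize percentiles",
         call. = FALSE)
  }
  roles <- c("benign", "pathogenic")
  rows <- list()
  srow <- function(x, cluster, parameter) {
    q <- unname(stats::quantile(x, c(0.025, 0.5, 0.975), type = 7))
    data.frame(cluster = cluster, parameter = parameter,
               mean = mean(x), sd = stats::sd(x),
               q2.5 = q[1], q50 = q[2], q97.5 = q[3],
               stringsAsFactors = FALSE)
  }
  for (k in 1:.K) {
    rows[[length(rows) + 1L]] <- srow(draws@omega[, k], roles[k], "weight")
    for (j in seq_along(draws@features)) {
      rows[[length(rows) + 1L]] <-
        srow(draws@mu[, k, j], roles[k], draws@features[j])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
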