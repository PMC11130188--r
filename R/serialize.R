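# JSON serialization of posterior draw containers, with enough metadata
# (features, priors, chain settings, package version) to reload and
# reuse a fitted model.

#' Save posterior draws to JSON
#'
#' Full-precision, versioned JSON container with the draws, the prior
#' hyperparameters and the chain configuration.
#'
#' @param draws A [PosteriorDraws-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
savePosteriorDraws <- function(draws, path) {
  stopifnot(is(draws, "PosteriorDraws"))
  pr <- draws@priors
  cfg <- draws@config
  obj <- list(
    container = "SanfilippoPred.PosteriorDraws",
    version = as.character(utils::packageVersion("SanfilippoPred")),
    features = draws@features,
    ordered = draws@ordered,
    priors = list(alpha = pr@alpha, eta = pr@eta, tau = pr@tau,
                  nu = pr@nu, psi = pr@psi),
    config = list(nIter = cfg@nIter, burnIn = cfg@burnIn, thin = cfg@thin,
                  seed = cfg@seed, init = cfg@init),
    omega = draws@omega,
    mu = draws@mu,
    sigma = draws@sigma)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load posterior draws from JSON
#'
#' @param path Path written by [savePosteriorDraws()].
#' @return A [PosteriorDraws-class].
#' @export
loadPosteriorDraws <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$container, "SanfilippoPred.PosteriorDraws")) {
    stop("not a posterior draws container: ", path, call. = FALSE)
  }
  p <- length(obj$features)
  priors <- new("PriorSpec",
                alpha = obj$priors$alpha,
                eta = obj$priors$eta,
                tau = matrix(unlist(obj$priors$tau), p, p),
                nu = obj$priors$nu,
                psi = matrix(unlist(obj$priors$psi), p, p),
                features = obj$features)
  cfg <- gibbsConfig(obj$config$nIter, obj$config$burnIn, obj$config$thin,
                     obj$config$seed, obj$config$init)
  M <- nrow(obj$omega)
  new("PosteriorDraws",
      omega = as.matrix(obj$omega),
      mu = array(unlist(obj$mu), c(M, 2L, p)),
      sigma = array(unlist(obj$sigma), c(M, 2L, p, p)),
      features = obj$features,
      priors = priors, config = cfg,
      ordered = isTRUE(obj$ordered))
}
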