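# Small generators shared across test files.

# Two well-separated Gaussian blobs with unequal weights (weight
# identifiability requires omega1 != omega2).
make_blobs <- function(n = 400, p = 2, sep = 6, w1 = 0.35, seed = 1,
                       sd = 1) {
  set.seed(seed)
  z <- 1L + (stats::runif(n) >= w1)
  mu <- rbind(rep(0, p), rep(sep, p))
  X <- mu[z, , drop = FALSE] + matrix(stats::rnorm(n * p, 0, sd), n, p)
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, z = z, mu = mu, w = c(w1, 1 - w1))
}

# A tiny labelled variant table written to a temp file.
write_toy_table <- function(path, sep = ",", n = 3) {
  header <- paste(c("variant_id", "gene", "label", "sift", "revel"), collapse = sep)
  rows <- vapply(seq_len(n), function(i) {
    paste(c(sprintf("v%d", i), "NAGLU",
            c("VUS", "benign", "pathogenic")[(i - 1) %% 3 + 1],
            sprintf("%.3f", i / (n + 1)), sprintf("%.3f", 1 - i / (n + 2))),
          collapse = sep)
  }, character(1))
  writeLines(c(header, rows), path)
  path
}

# Minimal hand-built PosteriorDraws object for classification tests.
toy_draws <- function(omega = c(0.4, 0.6), mu1 = c(0, 0), mu2 = c(4, 4),
                      s = 1, M = 1, features = c("f1", "f2")) {
  p <- length(mu1)
  om <- matrix(rep(omega, each = M), M, 2)
  mu <- array(0, c(M, 2, p))
  sg <- array(0, c(M, 2, p, p))
  for (m in seq_len(M)) {
    mu[m, 1, ] <- mu1; mu[m, 2, ] <- mu2
    sg[m, 1, , ] <- diag(s, p); sg[m, 2, , ] <- diag(s, p)
  }
  pr <- new("PriorSpec", alpha = c(1, 1), eta = rep(0, p), tau = diag(p),
            nu = p, psi = diag(p), features = features)
  new("PosteriorDraws", omega = om, mu = mu, sigma = sg,
      features = features, priors = pr,
      config = gibbsConfig(nIter = 10, burnIn = 5, thin = 1, seed = 1),
      ordered = TRUE)
}
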