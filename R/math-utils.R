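# Internal numerical helpers: multivariate normal log-density via
# Cholesky, samplers for the conjugate draws, and safe SPD handling.
# CADD/Grantham scales dwarf the [0,1] scores, so covariance handling
# uses relative ridges rather than absolute ones.

# Cholesky with escalating relative ridge; used wherever near-singular
# covariance estimates can appear (constant columns, tiny clusters).
.chol_safe <- function(S, ridge = 1e-6) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  scale <- mean(diag(S))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  eps <- ridge * scale
  for (i in 1:12) {
    ch <- tryCatch(chol(S + diag(eps, nrow(S))), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
    eps <- eps * 10
  }
  stop("matrix is numerically singular and could not be regularized", call. = FALSE)
}

.symmetrize <- function(S) (S + t(S)) / 2

# Nearest usable SPD version of S: symmetrize, then ridge until the
# Cholesky succeeds.
.as_spd <- function(S, ridge = 1e-6) {
  S <- .symmetrize(S)
  ch <- .chol_safe(S, ridge)
  crossprod(ch)
}

.spd_inverse <- function(S) {
  chol2inv(.chol_safe(S))
}

# Rows of X: log N(x; mu, Sigma). Returns length-n vector.
.log_dmvnorm <- function(X, mu, Sigma) {
  X <- rbind(X)
  p <- length(mu)
  ch <- .chol_safe(Sigma)
  z <- backsolve(ch, t(X) - mu, transpose = TRUE)
  -0.5 * colSums(z * z) - sum(log(diag(ch))) - 0.5 * p * log(2 * pi)
}

# One draw from N(mu, Sigma).
.rmvn1 <- function(mu, Sigma) {
  ch <- .chol_safe(Sigma)
  drop(mu + crossprod(ch, stats::rnorm(length(mu))))
}

# n draws from Dirichlet(alpha), n x K.
.rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  g <- matrix(stats::rgamma(n * K, shape = rep(alpha, each = n)), n, K)
  g / rowSums(g)
}

# One draw from inverse-Wishart(nu, Psi); E[X] = Psi / (nu - p - 1).
.rinvwishart <- function(nu, Psi) {
  W <- stats::rWishart(1, df = nu, Sigma = .spd_inverse(Psi))[, , 1]
  .as_spd(.spd_inverse(W))
}

# log(exp(a) + exp(b)) columnwise for two length-n vectors.
.logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

# Deterministic 32-bit FNV-1a hash of a string; used for stage seed
# fan-out and config hashing.
.fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit multiply by 16777619 without overflow, via split arithmetic
    lo <- (h %% 65536) * 16777619
    hi <- (h %/% 65536) * 16777619 %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  h
}

# Derive a stage-specific seed (< 2^31) from a global seed and a label.
.stage_seed <- function(seed, stage) {
  as.integer(.fnv1a(paste(seed, stage, sep = ":")) %% 2147483646) + 1L
}
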