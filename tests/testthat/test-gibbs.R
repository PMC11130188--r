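test_that("default priors are the data moments with the stated scalings", {
  set.seed(5)
  X <- matrix(rnorm(2e4), ncol = 2, dimnames = list(NULL, c("f1", "f2")))
  pr <- defaultPriors(X)
  expect_equal(pr@alpha, c(1, 1))
  expect_lt(max(abs(pr@eta)), 0.05)                    # eta ~ (0, 0)
  expect_lt(max(abs(pr@psi - diag(2))), 0.05)          # psi ~ identity
  expect_equal(pr@tau, 10 * pr@psi, tolerance = 1e-10) # tau = 10 x cov
  expect_equal(pr@nu, 2)                               # nu = p
  # p = 8 case
  X8 <- matrix(rnorm(160), ncol = 8)
  colnames(X8) <- sanfilippoFeatures()
  expect_equal(defaultPriors(X8)@nu, 8)
  # constant column: jittered scale matrix still factorizable
  Xc <- cbind(f1 = rnorm(100), f2 = rep(1, 100))
  expect_silent(chol(defaultPriors(Xc)@psi))
  # tau_scale switch
  expect_equal(defaultPriors(X, tauScale = 0.1)@tau, 0.1 * pr@psi,
               tolerance = 1e-10)
})

test_that("initialization is seeded, keeps both clusters and tracks blobs under pca init", {
  b <- make_blobs(n = 100, seed = 2)
  pr <- defaultPriors(b$X)
  cfg <- gibbsConfig(nIter = 10, burnIn = 5, thin = 1, seed = 42)
  s1 <- initState(b$X, pr, cfg)
  s2 <- initState(b$X, pr, cfg)
  expect_identical(s1, s2)
  expect_setequal(unique(s1$z), 1:2)
  # tiny n random init still yields both labels
  tiny <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("f1", "f2")))
  st <- initState(tiny, defaultPriors(rbind(tiny, tiny)), cfg)
  expect_setequal(unique(st$z), 1:2)
  # pca init recovers well-separated blobs up to relabeling
  sp <- initState(b$X, pr, gibbsConfig(nIter = 10, burnIn = 5, thin = 1,
                                       seed = 3, init = "pca"))
  agree <- max(mean(sp$z == b$z), mean(sp$z == 3L - b$z))
  expect_gte(agree, 0.95)
})

test_that("assignment conditional matches the closed-form responsibility", {
  # 1D: omega = (.5, .5), mu = (0, 4), var 1, x = 1 -> P(z=1) = 1/(1+e^-4)
  state <- list(omega = c(0.5, 0.5), mu = matrix(c(0, 4), 2, 1),
                sigma = list(matrix(1), matrix(1)))
  X <- matrix(rep(1, 1e4), ncol = 1)
  set.seed(8)
  z <- sampleAssignments(X, state)
  expect_equal(mean(z == 1L), 1 / (1 + exp(-4)), tolerance = 0.01)
  # symmetric components: uniform assignment
  state$mu <- matrix(c(0, 0), 2, 1)
  set.seed(9)
  z <- sampleAssignments(X, state)
  expect_equal(mean(z == 1L), 0.5, tolerance = 0.02)
  # near-certain assignment at a well-separated component mean
  state <- list(omega = c(0.5, 0.5), mu = matrix(c(0, 10), 2, 1),
                sigma = list(matrix(0.01), matrix(0.01)))
  set.seed(10)
  z <- sampleAssignments(matrix(rep(0, 1e4), ncol = 1), state)
  expect_gt(mean(z == 1L), 0.999)
})

test_that("weight conditional is the Dirichlet posterior", {
  set.seed(11)
  # n1 = 10, n2 = 30, alpha = (1, 1): E[w1] = 11/42
  z <- rep(1:2, c(10, 30))
  w <- replicate(1e5, sampleWeights(z)[1])
  expect_equal(mean(w), 11 / 42, tolerance = 0.005)
  # symmetric counts: mean weight one half
  z <- rep(1:2, c(20, 20))
  w <- replicate(1e5, sampleWeights(z)[1])
  expect_equal(mean(w), 0.5, tolerance = 0.005)
})

test_that("mean conditional matches the conjugate closed form and the prior when empty", {
  # 1D: prior N(0, 10), n_k = 10, ybar = 5, sigma^2 = 1
  # posterior mean 50/10.1, variance 1/10.1
  pr <- new("PriorSpec", alpha = c(1, 1), eta = 0, tau = matrix(10),
            nu = 1, psi = matrix(1), features = "f1")
  X <- matrix(rep(5, 20), ncol = 1)
  z <- rep(1:2, each = 10)
  sigma <- list(matrix(1), matrix(1))
  set.seed(12)
  d <- replicate(1e4, sampleMeans(X, z, sigma, pr)[1, 1])
  expect_equal(mean(d), 50 / 10.1, tolerance = 0.01)
  # relative MC error of a variance over 1e4 draws is sqrt(2/M) ~ 1.4%
  expect_equal(var(d), 1 / 10.1, tolerance = 0.05)
  # empty cluster draws from the prior (KS test at alpha = 0.01)
  z_empty <- rep(1L, 20)
  set.seed(13)
  d2 <- replicate(5e3, sampleMeans(X, z_empty, sigma, pr)[2, 1])
  expect_gt(stats::ks.test(d2, "pnorm", 0, sqrt(10))$p.value, 0.01)
  # concentration on the sample mean as n_k grows
  sd_at <- vapply(c(100, 10000), function(nk) {
    Xn <- matrix(rep(5, nk), ncol = 1)
    zn <- rep(1L, nk)
    set.seed(nk)
    stats::sd(replicate(500, sampleMeans(Xn, zn, sigma, pr)[1, 1]))
  }, numeric(1))
  expect_equal(sd_at[1] / sd_at[2], 10, tolerance = 3)
})

test_that("covariance conditional matches inverse-Wishart moments and stays SPD", {
  # empty cluster: prior draw with E[Sigma] = Psi / (nu - p - 1)
  p <- 2
  Psi <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  pr <- new("PriorSpec", alpha = c(1, 1), eta = rep(0, p), tau = diag(p),
            nu = 5, psi = Psi, features = c("f1", "f2"))
  X <- matrix(rnorm(20), 10, 2)
  z <- rep(1L, 10)
  mu <- matrix(0, 2, 2)
  set.seed(14)
  S <- array(0, c(p, p))
  M <- 1e4
  for (i in seq_len(M)) {
    draw <- sampleCovariances(X, z, mu, pr)[[2]]
    S <- S + draw / M
  }
  expect_equal(S, Psi / (5 - p - 1), tolerance = 0.05 * max(Psi))
  # p = 1 reduces to inverse-gamma: E = psi / (nu - 2)
  pr1 <- new("PriorSpec", alpha = c(1, 1), eta = 0, tau = matrix(1),
             nu = 4, psi = matrix(3), features = "f1")
  set.seed(15)
  m1 <- mean(replicate(1e4, sampleCovariances(matrix(0), 1L,
                                              matrix(0, 2, 1), pr1)[[2]][1, 1]))
  expect_equal(m1, 3 / (4 - 2), tolerance = 0.05 * 1.5)
  # every posterior draw passes a Cholesky factorization
  set.seed(16)
  zz <- rep(1:2, each = 5)
  for (i in 1:50) {
    for (Sk in sampleCovariances(X, zz, mu, pr)) expect_silent(chol(Sk))
  }
})

test_that("weight ordering constraint swaps whole parameter blocks consistently", {
  d <- toy_draws(omega = c(0.7, 0.3), mu1 = c(9, 9), mu2 = c(0, 0), M = 2)
  d@ordered <- FALSE
  o <- enforceWeightOrder(d)
  expect_equal(drawWeights(o)[1, ], c(0.3, 0.7))
  expect_equal(drawMeans(o)[1, 1, ], c(0, 0))   # mu swapped with omega
  expect_equal(drawMeans(o)[1, 2, ], c(9, 9))
  # already ordered draws unchanged
  d2 <- toy_draws(omega = c(0.3, 0.7), M = 1)
  o2 <- enforceWeightOrder(d2)
  expect_equal(drawWeights(o2), drawWeights(d2))
  expect_equal(drawMeans(o2), drawMeans(d2))
  # exact tie: anchor feature decides (benign = lower anchor value)
  d3 <- toy_draws(omega = c(0.5, 0.5), mu1 = c(5, 5), mu2 = c(0, 0), M = 1,
                  features = c("revel", "cadd"))
  o3 <- enforceWeightOrder(d3)
  expect_equal(drawMeans(o3)[1, 1, 1], 0)
})

test_that("the sampler recovers known mixture parameters and is seed-deterministic", {
  b <- make_blobs(n = 400, p = 2, sep = 6, w1 = 0.35, seed = 21)
  cfg <- gibbsConfig(nIter = 1200, burnIn = 400, thin = 2, seed = 5)
  fit <- runGibbs(b$X, config = cfg)
  s <- summarizePosterior(fit)
  w1_hat <- s$mean[s$cluster == "benign" & s$parameter == "weight"]
  expect_lt(abs(w1_hat - 0.35), 0.05)
  for (k in 1:2) {
    cl <- c("benign", "pathogenic")[k]
    mu_hat <- s$mean[s$cluster == cl & s$parameter != "weight"]
    expect_lt(max(abs(mu_hat - b$mu[k, ])), 0.3)
  }
  fit2 <- runGibbs(b$X, config = cfg)
  expect_identical(drawWeights(fit), drawWeights(fit2))
  expect_identical(drawMeans(fit), drawMeans(fit2))
  # every retained draw satisfies the invariants
  expect_true(all(abs(rowSums(drawWeights(fit)) - 1) < 1e-12))
  expect_true(all(drawWeights(fit)[, 1] < drawWeights(fit)[, 2] |
                  drawWeights(fit)[, 1] == drawWeights(fit)[, 2]))
  sg <- drawCovariances(fit)
  for (m in seq_len(5)) for (k in 1:2) expect_silent(chol(sg[m, k, , ]))
  expect_error(runGibbs(b$X[1:5, ], config = cfg), "too few rows")
})

test_that("posterior summaries match injected draw distributions", {
  # degenerate posterior: all draws identical
  d <- toy_draws(omega = c(0.4, 0.6), M = 50)
  s <- summarizePosterior(d)
  expect_equal(s$sd, rep(0, nrow(s)))
  expect_equal(s$q2.5, s$q97.5)
  expect_equal(s$mean[s$parameter == "weight"], c(0.4, 0.6))
  # injected standard normal draws: percentiles at the normal quantiles
  d2 <- toy_draws(M = 1e4)
  set.seed(30)
  d2@mu[, 1, 1] <- rnorm(1e4)
  s2 <- summarizePosterior(d2)
  row <- s2[s2$cluster == "benign" & s2$parameter == "f1", ]
  expect_equal(row$q2.5, qnorm(0.025), tolerance = 0.06)
  expect_equal(row$q50, 0, tolerance = 0.05)
  expect_equal(row$q97.5, qnorm(0.975), tolerance = 0.06)
  expect_equal(row$sd, 1, tolerance = 0.05)
  # summary layout: mean/SD plus the three percentiles per cluster
  expect_named(s2, c("cluster", "parameter", "mean", "sd", "q2.5", "q50", "q97.5"))
  expect_error(summarizePosterior(toy_draws(M = 10)), "at least 40")
})

test_that("row permutation leaves posterior summaries unchanged up to MC noise", {
  b <- make_blobs(n = 200, p = 2, sep = 6, w1 = 0.3, seed = 33)
  cfg <- gibbsConfig(nIter = 1500, burnIn = 500, thin = 1, seed = 17)
  f1 <- runGibbs(b$X, config = cfg)
  set.seed(1); perm <- sample.int(nrow(b$X))
  f2 <- runGibbs(b$X[perm, ], config = gibbsConfig(nIter = 1500, burnIn = 500,
                                                   thin = 1, seed = 91))
  s1 <- summarizePosterior(f1); s2 <- summarizePosterior(f2)
  M <- nDraws(f1)
  for (i in seq_len(nrow(s1))) {
    mc_se <- sqrt(s1$sd[i]^2 + s2$sd[i]^2) / sqrt(M / 10)  # conservative ESS
    expect_lt(abs(s1$mean[i] - s2$mean[i]), max(3 * mc_se, 1e-6))
  }
})
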