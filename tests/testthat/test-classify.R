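test_that("responsibilities match closed forms and normalize in log space", {
  # equidistant point under equal weights and covariances -> (0.5, 0.5)
  d <- toy_draws(omega = c(0.5, 0.5), mu1 = c(0, 0), mu2 = c(4, 4))
  r <- posteriorResponsibility(c(2, 2), d)
  expect_equal(unname(r[1, ]), c(0.5, 0.5))
  # 1D closed form: omega (.5,.5), mu (0,4), var 1, x = 1 -> 1/(1+e^-4)
  d1 <- toy_draws(omega = c(0.5, 0.5), mu1 = 0, mu2 = 4, features = "f1")
  r1 <- posteriorResponsibility(matrix(1), d1)
  expect_equal(unname(r1[1, 1]), 1 / (1 + exp(-4)), tolerance = 1e-12)
  # extreme point: both densities underflow, responsibilities still sum to 1
  rx <- posteriorResponsibility(c(1e4, 1e4), d)
  expect_false(anyNA(rx))
  expect_equal(unname(rowSums(rx)), 1)
  expect_error(posteriorResponsibility(c(1, 2, 3), d), "dimension mismatch")
})

test_that("per-draw responsibilities always normalize and the mean probability is their mean", {
  b <- make_blobs(n = 120, sep = 5, w1 = 0.3, seed = 4)
  fit <- runGibbs(b$X, config = gibbsConfig(nIter = 300, burnIn = 100,
                                            thin = 2, seed = 2))
  probs <- vapply(seq_len(nDraws(fit)), function(m) {
    r <- posteriorResponsibility(b$X[1:10, ], fit, m)
    expect_equal(unname(rowSums(r)), rep(1, 10), tolerance = 1e-12)
    r[, 2]
  }, numeric(10))
  res <- classifyVariants(b$X[1:10, ], fit)
  expect_equal(pathogenicProbability(res), unname(rowMeans(probs)),
               tolerance = 1e-12)
  expect_true(all(pathogenicProbability(res) >= 0 &
                  pathogenicProbability(res) <= 1))
})

test_that("classification takes the mode over draws, with pathogenic tie-break", {
  # M = 1: the mode is that draw's argmax
  d <- toy_draws(omega = c(0.4, 0.6), M = 1)
  res <- classifyVariants(rbind(c(0, 0), c(4, 4)), d)
  expect_equal(predictedLabels(res), c("benign", "pathogenic"))
  # split vote over 2 draws: benign under draw 1, pathogenic under draw 2
  d2 <- toy_draws(omega = c(0.4, 0.6), M = 2)
  d2@mu[2, 1, ] <- c(4, 4)  # swap roles in draw 2
  d2@mu[2, 2, ] <- c(0, 0)
  res2 <- classifyVariants(rbind(c(0, 0)), d2)
  expect_equal(predictedLabels(res2), "pathogenic")
  expect_true(res2@tie)
  # missing values direct the user to imputation
  expect_error(classifyVariants(rbind(c(NA, 1)), d), "impute")
  # draw order invariance
  b <- make_blobs(n = 100, sep = 5, w1 = 0.3, seed = 7)
  fit <- runGibbs(b$X, config = gibbsConfig(nIter = 200, burnIn = 100,
                                            thin = 1, seed = 3))
  rev_idx <- rev(seq_len(nDraws(fit)))
  fit_rev <- initialize(fit, omega = drawWeights(fit)[rev_idx, ],
                        mu = drawMeans(fit)[rev_idx, , , drop = FALSE],
                        sigma = drawCovariances(fit)[rev_idx, , , , drop = FALSE])
  expect_equal(pathogenicProbability(classifyVariants(b$X, fit)),
               pathogenicProbability(classifyVariants(b$X, fit_rev)),
               tolerance = 1e-12)
})

test_that("points at a fitted centroid classify as their own cluster with confidence", {
  b <- make_blobs(n = 300, sep = 6, w1 = 0.35, seed = 19)
  fit <- runGibbs(b$X, config = gibbsConfig(nIter = 600, burnIn = 200,
                                            thin = 2, seed = 23))
  s <- summarizePosterior(fit)
  path_centroid <- s$q50[s$cluster == "pathogenic" & s$parameter != "weight"]
  ben_centroid <- s$q50[s$cluster == "benign" & s$parameter != "weight"]
  res <- classifyVariants(rbind(path_centroid, ben_centroid), fit)
  expect_equal(predictedLabels(res), c("pathogenic", "benign"))
  expect_gt(pathogenicProbability(res)[1], 0.9)
  expect_lt(pathogenicProbability(res)[2], 0.1)
})

test_that("classification accuracy on well-separated mixtures exceeds 0.95", {
  b <- make_blobs(n = 400, p = 3, sep = 4, w1 = 0.3, seed = 29)  # >= 4 sd apart
  fit <- runGibbs(b$X, config = gibbsConfig(nIter = 600, burnIn = 200,
                                            thin = 2, seed = 31))
  res <- classifyVariants(b$X, fit)
  acc <- mean((predictedLabels(res) == "pathogenic") == (b$z == 2L))
  expect_gte(acc, 0.95)
})

test_that("deviance matches hand computations and is additive and order-invariant", {
  # single point at mu_1, w = (1, 0)-ish, 1D unit variance: D = log(2 pi)
  om <- c(1 - 1e-12, 1e-12)
  mu <- matrix(c(0, 50), 2, 1)
  sg <- list(matrix(1), matrix(1))
  expect_equal(computeDeviance(matrix(0), om, mu, sg), log(2 * pi),
               tolerance = 1e-9)
  set.seed(40)
  X <- matrix(rnorm(30), ncol = 1)
  d1 <- computeDeviance(X, c(0.4, 0.6), mu, sg)
  expect_equal(computeDeviance(rbind(X, X), c(0.4, 0.6), mu, sg), 2 * d1)
  expect_equal(computeDeviance(X[sample.int(30), , drop = FALSE],
                               c(0.4, 0.6), mu, sg), d1)
})

test_that("DIC satisfies its identities and the effective-parameter oracle", {
  # all draws identical -> pD = 0, dic = plug-in deviance
  d <- toy_draws(omega = c(0.4, 0.6), M = 5)
  X <- rbind(c(0, 0), c(4, 4), c(1, 2))
  r <- computeDIC(X, d)
  expect_equal(r@pD, 0, tolerance = 1e-9)
  expect_equal(r@dic, r@plugInDeviance, tolerance = 1e-9)
  expect_equal(r@dic, r@meanDeviance + r@pD, tolerance = 1e-12)
  expect_equal(r@dic, 2 * r@meanDeviance - r@plugInDeviance, tolerance = 1e-9)
  # 1D known-variance conjugate model: pD ~ 1
  pds <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 200
    y <- rnorm(n, 1, 1)
    # posterior for the mean under N(0, 100) prior, known variance 1
    post_var <- 1 / (1 / 100 + n)
    post_mean <- post_var * sum(y)
    M <- 400
    mus <- rnorm(M, post_mean, sqrt(post_var))
    d1 <- toy_draws(omega = c(0.5, 0.5), mu1 = 0, mu2 = 0, M = M,
                    features = "f1")
    d1@mu[, 1, 1] <- mus
    d1@mu[, 2, 1] <- mus   # both clusters identical: a single-Gaussian model
    computeDIC(matrix(y), d1)@pD
  }, numeric(1))
  expect_equal(mean(pds), 1, tolerance = 0.2)
})

test_that("backward elimination keeps informative features and respects the floor", {
  set.seed(50)
  n <- 250
  z <- 1L + (runif(n) < 0.6)
  mu <- rbind(c(0.2, 0.2), c(0.8, 0.8))
  X <- cbind(fA = mu[z, 1] + rnorm(n, 0, 0.15),
             fB = mu[z, 2] + rnorm(n, 0, 0.15),
             n1 = rnorm(n), n2 = rnorm(n))
  cfg <- gibbsConfig(nIter = 500, burnIn = 200, thin = 1, seed = 6)
  tr <- backwardEliminate(X, config = cfg)
  expect_s3_class(tr, "EliminationTrace")
  expect_true(all(c("fA", "fB") %in% tr$finalFeatures))
  expect_lt(length(tr$finalFeatures), 4)
  # each step removes exactly one feature
  sizes <- vapply(tr$steps, function(s) length(s$features), integer(1))
  expect_equal(diff(sizes), rep(-1L, length(sizes) - 1L))
  # two informative features only: floor of one feature is respected,
  # and the trace never goes below it
  tr2 <- backwardEliminate(X[, c("fA", "fB")], config = cfg)
  expect_gte(length(tr2$finalFeatures), 1)
  expect_error(backwardEliminate(X[, "fA", drop = FALSE], config = cfg),
               "at least 2")
})

test_that("the scoring rule thresholds the pathogenicity probability at 0.50", {
  set.seed(60)
  n <- 300
  z <- 1L + (runif(n) >= 0.4)
  cents <- defaultCentroids()[, predictionFeatures()]
  sds <- defaultClusterSds()[, predictionFeatures()]
  X <- t(vapply(z, function(k) rnorm(6, cents[k, ], sds[k, ]), numeric(6)))
  colnames(X) <- predictionFeatures()
  fit <- runGibbs(X, config = gibbsConfig(nIter = 500, burnIn = 200,
                                          thin = 2, seed = 61))
  s <- summarizePosterior(fit)
  path_med <- s$q50[s$cluster == "pathogenic" & s$parameter != "weight"]
  ben_med <- s$q50[s$cluster == "benign" & s$parameter != "weight"]
  probe <- rbind(path_med, ben_med)
  colnames(probe) <- predictionFeatures()
  for (mode in c("draws", "plug_in")) {
    sc <- sanfilippoScore(probe, fit, mode = mode)
    expect_equal(sc$label, c("pathogenic", "benign"))
    expect_gte(sc$probability[1], 0.5)
    expect_lt(sc$probability[2], 0.5)
  }
  # draws and plug-in agree away from the boundary
  sc_d <- sanfilippoScore(X[1:20, ], fit, mode = "draws")
  sc_p <- sanfilippoScore(X[1:20, ], fit, mode = "plug_in")
  clear <- abs(sc_d$probability - 0.5) > 0.45
  expect_true(all(sc_d$label[clear] == sc_p$label[clear]))
  # a missing score is named in the error
  bad <- probe[1, , drop = FALSE]
  bad[1, "cadd"] <- NA
  expect_error(sanfilippoScore(bad, fit), "cadd")
  expect_error(sanfilippoScore(probe[, -3, drop = FALSE], fit), "cadd")
})
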