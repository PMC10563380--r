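test_that("robit link follows the t-CDF closed form", {
  expect_equal(robit_prob(c(0, 0, 0, 0, 0), 5, 0.7, -0.2), 0.5)
  expect_equal(robit_prob(c(0.3, 0.5, 0.2, 0.1, -0.1), 4, 1, -1),
               pt(0.3 + 0.5 - 0.2 + 0.1 - 0.1, df = 4))
  expect_error(robit_prob(rep(0, 5), -1, 0, 0), "positive")
})

test_that("robit with v near 7 approximates the logistic curve", {
  x <- seq(-4, 4, by = 0.1)
  # scaled logistic: match slopes at 0
  s <- dt(0, 7) * 4
  logistic <- plogis(x * 4 * dt(0, 7))
  expect_lt(max(abs(pt(x, df = 7) - logistic)), 0.01)
})

test_that("robit converges to the probit curve as v grows", {
  x <- seq(-4, 4, by = 0.1)
  expect_lt(max(abs(pt(x, df = 1e6) - pnorm(x))), 1e-4)
})

test_that("posterior sampling is seed-deterministic", {
  g <- dose_grid(c(0.08, 0.16, 0.24, 0.32, 0.40), c(0.08, 0.16, 0.24))
  doses <- local_set(g, c(2, 2))$B
  n <- matrix(0L, 5, 3); y <- matrix(0L, 5, 3)
  n[doses] <- 6L; y[doses] <- 3L
  set.seed(99)
  f1 <- eff_posterior(n, y, doses, g, iters = 400L, burnin = 100L)
  set.seed(99)
  f2 <- eff_posterior(n, y, doses, g, iters = 400L, burnin = 100L)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$qbar, f2$qbar)
})

test_that("prior-only fit gives probabilities strictly inside (0,1)", {
  g <- dose_grid(c(0.08, 0.16, 0.24, 0.32, 0.40), c(0.08, 0.16, 0.24))
  doses <- local_set(g, c(2, 2))$B
  n <- y <- matrix(0L, 5, 3)
  set.seed(4)
  f <- eff_posterior(n, y, doses, g, iters = 2000L, burnin = 500L)
  expect_true(all(f$qbar > 0 & f$qbar < 1))
  # prior predictive mean at the centered dose: Monte Carlo from the prior
  pr <- eff_prior()
  m <- 20000
  v <- abs(rt(m, df = runif(m, pr$adf, pr$bdf)))
  eta <- rnorm(m, pr$mu_alpha, sqrt(pr$sd2_alpha))  # dA = dB = 0 cell
  want <- mean(pt(eta, df = v))
  expect_lt(abs(f$qbar["3,2"] - want), 0.05)
})

test_that("posterior recovers a known robit surface at large n", {
  g <- dose_grid(c(0.08, 0.16, 0.24, 0.32, 0.40), c(0.08, 0.16, 0.24))
  doses <- local_set(g, c(2, 2))$B
  theta <- c(0.2, 0.6, 0.4, -0.3, -0.2)
  truth <- robit_prob(theta, 7, g$stdA[doses[, 1]], g$stdB[doses[, 2]])
  n <- y <- matrix(0L, 5, 3)
  n[doses] <- 200L
  set.seed(1)
  y[doses] <- rbinom(nrow(doses), 200L, truth)
  f <- eff_posterior(n, y, doses, g, iters = 4000L, burnin = 1500L)
  expect_true(all(abs(f$qbar - truth) < 0.05))
})

test_that("monotone-generated data yields monotone posterior means", {
  g <- dose_grid(c(0.08, 0.16, 0.24, 0.32, 0.40), c(0.08, 0.16, 0.24))
  doses <- as.matrix(expand.grid(1:5, 1:3))
  truth <- robit_prob(c(0, 0.9, 0.7, 0, 0), 7,
                      g$stdA[doses[, 1]], g$stdB[doses[, 2]])
  n <- y <- matrix(0L, 5, 3)
  n[doses] <- 150L
  set.seed(32)
  y[doses] <- rbinom(nrow(doses), 150L, truth)
  f <- eff_posterior(n, y, doses, g, iters = 3000L, burnin = 1000L)
  q <- matrix(NA_real_, 5, 3); q[doses] <- f$qbar
  expect_true(all(apply(q, 2, diff) > -0.02))
  expect_true(all(apply(t(q), 2, diff) > -0.02))
})

test_that("futility flags concentrate on genuinely inactive doses", {
  g <- dose_grid(c(0.08, 0.16, 0.24, 0.32, 0.40), c(0.08, 0.16, 0.24))
  doses <- local_set(g, c(2, 2))$B
  n <- y <- matrix(0L, 5, 3)
  n[2, 2] <- 20L  # 0/20 responders at the current dose
  set.seed(8)
  f <- eff_posterior(n, y, doses, g, iters = 2000L, burnin = 500L)
  flags <- futility_eliminate(f, n, phiE = 0.2, cutoff = 0.9, min_n = 3L)
  idx <- which(doses[, 1] == 2 & doses[, 2] == 2)
  expect_true(flags[idx])
  # untried doses are never flagged regardless of the posterior
  expect_true(all(!flags[-idx]))
  # posterior mass entirely above phiE: not futile
  y[2, 2] <- 18L
  set.seed(8)
  f2 <- eff_posterior(n, y, doses, g, iters = 2000L, burnin = 500L)
  expect_false(any(futility_eliminate(f2, n, phiE = 0.2, cutoff = 0.9)))
})

test_that("posterior is invariant to the storage order of the dose set", {
  g <- dose_grid(c(0.08, 0.16, 0.24, 0.32, 0.40), c(0.08, 0.16, 0.24))
  doses <- local_set(g, c(2, 2))$B
  n <- y <- matrix(0L, 5, 3)
  n[doses] <- 12L; y[doses] <- c(1L, 3L, 5L, 2L, 4L, 6L, 3L, 5L, 7L)
  set.seed(77)
  f1 <- eff_posterior(n, y, doses, g, iters = 3000L, burnin = 1000L)
  set.seed(78)
  f2 <- eff_posterior(n, y, doses[9:1, ], g, iters = 3000L, burnin = 1000L)
  expect_lt(max(abs(f1$qbar[names(f2$qbar)] - f2$qbar)), 0.05)
})
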