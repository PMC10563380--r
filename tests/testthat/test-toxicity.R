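test_that("working-model probabilities follow the closed form", {
  sk <- crm_skeleton(0.3, 5, 4, 0.05)
  expect_equal(tox_prob(sk, 4, a = 0), 0.3)
  expect_equal(tox_prob(0.3, 1, a = log(2)), 0.09)
  # strictly increasing in rank for fixed a
  for (a in c(-1, 0, 1.5))
    expect_true(all(diff(tox_prob(sk, 1:5, a)) > 0))
})

test_that("per-ordering posterior matches the dense trapezoid oracle", {
  sk <- crm_skeleton(0.3, 5, 4, 0.05)$probs
  set.seed(11)
  for (rep in 1:100) {
    m <- sample(3:5, 1)
    piA <- sort(sample(sk, m))
    n <- sample(0:12, m, replace = TRUE)
    y <- vapply(n, function(ni) if (ni == 0) 0L else sample(0:ni, 1), 0L)
    got <- locrm:::ordering_posterior(y, n, piA, prior_sd2 = 2)
    want <- oracle_ordering_posterior(y, n, piA, prior_sd2 = 2)
    expect_equal(exp(got$log_marginal), want$marginal, tolerance = 1e-6)
    expect_equal(got$post_mean, want$post_mean, tolerance = 1e-6)
  }
})

test_that("no data gives unit marginal likelihood and prior means", {
  piA <- crm_skeleton(0.3, 3, 2, 0.05)$probs
  got <- locrm:::ordering_posterior(rep(0L, 3), rep(0L, 3), piA)
  expect_equal(got$log_marginal, 0)
  want <- oracle_ordering_posterior(rep(0L, 3), rep(0L, 3), piA)
  expect_equal(got$post_mean, want$post_mean, tolerance = 1e-6)
})

test_that("observing DLTs raises the posterior mean above the prior mean", {
  piA <- crm_skeleton(0.3, 5, 4, 0.05)$probs
  prior <- locrm:::ordering_posterior(rep(0L, 5), rep(0L, 5), piA)$post_mean
  post <- locrm:::ordering_posterior(c(0L, 0L, 3L, 0L, 0L),
                                     c(0L, 0L, 3L, 0L, 0L), piA)$post_mean
  expect_gt(post[3], prior[3])
})

test_that("BMA weights behave as posterior model probabilities", {
  g <- dose_grid(1:5, 1:3)
  n <- y <- matrix(0L, 5, 3)
  # no data: equal weights over the four interior orderings
  f <- tox_bma(n, y, local_set(g, c(2, 2)), target = 0.3)
  expect_equal(f$weights, rep(0.25, 4))
  # single-ordering corner: weight one
  f1 <- tox_bma(n, y, local_set(g, c(1, 3)), target = 0.3)
  expect_equal(f1$weights, 1)
  # random counts: weights sum to one, pbar within per-ordering range
  set.seed(3)
  for (rep in 1:10) {
    n <- matrix(sample(0:9, 15, TRUE), 5, 3)
    y <- matrix(vapply(n, function(ni) if (ni == 0) 0L else sample(0:ni, 1), 0L), 5, 3)
    f <- tox_bma(n, y, local_set(g, c(2, 2)), target = 0.3)
    expect_equal(sum(f$weights), 1)
    expect_true(all(f$weights >= 0))
    lo <- apply(f$per_ordering, 2, min)
    hi <- apply(f$per_ordering, 2, max)
    expect_true(all(f$pbar >= lo - 1e-12 & f$pbar <= hi + 1e-12))
  }
})

test_that("weights concentrate on the data-generating ordering", {
  g <- dose_grid(1:5, 1:3)
  ls <- local_set(g, c(2, 2))
  ords <- enumerate_orderings(ls)
  sk <- crm_skeleton(0.3, 5, 4, 0.05)$probs
  # counts whose empirical rates equal the skeleton under ordering 1
  w1 <- numeric(3)
  for (i in seq_along(c(1, 10, 100))) {
    m <- c(1, 10, 100)[i]
    n <- matrix(0L, 5, 3); y <- matrix(0L, 5, 3)
    n[ls$A] <- 20L * m
    y[ls$A] <- round(sk[ords[[1]]] * 20 * m)
    f <- tox_bma(n, y, ls, target = 0.3)
    w1[i] <- f$weights[1]
  }
  expect_true(all(diff(w1) > 0))
  expect_gt(w1[3], 0.95)
})

test_that("beta-binomial elimination matches closed-form tail probabilities", {
  # 3/3 DLTs: Pr(p > 0.3 | Beta(4,1)) = 1 - 0.3^4 = 0.9919 -> eliminate
  n <- y <- matrix(0L, 5, 3)
  n[2, 2] <- 3L; y[2, 2] <- 3L
  elim <- safety_eliminate(n, y, target = 0.3, cutoff = 0.95)
  expect_true(elim[2, 2])
  expect_equal(1 - pbeta(0.3, 4, 1), 1 - 0.3^4)
  # 0/3: Pr(p > 0.3 | Beta(1,4)) = 0.7^4 = 0.2401 -> keep
  y[2, 2] <- 0L
  expect_false(any(safety_eliminate(n, y, target = 0.3, cutoff = 0.95)))
  expect_equal(1 - pbeta(0.3, 1, 4), 0.7^4)
})

test_that("elimination is upward-closed and monotone in the cutoff", {
  set.seed(5)
  for (rep in 1:20) {
    n <- matrix(sample(0:9, 15, TRUE), 5, 3)
    y <- matrix(vapply(n, function(ni) if (ni == 0) 0L else sample(0:ni, 1), 0L), 5, 3)
    e95 <- safety_eliminate(n, y, 0.3, 0.95)
    e85 <- safety_eliminate(n, y, 0.3, 0.85)
    # upward closure
    for (j in 1:5) for (k in 1:3) {
      if (e95[j, k]) {
        if (j < 5) expect_true(e95[j + 1, k])
        if (k < 3) expect_true(e95[j, k + 1])
      }
    }
    # smaller cutoff eliminates a superset
    expect_true(all(e85 | !e95))
  }
})

test_that("dose with fewer patients than min_n is never eliminated", {
  n <- y <- matrix(0L, 5, 3)
  n[1, 1] <- 2L; y[1, 1] <- 2L
  expect_false(any(safety_eliminate(n, y, 0.3, 0.95, min_n = 3L)))
  expect_true(safety_eliminate(n, y, 0.3, 0.95, min_n = 1L)[1, 1])
})
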