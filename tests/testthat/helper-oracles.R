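# Independent oracles used across the test suite.  These deliberately use
# different algorithms from the package code paths they check.

# Brute-force linear-extension enumeration over a set of dose pairs under
# componentwise dominance, via full permutation search.
oracle_linear_extensions <- function(A) {
  m <- nrow(A)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  ok <- function(ranks) {
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i != j && A[i, 1L] <= A[j, 1L] && A[i, 2L] <= A[j, 2L] &&
          ranks[i] >= ranks[j]) return(FALSE)
    }
    TRUE
  }
  Filter(ok, perms(seq_len(m)))
}

# Dense trapezoid-rule oracle for the per-ordering CRM posterior.
oracle_ordering_posterior <- function(y, n, piA, prior_sd2 = 2,
                                      npts = 20001L) {
  a <- seq(-10, 10, length.out = npts)
  loglik <- vapply(a, function(ai) {
    p <- piA^exp(ai)
    sum(ifelse(y > 0, y * log(p), 0) +
          ifelse(n - y > 0, (n - y) * log1p(-p), 0))
  }, 0)
  f <- exp(loglik) * dnorm(a, 0, sqrt(prior_sd2))
  trap <- function(v) sum((v[-1] + v[-length(v)]) / 2) * diff(a[1:2])
  ml <- trap(f)
  pm <- vapply(seq_along(piA), function(d)
    trap(f * vapply(a, function(ai) piA[d]^exp(ai), 0)) / ml, 0)
  list(marginal = ml, post_mean = pm)
}

# Constrained least-squares oracle for the bivariate isotonic projection,
# solved as a quadratic program (needs pracma).
oracle_biviso <- function(x, w = matrix(1, nrow(x), ncol(x))) {
  J <- nrow(x); K <- ncol(x)
  idx <- function(j, k) (k - 1L) * J + j
  cons <- NULL
  for (j in seq_len(J)) for (k in seq_len(K)) {
    if (j < J) {
      r <- numeric(J * K); r[idx(j, k)] <- 1; r[idx(j + 1L, k)] <- -1
      cons <- rbind(cons, r)
    }
    if (k < K) {
      r <- numeric(J * K); r[idx(j, k)] <- 1; r[idx(j, k + 1L)] <- -1
      cons <- rbind(cons, r)
    }
  }
  # pracma::quadprog minimizes 0.5 x'Cx + d'x subject to A x <= b
  C <- diag(2 * as.vector(w))
  d <- -2 * as.vector(w) * as.vector(x)
  sol <- pracma::quadprog(C, d, A = cons, b = rep(0, nrow(cons)))
  matrix(sol$xmin, J, K)
}

# Uniroot-based transcription of the indifference-interval boundary
# conditions (independent of the closed-form recursion in the package).
oracle_skeleton <- function(target, n_doses, prior_mtd, halfwidth) {
  p <- numeric(n_doses)
  p[prior_mtd] <- target
  if (prior_mtd < n_doses) {
    for (l in prior_mtd:(n_doses - 1L)) {
      a <- uniroot(function(a) p[l]^exp(a) - (target - halfwidth),
                   c(-20, 20), tol = 1e-12)$root
      p[l + 1L] <- uniroot(function(q) q^exp(a) - (target + halfwidth),
                           c(1e-8, 1 - 1e-8), tol = 1e-12)$root
    }
  }
  if (prior_mtd > 1L) {
    for (l in prior_mtd:2L) {
      a <- uniroot(function(a) p[l]^exp(a) - (target + halfwidth),
                   c(-20, 20), tol = 1e-12)$root
      p[l - 1L] <- uniroot(function(q) q^exp(a) - (target - halfwidth),
                           c(1e-8, 1 - 1e-8), tol = 1e-12)$root
    }
  }
  p
}

# The four interior toxicity orderings written out by hand (rank of each
# member of A sorted row-major: (j-1,k), (j,k-1), (j,k), (j,k+1), (j+1,k)).
hardcoded_interior_orderings <- function() {
  list(
    O1 = c(1L, 2L, 3L, 5L, 4L),  # (j-1,k) < (j,k-1) < (j,k) < (j+1,k) < (j,k+1)
    O2 = c(2L, 1L, 3L, 5L, 4L),  # (j,k-1) < (j-1,k) < (j,k) < (j+1,k) < (j,k+1)
    O3 = c(1L, 2L, 3L, 4L, 5L),  # (j-1,k) < (j,k-1) < (j,k) < (j,k+1) < (j+1,k)
    O4 = c(2L, 1L, 3L, 4L, 5L)   # (j,k-1) < (j-1,k) < (j,k) < (j,k+1) < (j+1,k)
  )
}
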