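#' Working-model toxicity probability
#'
#' The empiric one-parameter CRM model: under ordering rank \code{r}, the
#' toxicity probability of a dose is \code{pi(r)^exp(a)} where \code{pi} is
#' the skeleton and \code{a} the model parameter.
#'
#' @param skeleton A \code{\link{crm_skeleton}} (or plain probability vector).
#' @param rank Integer skeleton position(s).
#' @param a Model parameter value.
#' @return Toxicity probabilities in (0, 1).
#' @export
tox_prob <- function(skeleton, rank, a = 0) {
  p <- if (inherits(skeleton, "crm_skeleton")) skeleton$probs else skeleton
  p[rank]^exp(a)
}

# Log-likelihood of local counts under one ordering, vectorized over a.
# piA: skeleton value assigned to each dose of A (dose order), y/n aligned.
tox_loglik <- function(a, y, n, piA) {
  lp <- exp(a) %o% log(piA)                 # length(a) x |A|, log p^e
  drop(lp %*% y + log1p(-exp(lp)) %*% (n - y))
}

# Prior density of the model parameter a.  "normal": a ~ N(0, prior_sd2);
# "exponential": exp(a) ~ Exp(1), i.e. f(a) = exp(a - exp(a)).
tox_prior_density <- function(prior = c("normal", "exponential"),
                              prior_sd2 = 2) {
  prior <- match.arg(prior)
  if (prior == "normal") {
    sd <- sqrt(prior_sd2)
    function(a) stats::dnorm(a, 0, sd)
  } else {
    function(a) exp(a - exp(a))
  }
}

# Posterior quantities for a single ordering: log marginal likelihood and
# posterior-mean toxicity per dose in A, by adaptive quadrature on [-10,10]
# (covers > 7 prior SDs for sigma_a^2 up to 2; the shifted integrand decays
# far faster than the prior tail).
ordering_posterior <- function(y, n, piA, prior_sd2 = 2, prior = "normal",
                               lower = -10, upper = 10, rel.tol = 1e-8) {
  dens <- tox_prior_density(prior, prior_sd2)
  if (sum(n) == 0) {
    pm <- vapply(piA, function(p) prior_mean_tox(p, prior_sd2, prior), 0)
    return(list(log_marginal = 0, post_mean = pm))
  }
  grid <- seq(lower, upper, length.out = 101L)
  shift <- max(tox_loglik(grid, y, n, piA))
  f0 <- function(a) exp(tox_loglik(a, y, n, piA) - shift) * dens(a)
  i0 <- tryCatch(
    stats::integrate(f0, lower, upper, rel.tol = rel.tol,
                     subdivisions = 200L),
    error = function(e) stop("toxicity posterior quadrature failed: ",
                             conditionMessage(e)))
  pm <- vapply(seq_along(piA), function(d) {
    fd <- function(a) exp(tox_loglik(a, y, n, piA) - shift +
                            exp(a) * log(piA[d])) * dens(a)
    stats::integrate(fd, lower, upper, rel.tol = rel.tol,
                     subdivisions = 200L)$value / i0$value
  }, 0)
  list(log_marginal = shift + log(i0$value), post_mean = pm)
}

# Prior mean of pi^exp(a); memoized.
.prior_mean_cache <- new.env(parent = emptyenv())
prior_mean_tox <- function(p, prior_sd2, prior = "normal") {
  key <- paste(p, prior_sd2, prior, sep = "|")
  v <- .prior_mean_cache[[key]]
  if (is.null(v)) {
    dens <- tox_prior_density(prior, prior_sd2)
    v <- stats::integrate(function(a) p^exp(a) * dens(a),
                          -10, 10, rel.tol = 1e-8)$value
    .prior_mean_cache[[key]] <- v
  }
  v
}

#' Local Bayesian-model-averaged toxicity estimates
#'
#' Fits the empiric CRM model separately under every toxicity ordering of
#' the local set \code{A}, weighting the orderings by their posterior model
#' probabilities (equal priors 1/I; weights proportional to marginal
#' likelihoods), and averages the per-ordering posterior-mean toxicity
#' probabilities into \code{pbar}.
#'
#' @param nmat,ymat J x K matrices of patients treated and DLT counts.
#' @param ls A \code{\link{local_set}}.
#' @param target Target toxicity probability phi_T (fixes the skeleton).
#' @param prior_sd2 Prior variance sigma_a^2 of the model parameter.
#' @param halfwidth Indifference-interval halfwidth of the skeleton.
#' @param prior_mtd_rule Where the skeleton anchors the prior MTD guess:
#'   \code{"current_rank"} (default) at the current dose's rank in the
#'   local set, or \code{"n_minus_1"} one position below the top.
#' @param prior Prior family for the model parameter, \code{"normal"}
#'   (default) or \code{"exponential"}.
#' @return An object of class \code{"tox_fit"}: fields \code{A} (dose index
#'   matrix), \code{weights}, \code{per_ordering} (matrix, orderings x
#'   doses), \code{pbar} (named by "j,k"), \code{skeleton}, \code{orderings}.
#' @examples
#' g <- dose_grid(1:5, 1:3)
#' n <- y <- matrix(0L, 5, 3); n[1, 1] <- 3L; y[1, 1] <- 1L
#' tox_bma(n, y, local_set(g, c(1, 1)), target = 0.3)
#' @export
tox_bma <- function(nmat, ymat, ls, target, prior_sd2 = 2,
                    halfwidth = 0.05, prior_mtd_rule = "current_rank",
                    prior = "normal") {
  A <- ls$A
  m <- nrow(A)
  ords <- enumerate_orderings(ls)
  # the current dose's rank is identical across orderings: the number of
  # members of A it dominates (weakly)
  cur_rank <- sum(A[, 1L] <= ls$current[1L] & A[, 2L] <= ls$current[2L])
  sk <- cached_skeleton(target, m,
                        prior_mtd_position(m, prior_mtd_rule, cur_rank),
                        halfwidth)
  y <- ymat[A]
  n <- nmat[A]
  fits <- lapply(ords, function(r)
    ordering_posterior(y, n, sk$probs[r], prior_sd2 = prior_sd2,
                       prior = prior))
  lm <- vapply(fits, `[[`, 0, "log_marginal")
  w <- exp(lm - max(lm))
  w <- w / sum(w)
  pm <- do.call(rbind, lapply(fits, `[[`, "post_mean"))
  pbar <- drop(w %*% pm)
  names(pbar) <- paste(A[, 1L], A[, 2L], sep = ",")
  structure(list(A = A, weights = w, per_ordering = pm, pbar = pbar,
                 skeleton = sk, orderings = ords), class = "tox_fit")
}

#' @export
print.tox_fit <- function(x, ...) {
  cat(sprintf("Local CRM toxicity fit over %d doses, %d ordering(s)\n",
              nrow(x$A), length(x$orderings)))
  cat("  model weights:", paste(sprintf("%.3f", x$weights), collapse = " "),
      "\n  pbar:\n")
  print(round(x$pbar, 3))
  invisible(x)
}

#' Beta-binomial overdose elimination
#'
#' Flags dose combinations as overly toxic when, under an independent
#' Beta(1 + y, 1 + n - y) posterior from a uniform prior on that dose's own
#' DLT rate, \code{Pr(p > target) > cutoff} with at least \code{min_n}
#' patients observed.  The returned elimination set is closed upward: every
#' combination dominating a flagged one is eliminated too.
#'
#' @param nmat,ymat J x K count matrices (patients, DLTs).
#' @param target Toxicity limit phi_T.
#' @param cutoff Posterior probability cutoff c_T (default 0.95).
#' @param min_n Minimum patients at a dose before it can be eliminated.
#' @return J x K logical matrix of eliminated combinations.
#' @examples
#' n <- y <- matrix(0L, 3, 3); n[1, 1] <- y[1, 1] <- 3L
#' safety_eliminate(n, y, target = 0.3)
#' @export
safety_eliminate <- function(nmat, ymat, target, cutoff = 0.95, min_n = 3L) {
  flag <- nmat >= min_n &
    stats::pbeta(target, 1 + ymat, 1 + nmat - ymat, lower.tail = FALSE) >
      cutoff
  upward_closure(flag)
}

# Upward closure under componentwise dominance on the grid.
upward_closure <- function(flag) {
  J <- nrow(flag); K <- ncol(flag)
  for (j in seq_len(J)) for (k in seq_len(K)) {
    if (j > 1L) flag[j, k] <- flag[j, k] || flag[j - 1L, k]
    if (k > 1L) flag[j, k] <- flag[j, k] || flag[j, k - 1L]
  }
  flag
}
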