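#' Robit dose-response probability
#'
#' Efficacy probability under the robit (Student-t link) regression
#' \code{q = F_v(alpha + b1*dA + b2*dB + g1*dA^2 + g2*dB^2)}, where
#' \code{F_v} is the t CDF with \code{v} degrees of freedom.  Small \code{v}
#' gives heavy-tailed, outlier-robust response curves; \code{v} near 7
#' approximates the logistic link and \code{v -> Inf} the probit link.
#'
#' @param theta Numeric vector \code{c(alpha, b1, b2, g1, g2)}.
#' @param v Degrees of freedom of the link, \code{v > 0}.
#' @param dA,dB Standardized dose values (vectors of equal length).
#' @return Efficacy probabilities in (0, 1).
#' @examples
#' robit_prob(c(0, 0.8, 0.8, 0, 0), v = 7, dA = 0, dB = 0)
#' @export
robit_prob <- function(theta, v, dA, dB) {
  if (any(v <= 0)) stop("degrees of freedom v must be positive")
  stats::pt(theta[1L] + theta[2L] * dA + theta[3L] * dB +
              theta[4L] * dA^2 + theta[5L] * dB^2, df = v)
}

#' Hyperparameters of the robit efficacy prior
#'
#' Defaults are weakly informative: coefficients centered at 0 except a
#' positive slope mean (0.8) that favors an increasing dose-response at the
#' start of a trial; variance 1.3 keeps the implied prior on each efficacy
#' probability diffuse; the degrees of freedom are uniform on (2, 10) so the
#' link can range from heavy-tailed to near-logistic.
#'
#' @param mu_alpha,sd2_alpha Intercept prior mean / variance.
#' @param mu_beta,sd2_beta Linear coefficient prior mean / variance.
#' @param mu_gamma,sd2_gamma Quadratic coefficient prior mean / variance.
#' @param adf,bdf Range of the uniform prior on the df hyperparameter of
#'   the half-t prior on \code{v}.
#' @return Named list of hyperparameters.
#' @export
eff_prior <- function(mu_alpha = 0, sd2_alpha = 1.3,
                      mu_beta = 0.8, sd2_beta = 1.3,
                      mu_gamma = 0, sd2_gamma = 1.3,
                      adf = 2, bdf = 10) {
  list(mu_alpha = mu_alpha, sd2_alpha = sd2_alpha,
       mu_beta = mu_beta, sd2_beta = sd2_beta,
       mu_gamma = mu_gamma, sd2_gamma = sd2_gamma,
       adf = adf, bdf = bdf)
}

#' Posterior of the robit efficacy model
#'
#' Samples the posterior of the robit regression parameters
#' \code{(alpha, b1, b2, g1, g2)}, the link degrees of freedom \code{v}
#' (half-t prior) and its df hyperparameter (uniform prior) by adaptive
#' random-walk Metropolis, from binomial response counts on a set of dose
#' combinations.  Returns per-dose posterior-mean efficacy probabilities
#' \code{qbar} and the posterior draws of per-dose probabilities used by the
#' futility rule.
#'
#' Determinism: the sampler uses R's RNG stream, so results are reproducible
#' under \code{set.seed}.
#'
#' @param nmat,ymat J x K matrices of patients and responder counts.
#' @param doses m x 2 integer matrix of dose index pairs to model (e.g. the
#'   local set \code{B}, or all tried doses for the end-of-trial fit).
#' @param grid A \code{\link{dose_grid}} supplying standardized doses.
#' @param prior Hyperparameters from \code{\link{eff_prior}}.
#' @param iters,burnin Total MCMC iterations and burn-in (kept draws are
#'   \code{iters - burnin}).
#' @return An object of class \code{"eff_fit"}: fields \code{doses},
#'   \code{draws} (kept draws; columns alpha, b1, b2, g1, g2, v, df),
#'   \code{qbar} (named by "j,k"), \code{qdraws} (doses x draws matrix),
#'   \code{accept_rate}, \code{diagnostics}.
#' @examples
#' g <- dose_grid(1:3, 1:3)
#' n <- matrix(3L, 3, 3); y <- matrix(1L, 3, 3)
#' set.seed(1)
#' fit <- eff_posterior(n, y, as.matrix(expand.grid(1:3, 1:3)), g,
#'                      iters = 500, burnin = 200)
#' round(fit$qbar, 2)
#' @export
eff_posterior <- function(nmat, ymat, doses, grid, prior = eff_prior(),
                          iters = 3000L, burnin = 1000L) {
  doses <- as.matrix(doses)
  storage.mode(doses) <- "integer"
  dA <- grid$stdA[doses[, 1L]]
  dB <- grid$stdB[doses[, 2L]]
  y <- as.numeric(ymat[doses])
  n <- as.numeric(nmat[doses])
  hyper <- c(prior$mu_alpha, sqrt(prior$sd2_alpha),
             prior$mu_beta, sqrt(prior$sd2_beta),
             prior$mu_gamma, sqrt(prior$sd2_gamma),
             prior$adf, prior$bdf)
  res <- robit_mcmc_cpp(y, n, dA, dB, hyper, as.integer(iters),
                        as.integer(burnin), 0.3)
  draws <- res$draws
  colnames(draws) <- c("alpha", "b1", "b2", "g1", "g2", "v", "df")
  X <- cbind(1, dA, dB, dA^2, dB^2)
  eta <- X %*% t(draws[, 1:5, drop = FALSE])   # doses x draws
  qdraws <- matrix(
    stats::pt(as.vector(eta), df = rep(draws[, "v"], each = nrow(doses))),
    nrow = nrow(doses))
  qbar <- rowMeans(qdraws)
  names(qbar) <- paste(doses[, 1L], doses[, 2L], sep = ",")
  diag_msg <- NULL
  if (res$accept_rate < 0.05 || res$accept_rate > 0.8)
    diag_msg <- sprintf(
      "MCMC acceptance rate %.2f outside [0.05, 0.8] after adaptation",
      res$accept_rate)
  structure(list(doses = doses, draws = draws, qbar = qbar,
                 qdraws = qdraws, accept_rate = res$accept_rate,
                 diagnostics = diag_msg), class = "eff_fit")
}

#' @export
print.eff_fit <- function(x, ...) {
  cat(sprintf(
    "Robit efficacy fit over %d doses (%d kept draws, acceptance %.2f)\n",
    nrow(x$doses), nrow(x$draws), x$accept_rate))
  cat("  qbar:\n")
  print(round(x$qbar, 3))
  if (!is.null(x$diagnostics)) cat("  note:", x$diagnostics, "\n")
  invisible(x)
}

#' Futility elimination
#'
#' Flags modeled dose combinations as futile when the posterior probability
#' that their efficacy rate falls below the lower limit \code{phiE} exceeds
#' \code{cutoff}, provided at least \code{min_n} patients have been treated
#' there.  Futile doses are removed from the trial permanently.
#'
#' @param fit An \code{\link{eff_posterior}} fit.
#' @param nmat J x K matrix of patients treated.
#' @param phiE Lowest acceptable efficacy rate.
#' @param cutoff Posterior probability cutoff c_E (default 0.9).
#' @param min_n Minimum patients at a dose before it can be flagged.
#' @return Logical vector along \code{fit$doses} rows; TRUE = futile.
#' @export
futility_eliminate <- function(fit, nmat, phiE, cutoff = 0.9, min_n = 3L) {
  frac_below <- rowMeans(fit$qdraws < phiE)
  nmat[fit$doses] >= min_n & frac_below > cutoff
}
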