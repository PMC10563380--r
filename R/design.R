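#' LOCRM design configuration
#'
#' Configuration of the toxicity-only local CRM design for locating the
#' maximum tolerated dose combination (MTDC).  Escalation runs over the
#' local set A of the current dose: per-ordering empiric CRM posteriors are
#' model-averaged and the next cohort goes to the admissible dose whose
#' estimated toxicity is closest to \code{phiT}; a beta-binomial overdose
#' rule eliminates overly toxic regions; the final MTDC is chosen from
#' bivariate-isotonic smoothed DLT rates.
#'
#' @param phiT Target toxicity probability (default 0.3).
#' @param cT Overdose-elimination posterior cutoff (default 0.95).
#' @param n_max Maximum sample size (default 51).
#' @param cohort Cohort size (default 3).
#' @param halfwidth Skeleton indifference-interval halfwidth (default 0.05).
#' @param prior_sd2 Prior variance of the CRM model parameter (default 2).
#' @param prior Prior family for the CRM parameter: \code{"normal"} or
#'   \code{"exponential"} (Exp(1) on \code{exp(a)}).
#' @param elim_min_n Minimum patients at a dose before it can be
#'   safety-eliminated (default 3, one cohort).
#' @param prior_mtd_rule Skeleton anchoring rule: \code{"current_rank"}
#'   (default) places the prior MTD guess at the current dose's rank in
#'   the local set; \code{"n_minus_1"} places it one below the top.
#' @param coherence Enforce the coherence restriction: after a cohort with
#'   at least one DLT the next cohort is never assigned to a dose strictly
#'   dominating the current one (default TRUE).
#' @return Object of class \code{"locrm_design"}.
#' @examples
#' locrm_design()
#' @export
locrm_design <- function(phiT = 0.3, cT = 0.95, n_max = 51L, cohort = 3L,
                         halfwidth = 0.05, prior_sd2 = 2,
                         prior = "normal", elim_min_n = 3L,
                         prior_mtd_rule = "current_rank", coherence = TRUE) {
  stopifnot(phiT > 0, phiT < 1, cT > 0, cT < 1, n_max >= cohort)
  structure(list(phiT = phiT, cT = cT, n_max = as.integer(n_max),
                 cohort = as.integer(cohort), halfwidth = halfwidth,
                 prior_sd2 = prior_sd2, prior = prior,
                 elim_min_n = as.integer(elim_min_n),
                 prior_mtd_rule = prior_mtd_rule,
                 coherence = isTRUE(coherence)),
            class = "locrm_design")
}

#' @export
print.locrm_design <- function(x, ...) {
  cat("LOCRM design (MTDC finding)\n")
  cat(sprintf("  target phiT = %.2f, elimination cutoff cT = %.2f\n",
              x$phiT, x$cT))
  cat(sprintf("  N = %d, cohort = %d, skeleton halfwidth = %.2f, sigma_a^2 = %.2f\n",
              x$n_max, x$cohort, x$halfwidth, x$prior_sd2))
  invisible(x)
}

#' LOCRM12 design configuration
#'
#' Configuration of the two-stage phase I/II design for optimizing the
#' biological dose combination (OBDC).  A model-free startup stage escalates
#' quickly until the first DLT (or its budget runs out); the main stage
#' allocates cohorts by combining the local CRM toxicity model with a robit
#' efficacy regression on the extended local set B, balancing exploration
#' and exploitation through the cutoff \code{((N - n) / N)^z}.  Safety and
#' futility are monitored continuously; the final OBDC is the most
#' efficacious tried dose within the isotonic safe set.
#'
#' @param phiT Toxicity upper limit (default 0.35; looser than the MTDC
#'   target to admit slightly toxic but efficacious doses).
#' @param cT Overdose-elimination cutoff (default 0.85).
#' @param phiE Lowest acceptable efficacy rate (default 0.2).
#' @param cE Futility cutoff (default 0.9).
#' @param z Exploration exponent of the allocation cutoff (default 2).
#' @param cohort Cohort size (default 3).
#' @param n_startup Startup-stage budget (default 21).
#' @param n_main Nominal main-stage size N in the allocation cutoff
#'   (default 30).
#' @param n_max Total maximum sample size (default 51).
#' @param halfwidth,prior_sd2,prior,elim_min_n,prior_mtd_rule Toxicity-model
#'   settings as in \code{\link{locrm_design}}.
#' @param eff_prior Hyperparameters from \code{\link{eff_prior}}.
#' @param mcmc_iters,mcmc_burnin Efficacy MCMC iterations and burn-in.
#' @param futility_min_n Minimum patients at a dose before it can be
#'   flagged futile (default 3).
#' @param eff_set Local set for the efficacy model: \code{"B"} (axis +
#'   diagonal neighbors, default) or \code{"A"} (axis neighbors only).
#' @param explore_rule How to pick an untried admissible dose when the
#'   allocation cutoff forces exploration: \code{"max_qbar"} (default) or
#'   \code{"uniform"}.
#' @param final_eff Efficacy estimator for the final OBDC pick:
#'   \code{"model"} (robit fit on all tried doses, default) or
#'   \code{"empirical"} (observed response rates).
#' @param coherence Apply the coherence restriction of
#'   \code{\link{locrm_design}} to the main-stage candidate set.  Default
#'   FALSE: the admissible set already caps estimated toxicity at the local
#'   MTDC and safety elimination runs continuously, so a further
#'   no-escalation-after-DLT restriction makes the design doubly
#'   conservative and skews the exploration-exploitation balance.
#' @return Object of class \code{"locrm12_design"}.
#' @examples
#' locrm12_design()
#' @export
locrm12_design <- function(phiT = 0.35, cT = 0.85, phiE = 0.2, cE = 0.9,
                           z = 2, cohort = 3L, n_startup = 21L,
                           n_main = 30L, n_max = 51L, halfwidth = 0.05,
                           prior_sd2 = 2, prior = "normal",
                           elim_min_n = 3L, prior_mtd_rule = "current_rank",
                           eff_prior = locrm::eff_prior(),
                           mcmc_iters = 3000L, mcmc_burnin = 1000L,
                           futility_min_n = 3L, eff_set = c("B", "A"),
                           explore_rule = c("max_qbar", "uniform"),
                           final_eff = c("model", "empirical"),
                           coherence = FALSE) {
  stopifnot(phiT > 0, phiT < 1, phiE > 0, phiE < 1, z > 0)
  structure(list(phiT = phiT, cT = cT, phiE = phiE, cE = cE, z = z,
                 cohort = as.integer(cohort),
                 n_startup = as.integer(n_startup),
                 n_main = as.integer(n_main), n_max = as.integer(n_max),
                 halfwidth = halfwidth, prior_sd2 = prior_sd2,
                 prior = prior, elim_min_n = as.integer(elim_min_n),
                 prior_mtd_rule = prior_mtd_rule, eff_prior = eff_prior,
                 mcmc_iters = as.integer(mcmc_iters),
                 mcmc_burnin = as.integer(mcmc_burnin),
                 futility_min_n = as.integer(futility_min_n),
                 eff_set = match.arg(eff_set),
                 explore_rule = match.arg(explore_rule),
                 final_eff = match.arg(final_eff),
                 coherence = isTRUE(coherence)),
            class = "locrm12_design")
}

#' @export
print.locrm12_design <- function(x, ...) {
  cat("LOCRM12 design (OBDC optimization)\n")
  cat(sprintf("  phiT = %.2f (cT = %.2f), phiE = %.2f (cE = %.2f), z = %g\n",
              x$phiT, x$cT, x$phiE, x$cE, x$z))
  cat(sprintf("  stages: startup <= %d, main N = %d, total <= %d, cohort %d\n",
              x$n_startup, x$n_main, x$n_max, x$cohort))
  invisible(x)
}
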