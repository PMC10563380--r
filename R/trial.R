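# Shared trial-engine helpers -------------------------------------------

# Random pick among ties with the trial RNG.
pick_random <- function(idx) {
  if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
}

# Argmin |pbar - target| among candidate rows (indices into fit$A);
# ties broken uniformly at random.
closest_to_target <- function(pbar, target, cand) {
  d <- abs(pbar[cand] - target)
  pick_random(cand[d < min(d) + 1e-12])
}

# Fallback when every dose of the local set is inadmissible: de-escalate to
# the nearest admissible dose dominated by the current one (max j + k,
# ties at the lowest drug-A level).  Returns NULL when none exists.
fallback_deescalate <- function(current, admissible) {
  J <- nrow(admissible); K <- ncol(admissible)
  best <- NULL; best_sum <- -1L
  for (j in seq_len(current[1L])) for (k in seq_len(current[2L])) {
    if (admissible[j, k]) {
      if (j + k > best_sum) { best <- c(j, k); best_sum <- j + k }
    }
  }
  best
}

# Deterministic final-selection tie-break: lowest j + k, then lowest j.
tie_break_low <- function(doses) {
  o <- order(doses[, 1L] + doses[, 2L], doses[, 1L])
  doses[o[1L], ]
}

# Isotonic smoothing of observed DLT rates for end-of-trial selection.
# Tried cells carry the Beta(1,1) posterior-mean rate (y + 0.5) / (n + 1) --
# the same posterior the safety rule evaluates -- which slightly penalizes
# sparsely tried doses relative to the raw proportion.  Untried cells get
# rate = phiT with a vanishing weight so they neither distort the fit nor
# matter for selection (untried doses are excluded from candidacy anyway).
isotonic_tox <- function(nmat, ymat, phiT) {
  rates <- ifelse(nmat > 0, (ymat + 0.5) / (nmat + 1), phiT)
  w <- ifelse(nmat > 0, nmat, 1e-6)
  biviso(rates, w)
}

# Pick the candidate whose isotonic rate is closest to the target.  Exactly
# equidistant estimates are common (observed rates are multiples of 1/n, and
# isotonic pooling equalizes whole blocks); following the convention of
# established combination-design implementations, ties are resolved by a
# small index-increasing perturbation of the fitted rates, which prefers the
# dose sitting just below the target (and the higher combination among
# tied below-target blocks) over one the same distance above.
select_closest_iso <- function(fit, cand, target) {
  adj <- fit + 1e-5 * (row(fit) + col(fit))
  d <- abs(adj - target)
  sel <- which(cand & d == min(d[cand]), arr.ind = TRUE)
  sel <- sel[order(sel[, 1L]), , drop = FALSE]
  as.integer(sel[1L, ])
}

# LOCRM ------------------------------------------------------------------

# Coherence filter on candidacy: when the most recent cohort at `current`
# contained at least one DLT, doses strictly dominating the current one are
# not escalation candidates for the next cohort.
coherence_filter <- function(ok, A, current, last_dlt) {
  if (last_dlt > 0L) {
    above <- A[, 1L] >= current[1L] & A[, 2L] >= current[2L] &
      (A[, 1L] + A[, 2L]) > sum(current)
    ok <- ok & !above
  }
  ok
}

# Model-based allocation within the local set A (overdose-eliminated doses
# are excluded from candidacy but their data still enter the fit).
next_dose_locrm <- function(nmat, ymat, current, eliminated, grid, design,
                            last_dlt = 0L) {
  ls <- local_set(grid, current)
  ok <- !eliminated[ls$A]
  if (isTRUE(design$coherence))
    ok <- coherence_filter(ok, ls$A, current, last_dlt)
  if (!any(ok)) {
    return(fallback_deescalate(current, !eliminated & nmat >= 0))
  }
  fit <- tox_bma(nmat, ymat, ls, target = design$phiT,
                 prior_sd2 = design$prior_sd2,
                 halfwidth = design$halfwidth,
                 prior_mtd_rule = design$prior_mtd_rule,
                 prior = design$prior)
  idx <- closest_to_target(fit$pbar, design$phiT, which(ok))
  ls$A[idx, ]
}

# End-of-trial MTDC selection from isotonic rates.
select_mtdc <- function(nmat, ymat, eliminated, phiT) {
  cand <- nmat > 0 & !eliminated
  if (!any(cand)) return(NULL)
  fit <- isotonic_tox(nmat, ymat, phiT)
  select_closest_iso(fit, cand, phiT)
}

#' Run one LOCRM trial
#'
#' Simulates a complete LOCRM trial on a scenario: cohorts start at (1,1),
#' each interim allocation is the admissible local dose whose model-averaged
#' toxicity estimate is closest to the target, overly toxic regions are
#' eliminated by the beta-binomial rule, and the MTDC is selected from
#' bivariate-isotonic smoothed DLT rates at the end.
#'
#' @param scn A \code{\link{scenario}}.
#' @param design A \code{\link{locrm_design}}.
#' @param seed Optional integer seed (trial fully reproducible given it).
#' @return Object of class \code{"locrm_trial"}: \code{selection} (integer
#'   pair or NULL), count matrices \code{n}, \code{yT}, \code{eliminated},
#'   \code{enrolled}, \code{stop_reason} ("max_n" or "toxicity"),
#'   \code{path} (matrix of visited doses).
#' @examples
#' tr <- run_locrm_trial(load_scenario("scenario1"), locrm_design(), seed = 1)
#' tr$selection
#' @export
run_locrm_trial <- function(scn, design = locrm_design(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- scn$grid
  n <- y <- matrix(0L, grid$J, grid$K)
  elim <- matrix(FALSE, grid$J, grid$K)
  current <- c(1L, 1L)
  path <- NULL
  selection <- NULL
  stop_reason <- "max_n"
  repeat {
    path <- rbind(path, current)
    out <- simulate_cohort(scn, current, design$cohort)
    n[current[1L], current[2L]] <- n[current[1L], current[2L]] + design$cohort
    y[current[1L], current[2L]] <- y[current[1L], current[2L]] + out$dlt
    elim <- elim | safety_eliminate(n, y, design$phiT, design$cT,
                                    design$elim_min_n)
    if (elim[1L, 1L]) {
      stop_reason <- "toxicity"
      break
    }
    if (sum(n) >= design$n_max) {
      selection <- select_mtdc(n, y, elim, design$phiT)
      break
    }
    nxt <- next_dose_locrm(n, y, current, elim, grid, design,
                           last_dlt = out$dlt)
    if (is.null(nxt)) {
      stop_reason <- "toxicity"
      break
    }
    current <- nxt
  }
  structure(list(selection = selection, n = n, yT = y, eliminated = elim,
                 enrolled = sum(n), stop_reason = stop_reason,
                 path = path, design = design, scenario = scn$name),
            class = "locrm_trial")
}

#' @export
print.locrm_trial <- function(x, ...) {
  cat(sprintf("%s trial on %s: %d patients, stopped for %s\n",
              if (!is.null(x$yE)) "LOCRM12" else "LOCRM",
              if (is.null(x$scenario)) "scenario" else x$scenario,
              x$enrolled, x$stop_reason))
  if (is.null(x$selection)) cat("  no dose selected\n")
  else cat(sprintf("  selected combination: (%d, %d)\n",
                   x$selection[1L], x$selection[2L]))
  cat("  patients per dose (rows = drug A levels):\n")
  print(x$n)
  invisible(x)
}

# LOCRM12 ----------------------------------------------------------------

# Startup escalation: raise one randomly chosen drug by one level; switch
# to the other drug at a boundary; hold at the top corner.
startup_next <- function(current, grid) {
  can_a <- current[1L] < grid$J
  can_b <- current[2L] < grid$K
  if (!can_a && !can_b) return(current)
  drug <- if (can_a && can_b) pick_random(1:2) else if (can_a) 1L else 2L
  current + if (drug == 1L) c(1L, 0L) else c(0L, 1L)
}

# Admissible set (doses of A with pbar not above the local MTDC's pbar),
# minus eliminated/futile doses.  `ok` = candidacy filter along rows of A.
admissible_set <- function(fit, target, ok) {
  jstar <- closest_to_target(fit$pbar, target, which(ok))
  which(ok & fit$pbar <= fit$pbar[jstar] + 1e-12)
}

# End-of-trial OBDC selection.
select_obdc <- function(nmat, yT, yE, eliminated, futile, grid, design) {
  tried <- nmat > 0
  cand <- tried & !eliminated
  if (!any(cand)) return(NULL)
  fit <- isotonic_tox(nmat, yT, design$phiT)
  mtdc <- select_closest_iso(fit, cand, design$phiT)
  safe <- tried & !eliminated & !futile &
    fit <= fit[mtdc[1L], mtdc[2L]] + 1e-6
  if (!any(safe)) return(NULL)
  if (design$final_eff == "model") {
    doses <- which(tried, arr.ind = TRUE)
    efit <- eff_posterior(nmat, yE, doses, grid, prior = design$eff_prior,
                          iters = design$mcmc_iters,
                          burnin = design$mcmc_burnin)
    qhat <- matrix(NA_real_, grid$J, grid$K)
    qhat[efit$doses] <- efit$qbar
  } else {
    qhat <- ifelse(nmat > 0, yE / pmax(nmat, 1L), NA_real_)
  }
  qmax <- max(qhat[safe])
  ties <- which(safe & qhat > qmax - 1e-12, arr.ind = TRUE)
  as.integer(tie_break_low(ties))
}

#' Run one LOCRM12 trial
#'
#' Simulates a complete two-stage LOCRM12 trial on a scenario with toxicity
#' and efficacy probabilities.  The startup stage escalates one randomly
#' chosen drug per DLT-free cohort until the first DLT or the startup
#' budget; the main stage allocates each cohort by the two-step rule: find
#' the local admissible set from the model-averaged toxicity fit, find its
#' most efficacious member under the robit fit, and either exploit it or
#' explore an untried admissible dose depending on the cutoff
#' \code{((N - n) / N)^z}.  Safety and futility rules can stop the trial
#' with no selection; otherwise the OBDC is selected at the sample-size
#' limit.
#'
#' @param scn A \code{\link{scenario}} with an efficacy matrix.
#' @param design A \code{\link{locrm12_design}}.
#' @param seed Optional integer seed.
#' @return Object of class \code{c("locrm12_trial", "locrm_trial")} with
#'   the fields of \code{\link{run_locrm_trial}} plus \code{yE},
#'   \code{futile}, \code{stage_sizes}.
#' @examples
#' \donttest{
#' tr <- run_locrm12_trial(load_scenario("scenario7"),
#'                         locrm12_design(mcmc_iters = 600,
#'                                        mcmc_burnin = 200), seed = 1)
#' tr$selection
#' }
#' @export
run_locrm12_trial <- function(scn, design = locrm12_design(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(scn$eff_true))
    stop("LOCRM12 requires a scenario with efficacy probabilities")
  grid <- scn$grid
  n <- yT <- yE <- matrix(0L, grid$J, grid$K)
  elim <- futile <- matrix(FALSE, grid$J, grid$K)
  current <- c(1L, 1L)
  path <- NULL
  selection <- NULL
  stop_reason <- NULL
  n_startup <- 0L
  n_main <- 0L
  stage <- "startup"

  treat <- function(dose) {
    out <- simulate_cohort(scn, dose, design$cohort)
    n[dose[1L], dose[2L]] <<- n[dose[1L], dose[2L]] + design$cohort
    yT[dose[1L], dose[2L]] <<- yT[dose[1L], dose[2L]] + out$dlt
    yE[dose[1L], dose[2L]] <<- yE[dose[1L], dose[2L]] + out$response
    path <<- rbind(path, dose)
    out
  }

  # startup stage
  last_dlt <- 0L
  repeat {
    out <- treat(current)
    last_dlt <- out$dlt
    n_startup <- n_startup + design$cohort
    elim <- elim | safety_eliminate(n, yT, design$phiT, design$cT,
                                    design$elim_min_n)
    if (elim[1L, 1L]) { stop_reason <- "toxicity"; break }
    if (out$dlt > 0L || n_startup >= design$n_startup) {
      stage <- "main"
      break
    }
    current <- startup_next(current, grid)
  }

  # main stage
  if (stage == "main") {
    repeat {
      if (sum(n) >= design$n_max) { stop_reason <- "max_n"; break }
      ls <- local_set(grid, current)
      toxfit <- tox_bma(n, yT, ls, target = design$phiT,
                        prior_sd2 = design$prior_sd2,
                        halfwidth = design$halfwidth,
                        prior_mtd_rule = design$prior_mtd_rule,
                        prior = design$prior)
      eff_doses <- if (design$eff_set == "B") ls$B else ls$A
      efit <- eff_posterior(n, yE, eff_doses, grid,
                            prior = design$eff_prior,
                            iters = design$mcmc_iters,
                            burnin = design$mcmc_burnin)
      flags <- futility_eliminate(efit, n, design$phiE, design$cE,
                                  design$futility_min_n)
      futile[efit$doses[flags, , drop = FALSE]] <- TRUE
      if (all(elim | futile)) { stop_reason <- "futility"; break }
      ok <- !elim[ls$A] & !futile[ls$A]
      if (isTRUE(design$coherence))
        ok <- coherence_filter(ok, ls$A, current, last_dlt)
      if (!any(ok)) {
        nxt <- fallback_deescalate(current, !elim & !futile)
        if (is.null(nxt)) { stop_reason <- "futility"; break }
        current <- nxt
        next
      }
      atilde <- admissible_set(toxfit, design$phiT, ok)
      # efficacy estimates aligned with rows of A
      keyA <- paste(ls$A[, 1L], ls$A[, 2L], sep = ",")
      qbarA <- efit$qbar[keyA]
      jdag <- pick_random(atilde[qbarA[atilde] > max(qbarA[atilde]) - 1e-12])
      untried <- atilde[n[ls$A[atilde, , drop = FALSE]] == 0L]
      cutoff <- max(0, (design$n_main - n_main) / design$n_main)^design$z
      if (n[ls$A[jdag, 1L], ls$A[jdag, 2L]] == 0L ||
          length(untried) == 0L || qbarA[jdag] > cutoff) {
        nxt_idx <- jdag
      } else if (design$explore_rule == "max_qbar") {
        nxt_idx <- pick_random(
          untried[qbarA[untried] > max(qbarA[untried]) - 1e-12])
      } else {
        nxt_idx <- pick_random(untried)
      }
      current <- ls$A[nxt_idx, ]
      out <- treat(current)
      last_dlt <- out$dlt
      n_main <- n_main + design$cohort
      elim <- elim | safety_eliminate(n, yT, design$phiT, design$cT,
                                      design$elim_min_n)
      if (elim[1L, 1L]) { stop_reason <- "toxicity"; break }
    }
    if (stop_reason == "max_n")
      selection <- select_obdc(n, yT, yE, elim, futile, grid, design)
  }

  structure(list(selection = selection, n = n, yT = yT, yE = yE,
                 eliminated = elim, futile = futile, enrolled = sum(n),
                 stop_reason = stop_reason, path = path,
                 stage_sizes = c(startup = n_startup, main = n_main),
                 design = design, scenario = scn$name),
            class = c("locrm12_trial", "locrm_trial"))
}
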