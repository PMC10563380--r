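#' Simulate many trials and summarize operating characteristics
#'
#' Replication engine: runs \code{n_trials} independent trials of a design
#' on a scenario with per-trial seeds derived deterministically from
#' \code{base_seed} (a vector of well-separated seeds is drawn once from a
#' stream seeded with \code{base_seed}; consecutive integer seeds are
#' avoided because they yield correlated early Mersenne-Twister output,
#' which visibly correlates the startup phase of neighboring replicates),
#' and aggregates the standard operating characteristics: selection percentage
#' of and mean patient counts at the scenario's target doses (MTDCs for
#' LOCRM, OBDCs and TDCs for LOCRM12) and at overdoses, the early-stopping
#' percentage, and mean enrollment.
#'
#' @param design A \code{\link{locrm_design}} or \code{\link{locrm12_design}}.
#' @param scn A \code{\link{scenario}}.
#' @param n_trials Number of simulated trials.
#' @param base_seed Base seed; trial t runs under \code{base_seed + t}.
#' @return Object of class \code{"locrm_study"}: \code{oc} (named numeric
#'   vector of operating characteristics), \code{sel_pct} (J x K selection
#'   percentage matrix), \code{pts_mean} (J x K mean allocation),
#'   \code{trials} (list of per-trial records: selection, stop reason,
#'   enrollment, allocation), \code{scenario}, \code{design}.
#' @examples
#' st <- run_study(locrm_design(), load_scenario("scenario1"),
#'                 n_trials = 5, base_seed = 1)
#' st$oc
#' @export
run_study <- function(design, scn, n_trials, base_seed = 0L) {
  is12 <- inherits(design, "locrm12_design")
  runner <- if (is12) run_locrm12_trial else run_locrm_trial
  set.seed(base_seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, n_trials)
  trials <- lapply(seq_len(n_trials), function(t)
    runner(scn, design, seed = trial_seeds[t]))

  J <- scn$grid$J; K <- scn$grid$K
  sel_cnt <- matrix(0, J, K)
  pts_sum <- matrix(0, J, K)
  early <- 0L
  enrolled <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    tr <- trials[[i]]
    if (is.null(tr$selection)) early <- early + 1L
    else sel_cnt[tr$selection[1L], tr$selection[2L]] <-
        sel_cnt[tr$selection[1L], tr$selection[2L]] + 1
    pts_sum <- pts_sum + tr$n
    enrolled[i] <- tr$enrolled
  }
  sel_pct <- 100 * sel_cnt / n_trials
  pts_mean <- pts_sum / n_trials

  pct_in <- function(set) if (is.null(set)) NA_real_ else sum(sel_pct[set])
  pts_in <- function(set) if (is.null(set)) NA_real_ else sum(pts_mean[set])
  oc <- c(
    sel_pct_mtdc = pct_in(scn$mtdc),
    pts_mtdc = pts_in(scn$mtdc),
    sel_pct_obdc = pct_in(scn$obdc),
    pts_obdc = pts_in(scn$obdc),
    sel_pct_tdc = pct_in(scn$tdc),
    pts_tdc = pts_in(scn$tdc),
    sel_pct_overdose = pct_in(scn$overdose),
    pts_overdose = pts_in(scn$overdose),
    early_stop_pct = 100 * early / n_trials,
    mean_enrolled = mean(enrolled),
    pts_not_enrolled = design$n_max - mean(enrolled)
  )
  records <- lapply(trials, function(tr) list(
    selection = tr$selection, stop_reason = tr$stop_reason,
    enrolled = tr$enrolled, n = tr$n))
  structure(list(oc = oc, sel_pct = sel_pct, pts_mean = pts_mean,
                 n_trials = n_trials, base_seed = base_seed,
                 trials = records, scenario = scn, design = design),
            class = "locrm_study")
}

#' @export
print.locrm_study <- function(x, ...) {
  is12 <- inherits(x$design, "locrm12_design")
  cat(sprintf("%s study: %d simulated trials on %s\n",
              if (is12) "LOCRM12" else "LOCRM", x$n_trials,
              if (is.null(x$scenario$name)) "scenario" else x$scenario$name))
  oc <- x$oc[!is.na(x$oc)]
  lab <- c(sel_pct_mtdc = "MTDC selection %", pts_mtdc = "patients at MTDCs",
           sel_pct_obdc = "OBDC selection %", pts_obdc = "patients at OBDCs",
           sel_pct_tdc = "TDC selection %", pts_tdc = "patients at TDCs",
           sel_pct_overdose = "overdose selection %",
           pts_overdose = "patients at overdoses",
           early_stop_pct = "early stop %",
           mean_enrolled = "mean enrollment",
           pts_not_enrolled = "patients not enrolled")
  for (nm in names(oc))
    cat(sprintf("  %-22s %6.1f\n", lab[[nm]], oc[[nm]]))
  invisible(x)
}

#' @export
summary.locrm_study <- function(object, ...) {
  print(object)
  cat("  selection % per dose (rows = drug A levels):\n")
  print(round(object$sel_pct, 1))
  cat("  mean patients per dose:\n")
  print(round(object$pts_mean, 1))
  invisible(object$oc)
}

#' @export
plot.locrm_study <- function(x, which = c("selection", "allocation"), ...) {
  which <- match.arg(which)
  m <- if (which == "selection") x$sel_pct else x$pts_mean
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                  xlab = "drug A level", ylab = "drug B level",
                  main = if (which == "selection")
                    "Selection percentage" else "Mean patients treated", ...)
  for (j in seq_len(nrow(m))) for (k in seq_len(ncol(m)))
    graphics::text(j, k, sprintf("%.1f", m[j, k]))
  invisible(x)
}

#' @rdname run_study
#' @param object Design object (for the \code{simulate} methods).
#' @param nsim Number of trials to simulate.
#' @param seed Base seed.
#' @param ... Unused.
#' @export
simulate.locrm_design <- function(object, nsim = 1, seed = 0L, ..., scn) {
  run_study(object, scn, n_trials = nsim, base_seed = seed)
}

#' @rdname run_study
#' @export
simulate.locrm12_design <- function(object, nsim = 1, seed = 0L, ..., scn) {
  run_study(object, scn, n_trials = nsim, base_seed = seed)
}
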