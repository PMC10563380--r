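#' Construct a simulation scenario
#'
#' A scenario fixes the dose grid and the true per-combination toxicity
#' (and optionally efficacy) probabilities that drive outcome generation,
#' together with the toxicity limit used to classify doses when scoring
#' operating characteristics.  Derived dose sets:
#' \itemize{
#'   \item MTDCs: combinations whose true toxicity equals \code{phiT_metric};
#'   \item overdoses: true toxicity above \code{phiT_metric};
#'   \item OBDCs: the maximum-efficacy combinations among the safe doses
#'     (true toxicity at most \code{phiT_metric});
#'   \item TDCs: safe combinations with true efficacy at least
#'     \code{eff_threshold} (default 0.45).
#' }
#'
#' @param grid A \code{\link{dose_grid}}.
#' @param tox_true J x K matrix of true DLT probabilities (row j = drug A
#'   level, column k = drug B level), non-decreasing along both axes.
#' @param eff_true Optional J x K matrix of true response probabilities.
#' @param phiT_metric Toxicity limit defining the dose classes above.
#' @param eff_threshold Efficacy threshold defining TDCs.
#' @param name Optional scenario label.
#' @return Object of class \code{"scenario"} with the fields above plus
#'   logical J x K matrices \code{mtdc}, \code{overdose}, \code{obdc},
#'   \code{tdc} (the last two NULL without efficacy).
#' @export
scenario <- function(grid, tox_true, eff_true = NULL, phiT_metric = 0.3,
                     eff_threshold = 0.45, name = NULL) {
  tox_true <- as.matrix(tox_true)
  if (!all(dim(tox_true) == c(grid$J, grid$K)))
    stop("tox_true must be a J x K matrix matching the grid")
  if (any(tox_true < 0 | tox_true > 1))
    stop("toxicity probabilities must lie in [0, 1]")
  if (any(apply(tox_true, 2, diff) < 0) ||
      any(apply(t(tox_true), 2, diff) < 0))
    stop("tox_true must be non-decreasing along both axes")
  safe <- tox_true <= phiT_metric + 1e-9
  mtdc <- abs(tox_true - phiT_metric) < 1e-9
  overdose <- !safe
  obdc <- tdc <- NULL
  if (!is.null(eff_true)) {
    eff_true <- as.matrix(eff_true)
    if (!all(dim(eff_true) == c(grid$J, grid$K)))
      stop("eff_true must be a J x K matrix matching the grid")
    if (any(eff_true < 0 | eff_true > 1))
      stop("efficacy probabilities must lie in [0, 1]")
    obdc <- matrix(FALSE, grid$J, grid$K)
    if (any(safe)) {
      best <- max(eff_true[safe])
      obdc <- safe & abs(eff_true - best) < 1e-9
    }
    tdc <- safe & eff_true >= eff_threshold - 1e-9
  }
  structure(list(name = name, grid = grid, tox_true = tox_true,
                 eff_true = eff_true, phiT_metric = phiT_metric,
                 eff_threshold = eff_threshold, mtdc = mtdc,
                 overdose = overdose, obdc = obdc, tdc = tdc),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario%s: %d x %d grid, toxicity limit %.2f\n",
              if (!is.null(x$name)) paste0(" ", x$name) else "",
              x$grid$J, x$grid$K, x$phiT_metric))
  cat("  true toxicity (rows = drug A levels):\n")
  print(x$tox_true)
  if (!is.null(x$eff_true)) {
    cat("  true efficacy:\n")
    print(x$eff_true)
    cat(sprintf("  OBDCs: %d, TDCs: %d, ", sum(x$obdc), sum(x$tdc)))
  }
  cat(sprintf("  MTDCs: %d, overdoses: %d\n", sum(x$mtdc), sum(x$overdose)))
  invisible(x)
}

#' Load a scenario from a YAML file
#'
#' Scenario files record, in YAML: \code{name}, \code{rawA}, \code{rawB},
#' \code{phiT_metric}, a \code{tox} matrix given as K rows of J values
#' (drug B level per row, drug A level per column -- the layout of printed
#' scenario tables), and optionally \code{eff} in the same layout and
#' \code{eff_threshold}.
#'
#' @param file Path to the scenario file, or the name of a bundled scenario
#'   (see \code{\link{list_scenarios}}), e.g. \code{"scenario1"}.
#' @return A \code{\link{scenario}}.
#' @examples
#' load_scenario("scenario1")
#' @export
load_scenario <- function(file) {
  if (!file.exists(file)) {
    bundled <- system.file("extdata", "scenarios", paste0(file, ".yaml"),
                           package = "locrm")
    if (nzchar(bundled)) file <- bundled
    else stop("scenario file not found: ", file)
  }
  s <- yaml::read_yaml(file)
  for (f in c("rawA", "rawB", "tox")) {
    if (is.null(s[[f]])) stop("scenario file misses field: ", f)
  }
  grid <- dose_grid(as.numeric(s$rawA), as.numeric(s$rawB))
  parse_mat <- function(rows, what) {
    lens <- lengths(rows)
    if (length(rows) != grid$K || any(lens != grid$J))
      stop(sprintf("%s matrix must have K=%d rows of J=%d values",
                   what, grid$K, grid$J))
    t(do.call(rbind, lapply(rows, as.numeric)))  # -> J x K
  }
  tox <- parse_mat(s$tox, "tox")
  eff <- if (!is.null(s$eff)) parse_mat(s$eff, "eff") else NULL
  scenario(grid, tox, eff,
           phiT_metric = if (!is.null(s$phiT_metric)) s$phiT_metric else 0.3,
           eff_threshold = if (!is.null(s$eff_threshold)) s$eff_threshold
                           else 0.45,
           name = s$name)
}

#' List bundled scenarios
#'
#' @return Character vector of bundled scenario names usable with
#'   \code{\link{load_scenario}}.
#' @export
list_scenarios <- function() {
  dir <- system.file("extdata", "scenarios", package = "locrm")
  sort(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
}

#' Simulate one cohort's outcomes
#'
#' Draws independent binomial DLT and response counts for a cohort treated
#' at one dose, from the scenario's true marginal probabilities.
#'
#' @param scn A \code{\link{scenario}}.
#' @param dose Integer pair \code{c(j, k)}.
#' @param cohort_size Number of patients in the cohort.
#' @return List with \code{dlt} and \code{response} counts (\code{response}
#'   is NA when the scenario has no efficacy matrix).
#' @export
simulate_cohort <- function(scn, dose, cohort_size = 3L) {
  check_dose(scn$grid, dose)
  dlt <- stats::rbinom(1L, cohort_size, scn$tox_true[dose[1L], dose[2L]])
  resp <- if (!is.null(scn$eff_true))
    stats::rbinom(1L, cohort_size, scn$eff_true[dose[1L], dose[2L]])
  else NA_integer_
  list(dlt = dlt, response = resp)
}
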