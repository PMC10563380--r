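#' Standardize raw dose values
#'
#' Centers a vector of raw dose values to mean zero and scales it to unit
#' sample standard deviation (denominator \code{n - 1}).  Standardized doses
#' are the covariates of the robit efficacy model, so that prior variances on
#' the regression coefficients have a scale-free interpretation.
#'
#' @param raw Numeric vector of at least two distinct raw dose values.
#' @return Numeric vector of standardized doses with mean 0 and sample
#'   standard deviation 1.
#' @examples
#' standardize_doses(c(0.08, 0.16, 0.24, 0.32, 0.40))
#' @export
standardize_doses <- function(raw) {
  if (length(raw) < 2L)
    stop("at least two dose values are required for standardization")
  s <- stats::sd(raw)
  if (!is.finite(s) || s == 0)
    stop("dose values are constant; standardization is undefined")
  (raw - mean(raw)) / s
}

#' Dose-combination grid
#'
#' Defines the J x K dose-exploration space of a two-drug combination trial:
#' J ordered levels of drug A crossed with K ordered levels of drug B.  Raw
#' dose values are kept for reporting; standardized values (mean 0, unit
#' sample SD per drug) feed the efficacy regression.
#'
#' @param rawA Strictly increasing raw dose values of drug A (length J).
#' @param rawB Strictly increasing raw dose values of drug B (length K).
#' @return An object of class \code{"dose_grid"} with fields \code{J},
#'   \code{K}, \code{rawA}, \code{rawB}, \code{stdA}, \code{stdB}.
#' @examples
#' dose_grid(c(0.08, 0.16, 0.24, 0.32, 0.40), c(0.08, 0.16, 0.24))
#' @export
dose_grid <- function(rawA, rawB) {
  if (any(diff(rawA) <= 0) || any(diff(rawB) <= 0))
    stop("raw dose values must be strictly increasing")
  J <- length(rawA)
  K <- length(rawB)
  structure(list(
    J = J, K = K,
    rawA = as.numeric(rawA), rawB = as.numeric(rawB),
    stdA = if (J >= 2L) standardize_doses(rawA) else 0,
    stdB = if (K >= 2L) standardize_doses(rawB) else 0
  ), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("Dose grid: %d levels of drug A x %d levels of drug B\n",
              x$J, x$K))
  cat("  drug A:", paste(format(x$rawA), collapse = " "),
      " (std:", paste(format(round(x$stdA, 2)), collapse = " "), ")\n")
  cat("  drug B:", paste(format(x$rawB), collapse = " "),
      " (std:", paste(format(round(x$stdB, 2)), collapse = " "), ")\n")
  invisible(x)
}

# Internal: validate a (j,k) index pair against a grid.
check_dose <- function(grid, dose) {
  j <- dose[1L]; k <- dose[2L]
  if (length(dose) != 2L || j < 1L || j > grid$J || k < 1L || k > grid$K)
    stop(sprintf("dose (%s) is outside the %d x %d grid",
                 paste(dose, collapse = ","), grid$J, grid$K))
  invisible(TRUE)
}
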