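#' Weighted pool-adjacent-violators (non-decreasing)
#'
#' Exact weighted least-squares isotonic regression in one dimension.
#'
#' @param y Numeric vector.
#' @param w Non-negative weights, same length.
#' @return Non-decreasing fitted vector.
#' @export
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 0L) return(y)
  # blocks as (value, weight, size) stacks
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- y[i]; wt[top] <- w[i]; sz[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      tw <- wt[top - 1L] + wt[top]
      val[top - 1L] <- if (tw > 0) (wt[top - 1L] * val[top - 1L] +
                                      wt[top] * val[top]) / tw
                       else (val[top - 1L] + val[top]) / 2
      wt[top - 1L] <- tw
      sz[top - 1L] <- sz[top - 1L] + sz[top]
      top <- top - 1L
    }
  }
  rep(val[seq_len(top)], sz[seq_len(top)])
}

#' Weighted bivariate isotonic regression
#'
#' Weighted least-squares projection of a matrix onto the cone of matrices
#' non-decreasing along both rows and columns (the matrix partial order),
#' computed by Dykstra's alternating-projection algorithm with exact
#' weighted PAVA projections onto the row-monotone and column-monotone
#' cones.  This is the end-of-trial smoothing step applied to observed
#' DLT rates before dose selection.
#'
#' @param x Numeric matrix.
#' @param w Non-negative weight matrix, same shape; at least one positive.
#' @param tol Convergence tolerance on the maximum absolute change per
#'   cycle (default 1e-8).
#' @param max_iter Maximum number of Dykstra cycles.
#' @return Fitted matrix, non-decreasing along each row and column.
#' @examples
#' biviso(matrix(c(0.4, 0.2, 0.1, 0.5), 2, 2))
#' @export
biviso <- function(x, w = NULL, tol = 1e-8, max_iter = 1000L) {
  x <- as.matrix(x)
  if (is.null(w)) w <- matrix(1, nrow(x), ncol(x))
  w <- as.matrix(w)
  if (any(w < 0) || all(w == 0))
    stop("weights must be non-negative with at least one positive entry")
  proj_rows <- function(m) {
    for (j in seq_len(nrow(m))) m[j, ] <- pava(m[j, ], w[j, ])
    m
  }
  proj_cols <- function(m) {
    for (k in seq_len(ncol(m))) m[, k] <- pava(m[, k], w[, k])
    m
  }
  p <- q <- matrix(0, nrow(x), ncol(x))
  fit <- x
  for (it in seq_len(max_iter)) {
    y1 <- proj_rows(fit + p)
    p <- fit + p - y1
    fit_new <- proj_cols(y1 + q)
    q <- y1 + q - fit_new
    if (max(abs(fit_new - y1)) < tol && max(abs(fit_new - fit)) < tol) {
      fit <- fit_new
      break
    }
    fit <- fit_new
  }
  fit
}
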