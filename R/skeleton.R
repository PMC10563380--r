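#' CRM skeleton by the indifference-interval method
#'
#' Generates the vector of prior toxicity guesses pi(1) < ... < pi(L) for the
#' empiric CRM working model p = pi^exp(a), using the indifference-interval
#' construction of Lee and Cheung.  The skeleton equals the target at the
#' prior MTD position; moving outward, each neighboring value is fixed by the
#' boundary condition that when the working model puts the current level at
#' one edge of the indifference interval \code{target +/- halfwidth}, the
#' neighbor sits at the other edge:
#' moving up, \code{pi(l+1)^e = target + halfwidth} at the \code{a} where
#' \code{pi(l)^e = target - halfwidth} (with \code{e = exp(a)}); moving down
#' the roles of the edges are swapped.
#'
#' @param target Target toxicity probability phi_T.
#' @param n_doses Number of skeleton positions L (the size of the local set).
#' @param prior_mtd Index nu of the prior MTD guess, \code{1 <= nu <= L}.
#' @param halfwidth Halfwidth delta of the indifference interval,
#'   \code{0 < delta < target}.
#' @return An object of class \code{"crm_skeleton"}: list with \code{probs},
#'   \code{target}, \code{prior_mtd}, \code{halfwidth}.
#' @examples
#' crm_skeleton(0.3, 5, 4, 0.05)
#' @export
crm_skeleton <- function(target, n_doses, prior_mtd, halfwidth = 0.05) {
  if (prior_mtd < 1L || prior_mtd > n_doses)
    stop("prior_mtd must lie in 1..n_doses")
  if (halfwidth <= 0 || halfwidth >= target || target + halfwidth >= 1)
    stop("need 0 < halfwidth < target and target + halfwidth < 1")
  p <- numeric(n_doses)
  p[prior_mtd] <- target
  lo <- log(target - halfwidth)
  hi <- log(target + halfwidth)
  if (prior_mtd < n_doses) {
    for (l in prior_mtd:(n_doses - 1L)) {
      # e solves pi(l)^e = target - halfwidth; then pi(l+1)^e = target + halfwidth
      p[l + 1L] <- exp(hi * log(p[l]) / lo)
    }
  }
  if (prior_mtd > 1L) {
    for (l in prior_mtd:2L) {
      p[l - 1L] <- exp(lo * log(p[l]) / hi)
    }
  }
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1) || any(diff(p) <= 0))
    stop("skeleton recursion left (0,1); choose a smaller halfwidth")
  structure(list(probs = p, target = target, prior_mtd = prior_mtd,
                 halfwidth = halfwidth), class = "crm_skeleton")
}

#' @export
print.crm_skeleton <- function(x, ...) {
  cat(sprintf("CRM skeleton (target %.2f at position %d, halfwidth %.2f):\n",
              x$target, x$prior_mtd, x$halfwidth))
  cat(" ", paste(sprintf("%.4f", x$probs), collapse = " "), "\n")
  invisible(x)
}

# Skeleton cache: decisions recompute the same (L, nu, delta, target)
# skeleton at every cohort, so memoize.
.skeleton_cache <- new.env(parent = emptyenv())

cached_skeleton <- function(target, n_doses, prior_mtd, halfwidth) {
  key <- paste(target, n_doses, prior_mtd, halfwidth, sep = "|")
  sk <- .skeleton_cache[[key]]
  if (is.null(sk)) {
    sk <- crm_skeleton(target, n_doses, prior_mtd, halfwidth)
    .skeleton_cache[[key]] <- sk
  }
  sk
}

# Prior-MTD position for a local set of size m: at the current dose's rank
# (default) or one below the top (nu = m - 1: sizes 3, 4, 5 -> 2, 3, 4).
prior_mtd_position <- function(m, rule = c("current_rank", "n_minus_1"),
                               current_rank = NULL) {
  rule <- match.arg(rule)
  if (rule == "n_minus_1") max(1L, m - 1L) else as.integer(current_rank)
}
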