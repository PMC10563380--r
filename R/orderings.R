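#' Local dose sets around the current combination
#'
#' Builds the local neighborhoods used for interim modeling.  The toxicity
#' set \code{A} holds the current combination and its one-step axis
#' neighbors (up to 5 doses); the efficacy set \code{B} additionally holds
#' the in-grid diagonal neighbors (up to 9 doses).  Both are clipped to the
#' grid and stored in a canonical row-major order by (j, k) so that
#' enumeration and tie-breaking are reproducible.
#'
#' @param grid A \code{\link{dose_grid}}.
#' @param current Integer pair \code{c(j, k)}, 1-based, inside the grid.
#' @return An object of class \code{"local_set"} with fields
#'   \code{current}, \code{A} (m x 2 integer matrix), \code{B} (m' x 2).
#' @examples
#' g <- dose_grid(1:5, 1:3)
#' local_set(g, c(2, 2))
#' @export
local_set <- function(grid, current) {
  check_dose(grid, current)
  j <- as.integer(current[1L]); k <- as.integer(current[2L])
  axis <- rbind(c(j - 1L, k), c(j, k - 1L), c(j, k),
                c(j + 1L, k), c(j, k + 1L))
  diag <- rbind(c(j - 1L, k - 1L), c(j - 1L, k + 1L),
                c(j + 1L, k - 1L), c(j + 1L, k + 1L))
  keep <- function(m) {
    m <- m[m[, 1L] >= 1L & m[, 1L] <= grid$J &
           m[, 2L] >= 1L & m[, 2L] <= grid$K, , drop = FALSE]
    m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  }
  A <- keep(axis)
  B <- keep(rbind(axis, diag))
  structure(list(current = c(j, k), A = A, B = B), class = "local_set")
}

#' @export
print.local_set <- function(x, ...) {
  fmt <- function(m) paste(sprintf("(%d,%d)", m[, 1], m[, 2]), collapse = " ")
  cat(sprintf("Local sets at (%d,%d)\n", x$current[1], x$current[2]))
  cat("  A:", fmt(x$A), "\n  B:", fmt(x$B), "\n")
  invisible(x)
}

#' Enumerate local toxicity orderings
#'
#' Enumerates every complete ordering of the local set \code{A} that is
#' consistent with the partial-ordering assumption (toxicity increases in
#' each drug's dose with the other fixed), i.e. all linear extensions of the
#' componentwise-dominance poset on \code{A}.  For an interior combination
#' there are exactly 4 orderings; for the (1,1) and (J,K) corners 2; for the
#' (J,1) and (1,K) corners the ordering is unique.
#'
#' Each ordering is returned as an integer rank vector aligned with the rows
#' of \code{ls$A}: rank 1 is the least toxic dose.  The current dose carries
#' the same rank in every returned ordering.
#'
#' @param ls A \code{\link{local_set}}.
#' @return List of integer rank vectors, one per ordering, in a
#'   deterministic order.
#' @examples
#' g <- dose_grid(1:5, 1:3)
#' enumerate_orderings(local_set(g, c(2, 2)))
#' @export
enumerate_orderings <- function(ls) {
  A <- ls$A
  m <- nrow(A)
  # dominance relation: dom[i, j] TRUE when dose i must be less toxic than j
  dom <- matrix(FALSE, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j && A[i, 1L] <= A[j, 1L] && A[i, 2L] <= A[j, 2L])
      dom[i, j] <- TRUE
  }
  out <- list()
  ranks <- integer(m)
  placed <- logical(m)
  extend <- function(level) {
    if (level > m) {
      out[[length(out) + 1L]] <<- ranks + 0L
      return(invisible(NULL))
    }
    for (i in seq_len(m)) {
      # a dose may take the next rank when everything it dominates is placed
      if (!placed[i] && all(placed[dom[, i]])) {
        placed[i] <<- TRUE; ranks[i] <<- level
        extend(level + 1L)
        placed[i] <<- FALSE
      }
    }
  }
  extend(1L)
  out
}
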