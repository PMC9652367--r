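# RW2 smooth-term machinery.  A smooth term is a set of ordered knots (the
# "ordered distinct values" grid of the covariate), an incidence map from
# observations to knots, and the second-difference penalty K = D'D whose
# quadratic form f'Kf / (2 tau2) is the negative log density of the
# second-order random-walk prior f(t) = 2 f(t-1) - f(t-2) + u(t).

#' Second-difference operator matrix
#'
#' @param m number of knots, at least 3.
#' @return an `(m-2) x m` matrix whose row `r` carries `(1, -2, 1)` at
#'   columns `(r, r+1, r+2)`.
#' @export
#' @examples
#' second_difference_matrix(4)
second_difference_matrix <- function(m) {
  if (length(m) != 1L || !is.finite(m) || m != floor(m) || m < 3)
    stop("m must be an integer >= 3 (no second difference exists otherwise)")
  D <- matrix(0, m - 2, m)
  for (r in seq_len(m - 2)) D[r, r + 0:2] <- c(1, -2, 1)
  D
}

#' RW2 penalty matrix
#'
#' `K = D'D` with `D` the second-difference operator; symmetric positive
#' semidefinite of rank `m - 2`, annihilating constant and linear vectors
#' (the null space of the RW2 prior).
#'
#' @param m number of knots, at least 3.
#' @return an `m x m` matrix.
#' @export
rw2_penalty <- function(m) {
  D <- second_difference_matrix(m)
  crossprod(D)
}

#' Bin a continuous covariate onto an equally spaced knot grid
#'
#' If the covariate has at most `max_bins` distinct values the knots are the
#' sorted distinct values themselves and the incidence is exact.  Otherwise
#' the knots are midpoints of `max_bins` equal-width intervals over the
#' observed range and each observation maps to the nearest knot (ties broken
#' toward the lower-index knot).  Equal-width bins keep the knot grid equally
#' spaced, matching the RW2 prior's equal-spacing assumption; empty knots are
#' allowed (the prior interpolates them).
#'
#' @param values numeric vector with at least 3 distinct finite values.
#' @param max_bins maximum number of knots, at least 3 (default 20).
#' @param covariate optional name carried along for labelling.
#' @return an object of class `smooth_term`: list with `covariate`, `knots`
#'   (strictly increasing), `incidence` (1-based knot index per observation),
#'   `penalty` (RW2 penalty), and `rank` (`length(knots) - 2`).
#' @export
bin_covariate <- function(values, max_bins = 20, covariate = NULL) {
  if (any(!is.finite(values))) stop("non-finite covariate values")
  if (length(max_bins) != 1L || max_bins < 3) stop("max_bins must be >= 3")
  ux <- sort(unique(values))
  if (length(ux) < 3)
    stop("fewer than 3 distinct values; enter this covariate as a fixed effect")
  if (length(ux) <= max_bins) {
    knots <- ux
    inc <- match(values, knots)
  } else {
    width <- (ux[length(ux)] - ux[1]) / max_bins
    knots <- ux[1] + width * (seq_len(max_bins) - 0.5)
    r <- (values - ux[1]) / width
    inc <- floor(r) + 1
    on_edge <- r == floor(r) & r > 0   # equidistant: take the lower knot
    inc[on_edge] <- r[on_edge]
    inc <- pmin(pmax(inc, 1), max_bins)
  }
  structure(
    list(covariate = covariate, knots = knots, incidence = as.integer(inc),
         penalty = rw2_penalty(length(knots)), rank = length(knots) - 2L),
    class = "smooth_term")
}

#' @export
print.smooth_term <- function(x, ...) {
  cat("smooth_term", if (!is.null(x$covariate)) paste0("(", x$covariate, ")"),
      ":", length(x$knots), "knots on [", min(x$knots), ",", max(x$knots),
      "],", length(x$incidence), "observations\n")
  invisible(x)
}
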