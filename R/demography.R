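# Piecewise-constant effective population size on a regular grid and the
# intrinsic first-order Gaussian Markov random field prior on its log.

#' Regular grid for piecewise-constant Ne(t)
#'
#' `Ne(t) = exp(gamma[d])` for `t` in `(x[d], x[d+1]]`; beyond the last grid
#' point the last value is extended so the likelihood stays defined under
#' numerical jitter.  `build_grid()` anchors the grid at 0 (the most recent
#' tip) and ends it at the TMRCA, matching the convention that the skyline
#' is inferred on a regular grid spanning the observed genealogy.
#'
#' @param x strictly increasing, regularly spaced grid points (`x[1] = 0`).
#' @param gamma optional log-Ne values, length `length(x) - 1`.
#' @return object of class `ne_grid`.
#' @export
ne_grid <- function(x, gamma = NULL) {
  x <- as.numeric(x)
  D <- length(x)
  if (D < 3) stop("need at least 3 grid points")
  if (any(diff(x) <= 0)) stop("grid points must be strictly increasing")
  if (!is.null(gamma) && length(gamma) != D - 1L) {
    stop("gamma must have length D - 1")
  }
  structure(list(x = x, gamma = gamma, D = D, h = x[2] - x[1]),
            class = "ne_grid")
}

#' @rdname ne_grid
#' @param data a [coal_data] object; the grid spans `[0, TMRCA]`.
#' @param D number of grid points (default 100).
#' @export
build_grid <- function(data, D = 100) {
  tK <- max(data$t)
  if (tK <= 0) stop("TMRCA must be positive")
  ne_grid(seq(0, tK, length.out = D))
}

#' Cell index of times on a grid: cell d covers (x[d], x[d+1]].
#' Times at or below 0 map to cell 1, times beyond the grid to the last cell.
#' @noRd
cell_index <- function(grid, t) {
  d <- ceiling((t - grid$x[1]) / grid$h - 1e-9)
  pmin(pmax(d, 1L), grid$D - 1L)
}

#' Evaluate Ne(t) on the grid (vectorized; last value extended past the end).
#' @param grid an [ne_grid] with `gamma` set.
#' @param t times.
#' @export
ne_at <- function(grid, t) {
  if (is.null(grid$gamma)) stop("grid has no gamma values")
  exp(grid$gamma[cell_index(grid, t)])
}

#' Integrated inverse population size
#'
#' Computes \eqn{\int_a^b du / N_e(u)} exactly for the piecewise-constant
#' `Ne`: the sum over grid cells of (overlap length) * exp(-gamma).  Because
#' `Ne` is exactly piecewise constant this is the limit of the Riemann-sum
#' scheme as the evaluation grid refines, and is additive in the interval.
#'
#' @param grid an [ne_grid] with `gamma` set.
#' @param a,b interval endpoints, `0 <= a <= b`.
#' @export
integrate_inverse_ne <- function(grid, a, b) {
  stopifnot(a >= 0, b >= a)
  if (is.null(grid$gamma)) stop("grid has no gamma values")
  if (b == a) return(0)
  x <- grid$x
  D <- grid$D
  lo <- pmax(a, x[-D])
  hi <- pmin(b, x[-1])
  ov <- pmax(0, hi - lo)
  extra <- max(0, b - x[D]) * exp(-grid$gamma[D - 1L])
  sum(ov * exp(-grid$gamma)) + extra
}

#' Intrinsic first-order random-walk precision structure
#'
#' Structure matrix `Q` of an intrinsic RW1 on `p` values: tridiagonal with
#' free boundaries (first and last diagonal entries 1), zero row sums, rank
#' `p - 1`, and quadratic form `gamma' Q gamma = sum(diff(gamma)^2)`.
#'
#' @param p dimension (number of log-Ne cells, `D - 1`).
#' @return a `p` x `p` matrix.
#' @export
gmrf_precision <- function(p) {
  stopifnot(p >= 2)
  Q <- diag(c(1, rep(2, p - 2), 1))
  idx <- seq_len(p - 1)
  Q[cbind(idx, idx + 1)] <- -1
  Q[cbind(idx + 1, idx)] <- -1
  Q
}

#' Log density of the intrinsic GMRF prior on log Ne
#'
#' Up to a fixed constant: `((p - 1)/2) * log(tau) - (tau/2) * gamma' Q gamma`
#' where `p = length(gamma)` and the rank of the intrinsic RW1 precision is
#' `p - 1` (i.e. `D - 2` on a `D`-point grid).  Invariant to adding a
#' constant to `gamma`.
#'
#' @param gamma log-Ne values.
#' @param tau precision (> 0).
#' @param Q optional precision structure (defaults to [gmrf_precision]).
#' @export
gmrf_logprior <- function(gamma, tau, Q = NULL) {
  stopifnot(tau > 0)
  qf <- if (is.null(Q)) sum(diff(gamma)^2) else
    as.numeric(crossprod(gamma, Q %*% gamma))
  0.5 * (length(gamma) - 1) * log(tau) - 0.5 * tau * qf
}
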