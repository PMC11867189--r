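# Base measures Lambda on [0,1] and the merger-rate algebra they generate.
#
# A Lambda-coalescent is determined by a finite measure Lambda on [0,1]:
# when b ancestral lineages are extant, any specific set of k of them merges
# at rate
#     lambda_{b,k} = int_0^1 x^(k-2) (1-x)^(b-k) Lambda(dx),   2 <= k <= b.
# Kingman's coalescent is the point mass at 0 (only pairwise mergers), the
# star coalescent the point mass at 1 (everything merges at once), and the
# Beta(2-alpha, alpha) family interpolates, with alpha -> 2 recovering
# Kingman and alpha = 1 the Bolthausen-Sznitman coalescent.

#' Construct a Lambda-coalescent base measure
#'
#' @description
#' Constructors for the base measure \eqn{\Lambda} on \eqn{[0,1]} that
#' generates all multiple-merger rates:
#' \itemize{
#'   \item `kingman_measure()`: point mass at 0 (binary Kingman coalescent).
#'   \item `star_measure()`: point mass at 1 (star-shaped coalescent).
#'   \item `beta_measure(alpha)`: \eqn{\Lambda = \mathrm{Beta}(2-\alpha,\alpha)}
#'     with \eqn{\alpha \in (0,2]}; `alpha = 2` is defined to be the Kingman
#'     limit exactly (the Beta normalizer diverges there but all rate ratios
#'     converge to the Kingman rates).
#'   \item `discrete_measure(x, w)`: atoms at `x` in \eqn{[0,1]} with strictly
#'     positive weights `w`.
#'   \item `continuous_measure(density)`: an absolutely continuous measure
#'     given by its density on \eqn{[0,1]}; rates are computed by adaptive
#'     quadrature.
#' }
#'
#' @param alpha Beta-coalescent parameter in (0, 2].
#' @param x,w atom locations in \eqn{[0,1]} and strictly positive weights.
#' @param density vectorized density function on \eqn{[0,1]}.
#' @return An object of class `lambda_measure`.
#' @examples
#' merger_rate(kingman_measure(), b = 7, k = 2)   # 1
#' merger_rate(beta_measure(1), b = 3, k = 2)     # 1/2 (Bolthausen-Sznitman)
#' @export
beta_measure <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 2) {
    stop("'alpha' must be a single number in (0, 2]")
  }
  if (alpha == 2) return(kingman_measure())
  structure(list(kind = "beta", alpha = alpha), class = "lambda_measure")
}

#' @rdname beta_measure
#' @export
kingman_measure <- function() {
  structure(list(kind = "kingman"), class = "lambda_measure")
}

#' @rdname beta_measure
#' @export
star_measure <- function() {
  structure(list(kind = "star"), class = "lambda_measure")
}

#' @rdname beta_measure
#' @export
discrete_measure <- function(x, w) {
  stopifnot(length(x) == length(w), length(x) >= 1)
  if (any(x < 0 | x > 1)) stop("atoms must lie in [0,1]")
  if (any(w <= 0) || !all(is.finite(w))) stop("weights must be finite and > 0")
  structure(list(kind = "discrete", x = as.numeric(x), w = as.numeric(w)),
            class = "lambda_measure")
}

#' @rdname beta_measure
#' @export
continuous_measure <- function(density) {
  stopifnot(is.function(density))
  structure(list(kind = "continuous", density = density),
            class = "lambda_measure")
}

#' Demonstration measures: standard normal truncated to [0,1] (renormalized),
#' and a discrete pmf on {0.2, 0.7, 0.9, 1} with equal probabilities.
#' @rdname beta_measure
#' @export
truncnorm_measure <- function() {
  z <- stats::pnorm(1) - stats::pnorm(0)
  continuous_measure(function(x) stats::dnorm(x) / z)
}

#' @rdname beta_measure
#' @export
demo_discrete_measure <- function() {
  discrete_measure(c(0.2, 0.7, 0.9, 1), rep(0.25, 4))
}

#' @export
print.lambda_measure <- function(x, ...) {
  cat("<lambda_measure>", x$kind)
  if (x$kind == "beta") cat(sprintf(" (alpha = %g)", x$alpha))
  cat("\n")
  invisible(x)
}

check_bk <- function(b, k) {
  if (any(b < 2) || any(k < 2) || any(k > b)) {
    stop("require 2 <= k <= b")
  }
}

#' Log merger rate log(lambda_{b,k}); vectorized over (b, k).
#' @noRd
log_merger_rate <- function(measure, b, k) {
  check_bk(b, k)
  n <- max(length(b), length(k))
  b <- rep_len(b, n); k <- rep_len(k, n)
  switch(measure$kind,
    kingman = ifelse(k == 2, 0, -Inf),
    star = ifelse(k == b, 0, -Inf),
    beta = {
      a <- measure$alpha
      lbeta(k - a, a + b - k) - lbeta(2 - a, a)
    },
    discrete = {
      # 0^0 == 1 in R gives the correct limit for atoms at 0 and 1
      log(vapply(seq_len(n), function(i) {
        sum(measure$w * measure$x^(k[i] - 2) * (1 - measure$x)^(b[i] - k[i]))
      }, numeric(1)))
    },
    continuous = {
      log(vapply(seq_len(n), function(i) quad_rate(measure$density, b[i], k[i]),
                 numeric(1)))
    },
    stop("unknown measure kind")
  )
}

quad_rate <- function(density, b, k) {
  f <- function(x) density(x) * x^(k - 2) * (1 - x)^(b - k)
  res <- tryCatch(
    stats::integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 1e-10,
                     subdivisions = 500L),
    error = function(e) stop("quadrature failed for (b=", b, ", k=", k, "): ",
                             conditionMessage(e))
  )
  res$value
}

#' Merger rates of a Lambda-coalescent
#'
#' `merger_rate()` evaluates \eqn{\lambda_{b,k}}, the rate at which a specific
#' set of \eqn{k} of \eqn{b} extant lineages merges; `total_rate()` the total
#' coalescent rate \eqn{\lambda_b = \sum_{k=2}^b \binom{b}{k}\lambda_{b,k}};
#' `block_size_pmf()` the distribution of the merger (block) size at a
#' coalescent event, \eqn{P(X=k) = \binom{b}{k}\lambda_{b,k}/\lambda_b}.
#'
#' Beta-family rates use the closed form
#' \eqn{\lambda_{b,k} = B(k-\alpha, \alpha+b-k)/B(2-\alpha, \alpha)}
#' evaluated via log-gamma; discrete measures are summed exactly and
#' continuous measures integrated by adaptive quadrature.
#'
#' @param measure a [lambda_measure][beta_measure] object.
#' @param b number of extant lineages (integer, >= 2).
#' @param k merger size, integer in `[2, b]` (vectorized).
#' @return `merger_rate`: nonnegative rate(s); `total_rate`: a positive
#'   scalar; `block_size_pmf`: a probability vector over `k = 2..b`.
#' @export
merger_rate <- function(measure, b, k) {
  exp(log_merger_rate(measure, b, k))
}

#' @rdname merger_rate
#' @export
total_rate <- function(measure, b) {
  stopifnot(length(b) == 1L, b >= 2)
  k <- 2:b
  exp(logsumexp(lchoose(b, k) + log_merger_rate(measure, b, k)))
}

#' @rdname merger_rate
#' @export
block_size_pmf <- function(measure, b) {
  stopifnot(length(b) == 1L, b >= 2)
  k <- 2:b
  lw <- lchoose(b, k) + log_merger_rate(measure, b, k)
  lt <- logsumexp(lw)
  if (!is.finite(lt)) stop("degenerate measure: total rate is zero")
  p <- exp(lw - lt)
  names(p) <- k
  p
}

#' Closed-form approximation to the total Beta-coalescent rate
#'
#' Returns \eqn{(b-1)(b/2)^{\alpha-1}}, an analytic approximation to the
#' total rate \eqn{\lambda_b} of the Beta(2-\eqn{\alpha}, \eqn{\alpha})
#' coalescent.  At \eqn{\alpha = 2} it equals \eqn{\binom{b}{2}} (Kingman)
#' and at \eqn{\alpha = 1} it equals \eqn{b - 1} (Bolthausen-Sznitman),
#' both exactly.  Provided as a diagnostic only; none of the likelihoods in
#' this package use it.
#'
#' @param alpha Beta parameter in (0, 2].
#' @param b number of lineages, >= 2.
#' @export
total_rate_approx <- function(alpha, b) {
  if (alpha <= 0 || alpha > 2) stop("'alpha' must be in (0, 2]")
  if (any(b < 2)) stop("'b' must be >= 2")
  (b - 1) * (b / 2)^(alpha - 1)
}

#' Table of log merger rates up to a maximum lineage count
#'
#' Caches \eqn{\log\lambda_{b,k}} for all \eqn{2 \le k \le b \le} `b_max`
#' together with the log total rates; rates depend on the measure but not on
#' time, so one table serves every likelihood evaluation for a genealogy
#' with at most `b_max` tips.
#'
#' @param measure a [lambda_measure][beta_measure].
#' @param b_max largest lineage count needed.
#' @return list with `loglam` (`b_max` x `b_max` matrix, entry `[b, k]` valid
#'   for `2 <= k <= b`) and `logtot` (vector indexed by `b`).
#' @export
rate_table <- function(measure, b_max) {
  stopifnot(b_max >= 2)
  loglam <- matrix(NA_real_, b_max, b_max)
  logtot <- rep(NA_real_, b_max)
  for (b in 2:b_max) {
    k <- 2:b
    loglam[b, k] <- log_merger_rate(measure, b, k)
    logtot[b] <- logsumexp(lchoose(b, k) + loglam[b, k])
  }
  structure(list(loglam = loglam, logtot = logtot, b_max = b_max,
                 kind = measure$kind),
            class = "rate_table")
}
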