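# Independent oracles used across the suite.  These deliberately avoid the
# package's internal code paths: rates by adaptive quadrature against the
# Beta density, likelihoods by direct enumeration of the definition.

# lambda_{b,k} for the Beta(2-alpha, alpha) measure by numeric quadrature of
# int_0^1 x^(k-2) (1-x)^(b-k) Beta(2-alpha, alpha)(dx).
quad_rate_oracle <- function(alpha, b, k) {
  # probability-scale substitution tames the endpoint singularities of the
  # Beta density: E[X^(k-2) (1-X)^(b-k)] with X = qbeta(p); fall back to the
  # density-scale integral where the transformed integrand defeats the
  # adaptive rule (tiny sharply peaked values)
  tryCatch(
    stats::integrate(function(p) {
      x <- stats::qbeta(p, 2 - alpha, alpha)
      x^(k - 2) * (1 - x)^(b - k)
    }, 0, 1, rel.tol = 1e-11, subdivisions = 2000L)$value,
    error = function(e) {
      stats::integrate(function(x) x^(k - 2) * (1 - x)^(b - k) *
                         stats::dbeta(x, 2 - alpha, alpha),
                       0, 1, rel.tol = 1e-10, subdivisions = 2000L)$value
    })
}

# Brute-force total rate from the quadrature oracle.
quad_total_oracle <- function(alpha, b) {
  sum(vapply(2:b, function(k) choose(b, k) * quad_rate_oracle(alpha, b, k),
             numeric(1)))
}

# Direct (naive) evaluation of the heterochronous variable-Ne coalescent
# log-likelihood: its own lineage counting, its own change-point sweep, and
# rates via lgamma written out longhand.
naive_loglik <- function(data, alpha, grid) {
  lam_bk <- function(b, k) {
    exp(lgamma(k - alpha) + lgamma(alpha + b - k) - lgamma(b) -
          (lgamma(2 - alpha) + lgamma(alpha) - lgamma(2)))
  }
  lam_tot <- function(b) sum(choose(b, 2:b) * lam_bk(b, 2:b))
  A_of <- function(tt) sum(data$n[data$s < tt]) - sum((data$m - 1)[data$t < tt])
  ne_of <- function(tt) {
    d <- findInterval(tt, grid$x, left.open = TRUE, rightmost.closed = FALSE)
    d <- min(max(d, 1), grid$D - 1)
    exp(grid$gamma[d])
  }
  tK <- max(data$t)
  bps <- sort(unique(c(0, data$s, data$t, grid$x, tK)))
  bps <- bps[bps <= tK]
  integral <- 0
  for (i in seq_len(length(bps) - 1)) {
    mid <- (bps[i] + bps[i + 1]) / 2
    A <- A_of(mid)
    if (A >= 2) {
      integral <- integral + lam_tot(A) * (bps[i + 1] - bps[i]) / ne_of(mid)
    }
  }
  pts <- 0
  for (j in seq_along(data$t)) {
    A <- A_of(data$t[j])
    pts <- pts + log(choose(A, data$m[j])) + log(lam_bk(A, data$m[j])) -
      log(ne_of(data$t[j]))
  }
  pts - integral
}

# Small fixed heterochronous dataset used by several tests:
# samples (3 at 0, 2 at 0.5), events at 0.3 (pair), 0.8 (triple), 1.5 (pair).
toy_data <- function() {
  coal_data(c(0, 0.5), c(3, 2), c(0.3, 0.8, 1.5), c(2, 3, 2))
}

sim_fixture <- function(alpha = 1.5, ne = "uniform", n = 30, seed = 42) {
  simulate_genealogy(beta_measure(alpha), ne, n, seed = seed, tree = FALSE)$data
}
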