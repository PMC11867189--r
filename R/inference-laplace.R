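# Estimation of alpha from block sizes, and of Ne(t) given alpha via an
# explicit Newton--Laplace (Gaussian) approximation with the GMRF prior and
# the precision tau integrated over a log-spaced grid.

# alpha grid used throughout: midpoints of the 400 intervals
# ((m-1)*0.005, m*0.005], m = 1..400, exactly tiling (0, 2].
alpha_grid_midpoints <- function() seq_len(400) * 0.005 - 0.0025

# Cached log total Beta rates on the alpha grid for all b = 2..n:
# matrix [400 x (n - 1)], column j is b = j + 1.  One table serves every
# genealogy with at most n tips of the same size class.
logtot_grid <- function(n) {
  cache_get_or(paste0("logtot_", n), function() {
    ag <- alpha_grid_midpoints()
    bs <- 2:n
    B <- rep.int(bs, bs - 1L)
    K <- unlist(lapply(bs, function(b) 2:b), use.names = FALSE)
    lch <- lchoose(B, K)
    grp <- rep.int(seq_along(bs), bs - 1L)
    out <- matrix(NA_real_, 400L, n - 1L)
    for (i in seq_along(ag)) {
      a <- ag[i]
      v <- lch + lbeta(K - a, a + B - K) - lbeta(2 - a, a)
      out[i, ] <- logsumexp_by(v, grp, ug = seq_along(bs))
    }
    out
  })
}

#' Block-size pseudo-likelihood estimator of alpha
#'
#' Maximizes the topology-only pseudo-likelihood [topology_loglik()] over
#' `alpha` in (0, 2]: a coarse grid of step 0.005 followed by numerical
#' refinement in the best bracket.  A genealogy whose pseudo-likelihood is
#' maximized at a boundary (e.g. an all-binary tree, for which the
#' pseudo-likelihood increases monotonically toward the Kingman limit) is
#' reported at the boundary with `boundary = TRUE`.
#'
#' @param data a [coal_data].
#' @return list with `alpha` (the estimate), `boundary` flag and `value`
#'   (the maximized log pseudo-likelihood).
#' @export
estimate_alpha_blocksize <- function(data) {
  v <- topology_grid_values(data)
  ag <- alpha_grid_midpoints()
  i <- which.max(v)
  lo <- max(ag[i] - 0.005, 1e-6)
  hi <- min(ag[i] + 0.005, 2)
  opt <- stats::optimize(function(a) topology_loglik(data, a),
                         c(lo, hi), maximum = TRUE, tol = 1e-7)
  alpha <- opt$maximum
  val <- opt$objective
  boundary <- FALSE
  if (i == 400L && topology_loglik(data, 2) >= val - 1e-9) {
    alpha <- 2; val <- topology_loglik(data, 2); boundary <- TRUE
  } else if (i == 1L && alpha < 0.005) {
    alpha <- 0.005; val <- topology_loglik(data, alpha); boundary <- TRUE
  }
  list(alpha = alpha, boundary = boundary, value = val)
}

# Pseudo-likelihood on the 400-point alpha grid, vectorized via the cached
# per-n total-rate table.
topology_grid_values <- function(data) {
  A_k <- as.integer(lineage_count(data, data$t))
  m <- data$m
  n <- data$n_total
  LT <- logtot_grid(n)
  ag <- alpha_grid_midpoints()
  lch <- sum(lchoose(A_k, m))
  # pair terms: 400 x K lbeta evaluations
  pair <- matrix(lbeta(outer(-ag, m, "+"), outer(ag, A_k - m, "+")),
                 nrow = 400L)
  norm <- lbeta(2 - ag, ag)
  tot <- rowSums(LT[, A_k - 1L, drop = FALSE])
  lch + rowSums(pair) - length(m) * norm - tot
}

# --------------------------------------------------------------------------
# Newton--Laplace approximation of p(gamma | data, tau, alpha)

# Given the per-cell hazard coefficients Td and event counts cnt, the
# log-posterior (up to constants) is
#   f(g) = -sum(cnt * g) - sum(Td * exp(-g)) + (p-1)/2 log tau - tau/2 g'Qg,
# concave in g with diagonal likelihood Hessian -Td*exp(-g).
laplace_mode <- function(Td, cnt, tau, Q, gamma0, max_iter = 100,
                         grad_tol = 1e-8) {
  g <- gamma0
  f <- function(g) -sum(cnt * g) - sum(Td * exp(-g)) -
    0.5 * tau * as.numeric(crossprod(g, Q %*% g))
  fg <- f(g)
  for (it in seq_len(max_iter)) {
    w <- Td * exp(-g)
    grad <- -cnt + w - tau * as.vector(Q %*% g)
    if (max(abs(grad)) < grad_tol) {
      return(list(gamma = g, negH = diag(w) + tau * Q, converged = TRUE,
                  iter = it, grad_norm = max(abs(grad)), f = fg))
    }
    step <- solve(diag(w) + tau * Q, grad)
    lam <- 1
    repeat {
      g_new <- g + lam * step
      f_new <- f(g_new)
      if (f_new >= fg - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    g <- g_new; fg <- f_new
  }
  w <- Td * exp(-g)
  grad <- -cnt + w - tau * as.vector(Q %*% g)
  if (max(abs(grad)) > 1e-4) {
    stop("Newton iteration for the Laplace mode did not converge (|grad| = ",
         format(max(abs(grad))), ")")
  }
  list(gamma = g, negH = diag(w) + tau * Q, converged = FALSE, iter = max_iter,
       grad_norm = max(abs(grad)), f = f(g))
}

# Laplace-approximate log marginal of tau (up to constants):
# f(gamma_hat) + (p-1)/2 log tau + log Gamma-prior(tau) - 1/2 logdet(-H).
tau_log_marginal <- function(tau, Td, cnt, Q, gamma0, tau_a = 0.001,
                             tau_b = 0.001) {
  p <- length(gamma0)
  md <- laplace_mode(Td, cnt, tau, Q, gamma0)
  ld <- 2 * sum(log(diag(chol(md$negH))))
  list(value = md$f + 0.5 * (p - 1) * log(tau) +
         stats::dgamma(tau, tau_a, rate = tau_b, log = TRUE) - 0.5 * ld,
       mode = md)
}

new_posterior_result <- function(grid, med, lo, hi, alpha, method,
                                 diagnostics = list(), alpha_samples = NULL) {
  stopifnot(all(lo <= med + 1e-9), all(med <= hi + 1e-9))
  mids <- (grid$x[-grid$D] + grid$x[-1]) / 2
  structure(list(grid = grid, t_mid = mids, ne_median = med,
                 ne_lower95 = lo, ne_upper95 = hi, alpha = alpha,
                 alpha_samples = alpha_samples, method = method,
                 diagnostics = diagnostics),
            class = "posterior_result")
}

#' @export
print.posterior_result <- function(x, ...) {
  cat(sprintf("<posterior_result> method = %s, alpha = %.4f, D = %d grid points\n",
              x$method, x$alpha, x$grid$D))
  cat(sprintf("  Ne(t) median range: [%.3g, %.3g]\n",
              min(x$ne_median), max(x$ne_median)))
  invisible(x)
}

#' Skyline estimate of Ne(t) given alpha (Laplace approximation)
#'
#' Approximates the posterior of the log-Ne grid values under the intrinsic
#' GMRF prior by a Gaussian (Laplace) approximation at each value of a
#' log-spaced precision grid: Newton iterations find the conditional mode,
#' tau is integrated over 31 grid values (centred at the maximizer of its
#' Laplace-approximate marginal under the Gamma(0.001, 0.001) prior), and
#' pointwise medians and 95% bands are read off the resulting Gaussian
#' mixture.
#'
#' @param data a [coal_data].
#' @param alpha Beta-coalescent parameter in (0, 2]; ignored when `measure`
#'   is supplied.
#' @param measure optional [lambda_measure][beta_measure] for Ne-only
#'   inference under an arbitrary base measure.
#' @param D number of grid points (default 100).
#' @param tau_grid_size,tau_spread size and half-width (in log units) of the
#'   precision grid.
#' @param tau_map if `TRUE`, condition on the modal tau instead of
#'   integrating over the grid.
#' @return a `posterior_result` with pointwise `ne_median`, `ne_lower95`,
#'   `ne_upper95` and diagnostics (tau grid, weights, Newton certificates).
#' @export
fit_ne_given_alpha <- function(data, alpha = NULL, measure = NULL, D = 100,
                               tau_grid_size = 31, tau_spread = 4,
                               tau_map = FALSE) {
  if (is.null(measure)) {
    if (is.null(alpha)) stop("supply 'alpha' or 'measure'")
    measure <- if (alpha == 2) kingman_measure() else beta_measure(alpha)
  } else if (is.null(alpha)) {
    alpha <- if (measure$kind == "beta") measure$alpha else NA_real_
  }
  grid <- build_grid(data, D)
  ws <- lik_workspace(data, grid)
  rates <- rates_for_measure(ws, measure)
  Td <- hazard_cellsum(ws, rates)
  cnt <- ws$cnt
  p <- ws$p
  Q <- gmrf_precision(p)
  gamma0 <- rep(log(max(sum(Td) / max(sum(cnt), 1), 1e-8)), p)
  # centre the precision grid at the marginal maximizer
  marg <- function(lt) tau_log_marginal(exp(lt), Td, cnt, Q, gamma0)$value
  lt_hat <- stats::optimize(marg, c(-12, 12), maximum = TRUE, tol = 1e-3)$maximum
  lts <- seq(lt_hat - tau_spread, lt_hat + tau_spread,
             length.out = tau_grid_size)
  modes <- vector("list", tau_grid_size)
  lpost <- numeric(tau_grid_size)
  for (j in seq_len(tau_grid_size)) {
    r <- tau_log_marginal(exp(lts[j]), Td, cnt, Q, gamma0)
    # + log tau Jacobian for the uniform-in-log grid weights
    lpost[j] <- r$value + lts[j]
    modes[[j]] <- r$mode
  }
  w <- exp(lpost - logsumexp(lpost))
  if (tau_map) {
    jj <- which.max(w)
    w <- replace(rep(0, tau_grid_size), jj, 1)
  }
  keep <- which(w > 1e-12)
  mus <- do.call(rbind, lapply(modes[keep], `[[`, "gamma"))
  sds <- do.call(rbind, lapply(modes[keep], function(m) {
    sqrt(diag(chol2inv(chol(m$negH))))
  }))
  wk <- w[keep] / sum(w[keep])
  qs <- mixture_quantiles(mus, sds, wk, c(0.025, 0.5, 0.975))
  new_posterior_result(
    grid, exp(qs[, 2]), exp(qs[, 1]), exp(qs[, 3]), alpha, "laplace",
    diagnostics = list(
      tau_grid = exp(lts), tau_weights = w, tau_map = exp(lt_hat),
      grad_norm = max(vapply(modes[keep], `[[`, numeric(1), "grad_norm")),
      newton_iter = max(vapply(modes[keep], `[[`, numeric(1), "iter"))))
}

# Pointwise quantiles of a Gaussian mixture, per coordinate.
mixture_quantiles <- function(mus, sds, w, probs) {
  p <- ncol(mus)
  out <- matrix(NA_real_, p, length(probs))
  for (d in seq_len(p)) {
    mu <- mus[, d]; sd <- sds[, d]
    lo <- min(mu - 8 * sd); hi <- max(mu + 8 * sd)
    for (q in seq_along(probs)) {
      pr <- probs[q]
      out[d, q] <- stats::uniroot(function(z) {
        sum(w * stats::pnorm(z, mu, sd)) - pr
      }, c(lo, hi), tol = 1e-8)$root
    }
  }
  out
}

#' Hybrid iterative estimator of (alpha, Ne)
#'
#' Initializes `alpha` at the block-size pseudo-likelihood estimate, then
#' alternates (i) a Laplace skyline fit of `Ne(t)` at the current `alpha`,
#' taking the posterior median trajectory, and (ii) maximum-likelihood
#' re-estimation of `alpha` under the full coalescent likelihood at that
#' fixed `Ne(t)`, until the change in `alpha` drops below `tol`.
#'
#' @param data a [coal_data].
#' @param D number of grid points.
#' @param max_iter,tol iteration cap and convergence tolerance on alpha.
#' @return a `posterior_result` (method `"hybrid"`) whose diagnostics record
#'   the iteration path of alpha.
#' @export
estimate_hybrid <- function(data, D = 100, max_iter = 20, tol = 1e-3) {
  a <- estimate_alpha_blocksize(data)$alpha
  path <- a
  fit <- NULL
  for (it in seq_len(max_iter)) {
    fit <- fit_ne_given_alpha(data, alpha = a, D = D)
    grid <- fit$grid
    grid$gamma <- log(fit$ne_median)
    a_new <- mle_alpha_given_ne(data, grid)
    path <- c(path, a_new)
    if (abs(a_new - a) < tol) { a <- a_new; break }
    a <- a_new
  }
  fit$alpha <- a
  fit$method <- "hybrid"
  fit$diagnostics$alpha_path <- path
  fit$diagnostics$iterations <- it
  fit
}

# Full-likelihood MLE of alpha at fixed Ne (grid + refinement).
mle_alpha_given_ne <- function(data, grid) {
  ws <- lik_workspace(data, grid)
  gamma <- grid$gamma
  IA <- cellsum_by_A(ws, gamma)
  ag <- alpha_grid_midpoints()
  LT <- logtot_grid(data$n_total)
  lamA <- exp(LT[, ws$dA - 1L, drop = FALSE])
  pair <- matrix(lbeta(outer(-ag, ws$m_k, "+"), outer(ag, ws$A_k - ws$m_k, "+")),
                 nrow = 400L)
  vals <- rowSums(pair) - length(ws$m_k) * lbeta(2 - ag, ag) -
    as.vector(lamA %*% IA)
  i <- which.max(vals)
  f <- function(a) loglik(data, beta_measure(a), grid)
  lo <- max(ag[i] - 0.005, 1e-6); hi <- min(ag[i] + 0.005, 2 - 1e-9)
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-6)
  if (i == 400L && loglik(data, kingman_measure(), grid) > opt$objective) {
    return(2)
  }
  opt$maximum
}

# Integrated inverse-Ne mass per distinct lineage count:
# I_A = sum over intervals with that A of length * exp(-gamma_cell).
cellsum_by_A <- function(ws, gamma) {
  as.vector(rowsum(ws$len * exp(-gamma[ws$cell]),
                   factor(ws$iA, levels = seq_along(ws$dA))))
}
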