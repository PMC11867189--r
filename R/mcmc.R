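# Metropolis-within-Gibbs sampler for (gamma, tau, alpha):
#   (a) conjugate Gibbs draw of the GMRF precision tau | gamma,
#   (b) split Hamiltonian Monte Carlo update of gamma | tau, alpha, in which
#       the Gaussian-prior part of the dynamics is solved exactly in the
#       eigenbasis of the RW1 structure matrix and only the likelihood force
#       enters the leapfrog kicks,
#   (c) a draw of alpha from its discretized full conditional: the
#       likelihood is evaluated at the 400 midpoints of the 0.005-wide
#       intervals tiling (0, 2], normalized by the Riemann sum, an interval
#       is sampled and alpha is drawn uniformly within it.

#' Discretized full conditional of alpha
#'
#' Probabilities of the 400 intervals `((m-1)*0.005, m*0.005]` tiling
#' (0, 2] under the coalescent likelihood at fixed `Ne` (given by
#' `grid$gamma`), i.e. the Riemann-sum normalization of the alpha
#' conditional used inside the MCMC sampler.
#'
#' @param data a [coal_data].
#' @param grid an [ne_grid] with `gamma` set.
#' @return data.frame with columns `midpoint` and `prob` (summing to 1).
#' @export
alpha_conditional <- function(data, grid) {
  ws <- lik_workspace(data, grid)
  gamma <- grid$gamma
  ag <- alpha_grid_midpoints()
  LT <- logtot_grid(data$n_total)
  lamA <- exp(LT[, ws$dA - 1L, drop = FALSE])
  IA <- cellsum_by_A(ws, gamma)
  pair <- matrix(lbeta(outer(-ag, ws$m_k, "+"),
                       outer(ag, ws$A_k - ws$m_k, "+")), nrow = 400L)
  ll <- rowSums(pair) - length(ws$m_k) * lbeta(2 - ag, ag) -
    as.vector(lamA %*% IA)
  data.frame(midpoint = ag, prob = exp(ll - logsumexp(ll)))
}

#' Joint MCMC for effective population size and alpha
#'
#' Samples from the posterior of the log-Ne grid values `gamma`, the GMRF
#' precision `tau` (Gamma(0.001, 0.001) prior) and the Beta-coalescent
#' parameter `alpha` (uniform prior on (0, 2]) given a multifurcating
#' genealogy.  See the module header for the update scheme.  Step size is
#' adapted toward `target_accept` during burn-in and then frozen.
#'
#' @param data a [coal_data].
#' @param D number of grid points.
#' @param iterations total MCMC iterations (default 20000).
#' @param burnin_frac fraction discarded as burn-in (default 10%).
#' @param seed optional integer seed.
#' @param alpha if a number, alpha is held fixed at that value; if `NULL`
#'   (default) it is sampled.
#' @param include_likelihood set `FALSE` for a prior-only run (sampler
#'   validation: alpha is then uniform on (0, 2] and gamma follows the
#'   intrinsic GMRF prior).
#' @param fix_tau optionally hold tau fixed (used with prior-only runs,
#'   where the Gamma(0.001, 0.001) prior is nearly improper).
#' @param L number of leapfrog steps per HMC update.
#' @param step_size initial leapfrog step size (default: set from the
#'   likelihood curvature at the initial state).
#' @param target_accept HMC acceptance target for step-size adaptation.
#' @return list with `result` (a `posterior_result`) and `trace` (class
#'   `mcmc_trace`: matrices/vectors of post-burn-in and burn-in draws).
#' @export
run_mcmc <- function(data, D = 100, iterations = 20000, burnin_frac = 0.1,
                     seed = NULL, alpha = NULL, include_likelihood = TRUE,
                     fix_tau = NULL, L = 10, step_size = NULL,
                     target_accept = 0.7) {
  stopifnot(iterations >= 100)
  if (!is.null(seed)) set.seed(seed)
  grid <- build_grid(data, D)
  ws <- lik_workspace(data, grid)
  p <- ws$p
  Q <- gmrf_precision(p)
  eQ <- eigen(Q, symmetric = TRUE)
  V <- eQ$vectors
  ev <- pmax(eQ$values, 0)
  ev[ev < 1e-10] <- 0

  # alpha-grid tables (data-dependent, iteration-independent)
  ag <- alpha_grid_midpoints()
  sample_alpha <- is.null(alpha) && include_likelihood
  if (sample_alpha) {
    LT <- logtot_grid(data$n_total)
    lamA_grid <- exp(LT[, ws$dA - 1L, drop = FALSE])      # 400 x ndA
    pair_sum <- rowSums(matrix(
      lbeta(outer(-ag, ws$m_k, "+"), outer(ag, ws$A_k - ws$m_k, "+")),
      nrow = 400L)) - length(ws$m_k) * lbeta(2 - ag, ag)
  }

  # initial state
  a_cur <- if (!is.null(alpha)) alpha else if (include_likelihood) {
    estimate_alpha_blocksize(data)$alpha
  } else 1
  if (a_cur >= 2) a_cur <- 2 - 1e-6
  rates <- rates_for_alpha(ws, a_cur)
  Td <- hazard_cellsum(ws, rates)
  cnt <- ws$cnt
  if (include_likelihood) {
    gamma <- rep(log(max(sum(Td) / max(sum(cnt), 1), 1e-8)), p)
  } else {
    gamma <- rep(0, p)
  }
  tau <- if (!is.null(fix_tau)) fix_tau else 10
  eps <- if (is.null(step_size)) {
    0.5 / sqrt(max(Td * exp(-gamma), 1))
  } else step_size

  n_burn <- ceiling(burnin_frac * iterations)
  tr_gamma <- matrix(NA_real_, iterations, p)
  tr_tau <- numeric(iterations)
  tr_alpha <- numeric(iterations)
  acc <- 0L

  lik_U <- function(g, Td) {
    if (!include_likelihood) return(0)
    sum(cnt * g) + sum(Td * exp(-g))
  }
  lik_grad <- function(g, Td) {
    if (!include_likelihood) return(numeric(p))
    -cnt + Td * exp(-g)
  }

  for (it in seq_len(iterations)) {
    # (a) tau | gamma: conjugate Gamma draw
    if (is.null(fix_tau)) {
      qf <- sum(diff(gamma)^2)
      tau <- stats::rgamma(1, 0.001 + 0.5 * (p - 1), rate = 0.001 + 0.5 * qf)
    }

    # (b) split HMC for gamma | tau, alpha; the step size is jittered so the
    # exact prior rotations cannot lock onto per-mode resonances
    pm <- stats::rnorm(p)
    U0 <- lik_U(gamma, Td) + 0.5 * tau * sum(diff(gamma)^2)
    H0 <- U0 + 0.5 * sum(pm^2)
    g <- gamma; mo <- pm
    eps_it <- eps * stats::runif(1, 0.8, 1.2)
    omega <- sqrt(tau * ev)
    co <- cos(omega * eps_it); si <- sin(omega * eps_it)
    sn_ov <- ifelse(omega > 0, si / omega, eps_it)  # sin(wt)/w -> t as w -> 0
    for (l in seq_len(L)) {
      mo <- mo + 0.5 * eps_it * lik_grad(g, Td)
      qt <- crossprod(V, g); pt <- crossprod(V, mo)
      qn <- co * qt + sn_ov * pt
      pn <- -omega * si * qt + co * pt
      g <- as.vector(V %*% qn); mo <- as.vector(V %*% pn)
      mo <- mo + 0.5 * eps_it * lik_grad(g, Td)
    }
    U1 <- lik_U(g, Td) + 0.5 * tau * sum(diff(g)^2)
    H1 <- U1 + 0.5 * sum(mo^2)
    a_prob <- if (is.finite(H1)) min(1, exp(H0 - H1)) else 0
    if (stats::runif(1) < a_prob) {
      gamma <- g
      acc <- acc + 1L
    }
    if (it <= n_burn) {
      eps <- eps * exp(0.05 * (a_prob - target_accept))
    }

    # (c) alpha | gamma from the discretized conditional
    if (sample_alpha) {
      IA <- cellsum_by_A(ws, gamma)
      ll <- pair_sum - as.vector(lamA_grid %*% IA)
      pr <- exp(ll - logsumexp(ll))
      m_idx <- sample.int(400L, 1L, prob = pr)
      a_cur <- stats::runif(1, (m_idx - 1) * 0.005, m_idx * 0.005)
      rates <- rates_for_alpha(ws, a_cur)
      Td <- hazard_cellsum(ws, rates)
    } else if (!include_likelihood && is.null(alpha)) {
      a_cur <- stats::runif(1, 0, 2)
    }

    tr_gamma[it, ] <- gamma
    tr_tau[it] <- tau
    tr_alpha[it] <- a_cur
  }

  keep <- (n_burn + 1L):iterations
  G <- tr_gamma[keep, , drop = FALSE]
  qs <- apply(G, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              names = FALSE)
  accept_rate <- acc / iterations
  # prior-only flights are exact (deltaH = 0), so acceptance 1 is expected
  if (include_likelihood && (accept_rate < 0.2 || accept_rate > 0.95)) {
    warning(sprintf("HMC acceptance rate %.2f outside [0.2, 0.95]",
                    accept_rate))
  }
  res <- new_posterior_result(
    grid, exp(qs[2, ]), exp(qs[1, ]), exp(qs[3, ]),
    alpha = stats::median(tr_alpha[keep]), method = "mcmc",
    diagnostics = list(accept_rate = accept_rate, step_size = eps,
                       iterations = iterations, burnin = n_burn,
                       alpha_mean = mean(tr_alpha[keep]),
                       tau_median = stats::median(tr_tau[keep])),
    alpha_samples = tr_alpha[keep])
  trace <- structure(list(gamma = tr_gamma, tau = tr_tau, alpha = tr_alpha,
                          burnin = n_burn), class = "mcmc_trace")
  list(result = res, trace = trace)
}

#' @export
print.mcmc_trace <- function(x, ...) {
  cat(sprintf("<mcmc_trace> %d iterations (%d burn-in), %d gamma dims\n",
              length(x$tau), x$burnin, ncol(x$gamma)))
  invisible(x)
}
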