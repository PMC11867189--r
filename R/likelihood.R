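# Heterochronous variable-Ne Lambda-coalescent log-likelihood, the
# topology-only (block-size) pseudo-likelihood, and the gradient in the
# log-Ne grid values.
#
# The density of (m, t) given (n, s, Ne, Lambda) factorizes as a point
# process of coalescent events with total rate lambda_A(t)/Ne(t) times the
# block-size probabilities:
#   loglik = sum_k [ log C(A_k, m_k) + log lambda_{A_k, m_k} - log Ne(t_k) ]
#            - sum_intervals lambda_A * int du / Ne(u),
# where within each interval of the change-point partition (sampling times,
# coalescent times, grid boundaries) both A and Ne are constant, so the
# exponent integral is evaluated exactly.

#' Change-point workspace for likelihood evaluations.
#' Intervals tile [0, tK]; within each, A(t) and the grid cell are constant.
#' @noRd
lik_workspace <- function(data, grid) {
  tK <- max(data$t)
  cps <- sort(unique(c(0, data$s[data$s > 0 & data$s < tK],
                       data$t[data$t < tK],
                       grid$x[grid$x > 0 & grid$x < tK], tK)))
  cps <- c(0, cps[cps > 0])
  lo <- cps[-length(cps)]
  hi <- cps[-1]
  mid <- (lo + hi) / 2
  A <- as.integer(lineage_count(data, mid))
  cell <- cell_index(grid, mid)
  act <- A >= 2L                       # A < 2 stretches carry no hazard
  dA <- sort(unique(A[act]))
  iA <- match(A[act], dA)
  A_k <- as.integer(lineage_count(data, data$t))
  if (any(A_k < data$m)) stop("invalid genealogy: block size exceeds A(t)")
  cell_k <- cell_index(grid, data$t)
  p <- grid$D - 1L
  skel_b <- rep.int(dA, dA - 1L)
  skel_k <- unlist(lapply(dA, function(b) 2:b), use.names = FALSE)
  list(len = (hi - lo)[act], cell = cell[act], iA = iA, dA = dA,
       A_k = A_k, m_k = data$m, cell_k = cell_k,
       cnt = cellsum(rep(1, length(cell_k)), cell_k, p),
       lch_sum = sum(lchoose(A_k, data$m)), p = p, D = grid$D,
       skel = list(B = skel_b, K = skel_k,
                   lch = lchoose(skel_b, skel_k),
                   grp = rep.int(seq_along(dA), dA - 1L)),
       # full-partition view (incl. A < 2) for the Riemann-mode exponent
       all_len = hi - lo, all_cell = cell, all_A = A, tK = tK)
}

#' Log total Beta-coalescent rates for the distinct lineage counts of a
#' workspace skeleton, vectorized in one pass.
#' @noRd
beta_logtot_skel <- function(alpha, skel, ndA) {
  if (alpha == 2) stop("use kingman rates at alpha = 2")
  v <- skel$lch + lbeta(skel$K - alpha, alpha + skel$B - skel$K) -
    lbeta(2 - alpha, alpha)
  logsumexp_by(v, skel$grp, ug = seq_len(ndA))
}

#' Rates needed by the likelihood: total rate per distinct interval-A and
#' log merger rate per observed (A_k, m_k) pair.
#' @noRd
rates_for_alpha <- function(ws, alpha) {
  if (alpha == 2) return(rates_for_measure(ws, kingman_measure()))
  list(lamA = exp(beta_logtot_skel(alpha, ws$skel, length(ws$dA))),
       loglam_ev = lbeta(ws$m_k - alpha, alpha + ws$A_k - ws$m_k) -
         lbeta(2 - alpha, alpha))
}

#' @noRd
rates_for_measure <- function(ws, measure) {
  if (measure$kind == "beta") return(rates_for_alpha(ws, measure$alpha))
  bmax <- max(ws$dA, ws$A_k)
  rt <- rate_table(measure, bmax)
  list(lamA = exp(rt$logtot[ws$dA]),
       loglam_ev = rt$loglam[cbind(ws$A_k, ws$m_k)])
}

#' Per-cell integrated hazard coefficients T_d = sum lambda_A * len over the
#' intervals in cell d; the exponent of the likelihood is
#' sum_d T_d * exp(-gamma_d).
#' @noRd
hazard_cellsum <- function(ws, rates) {
  cellsum(rates$lamA[ws$iA] * ws$len, ws$cell, ws$p)
}

#' Coalescent log-likelihood under a Lambda measure and grid Ne
#'
#' Evaluates the log density of the sufficient statistics `(m, t)` of a
#' heterochronous multifurcating genealogy given the sampling schedule, the
#' base measure and the piecewise-constant `Ne` encoded by `grid$gamma`.
#' Computed fully in log space; the exponent integral is evaluated exactly
#' over the change-point partition (set `riemann = TRUE` for the coarser
#' grid-cell Riemann sum, which freezes `A(t)` at each cell midpoint).
#'
#' @param data a [coal_data].
#' @param measure a [lambda_measure][beta_measure].
#' @param grid an [ne_grid] with `gamma` set.
#' @param riemann use the grid-cell Riemann approximation of the exponent.
#' @return log-likelihood (scalar).
#' @export
loglik <- function(data, measure, grid, riemann = FALSE) {
  if (is.null(grid$gamma)) stop("grid has no gamma values")
  ws <- lik_workspace(data, grid)
  rates <- rates_for_measure(ws, measure)
  gamma <- grid$gamma
  pt <- ws$lch_sum + sum(rates$loglam_ev) - sum(ws$cnt * gamma)
  if (!riemann) {
    return(pt - sum(hazard_cellsum(ws, rates) * exp(-gamma)))
  }
  # Riemann mode: one lambda_A per grid cell, A taken at the cell midpoint
  xm <- (grid$x[-grid$D] + grid$x[-1]) / 2
  Am <- as.integer(lineage_count(data, xm))
  act <- Am >= 2L
  wsr <- list(dA = sort(unique(Am[act])), A_k = ws$A_k, m_k = ws$m_k)
  wsr$skel <- list(B = rep.int(wsr$dA, wsr$dA - 1L),
                   K = unlist(lapply(wsr$dA, function(b) 2:b)),
                   grp = rep.int(seq_along(wsr$dA), wsr$dA - 1L))
  wsr$skel$lch <- lchoose(wsr$skel$B, wsr$skel$K)
  r2 <- rates_for_measure(wsr, measure)
  lamc <- numeric(grid$D - 1L)
  lamc[act] <- r2$lamA[match(Am[act], wsr$dA)]
  pt - sum(lamc * diff(grid$x) * exp(-gamma))
}

#' Topology-only (block-size) log pseudo-likelihood
#'
#' The log probability of the observed block sizes given the lineage-count
#' sequence under the Beta(2-alpha, alpha) coalescent:
#' `sum_k log[ C(A_k, m_k) lambda_{A_k,m_k}(alpha) / lambda_{A_k}(alpha) ]`.
#' Depends on the topology (m and A) only, not on the coalescent times or
#' `Ne`, so it is invariant to any rescaling of time.
#'
#' @param data a [coal_data].
#' @param alpha Beta parameter in (0, 2] (`2` = Kingman limit).
#' @export
topology_loglik <- function(data, alpha) {
  if (alpha <= 0 || alpha > 2) stop("'alpha' must be in (0, 2]")
  A_k <- as.integer(lineage_count(data, data$t))
  measure <- if (alpha == 2) kingman_measure() else beta_measure(alpha)
  dA <- sort(unique(A_k))
  skel <- list(B = rep.int(dA, dA - 1L),
               K = unlist(lapply(dA, function(b) 2:b), use.names = FALSE),
               grp = rep.int(seq_along(dA), dA - 1L))
  skel$lch <- lchoose(skel$B, skel$K)
  logtot <- if (alpha == 2) lchoose(dA, 2) else
    beta_logtot_skel(alpha, skel, length(dA))
  sum(lchoose(A_k, data$m) + log_merger_rate(measure, A_k, data$m) -
        logtot[match(A_k, dA)])
}

#' Gradient of the coalescent log-likelihood in gamma
#'
#' `d loglik / d gamma_d = -(# events in cell d) +
#'  sum_{intervals in cell d} lambda_A * length * exp(-gamma_d)`.
#'
#' @inheritParams loglik
#' @return numeric vector of length `D - 1`.
#' @export
loglik_grad_gamma <- function(data, measure, grid) {
  if (is.null(grid$gamma)) stop("grid has no gamma values")
  ws <- lik_workspace(data, grid)
  rates <- rates_for_measure(ws, measure)
  -ws$cnt + hazard_cellsum(ws, rates) * exp(-grid$gamma)
}
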