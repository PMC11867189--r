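# Performance metrics for skyline estimates and the simulation-study driver.

#' Skyline accuracy metrics against a known trajectory
#'
#' Evaluated at the grid cells of the estimate (truth taken at the cell
#' midpoints): `coverage` is the fraction of cells whose 95% band contains
#' the truth; `bias`, `deviance` and `mse` are the mean signed error, mean
#' absolute error and mean squared error of `log(Ne_hat) - log(Ne_true)`.
#' Log-scale error definitions are used because the skyline is modelled and
#' plotted on the log scale; coverage is scale-free.
#'
#' @param result a `posterior_result`.
#' @param truth a vectorized function `Ne(t)` (positive), or a single
#'   positive number for a constant trajectory.
#' @return list with `coverage`, `bias`, `deviance`, `mse`.
#' @export
ne_metrics <- function(result, truth) {
  f <- if (is.function(truth)) truth else function(t) rep(truth, length(t))
  tv <- f(result$t_mid)
  if (any(tv <= 0)) stop("truth must be positive on the grid")
  err <- log(result$ne_median) - log(tv)
  list(coverage = mean(result$ne_lower95 <= tv & tv <= result$ne_upper95),
       bias = mean(err),
       deviance = mean(abs(err)),
       mse = mean(err^2))
}

study_truth <- function(trajectory) {
  switch(trajectory,
         uniform = function(t) rep(100, length(t)),
         exponential = function(t) 1000 * exp(-t),
         boombust = function(t) 1000 * exp(-abs(t - 1)),
         stop("unknown trajectory: ", trajectory))
}

study_schedule <- function(id, n) {
  switch(id,
         iso = iso_schedule(n),
         two = split_schedule(n, c(0.5, 0.5)),
         four = split_schedule(n, c(0.5, 0.3, 0.1, 0.1)),
         stop("unknown schedule: ", id))
}

#' Simulation-study driver
#'
#' Simulates Beta-coalescent genealogies for every combination of `alphas`,
#' `ns`, `trajectories` and `schedules`, runs the requested estimation
#' methods on each tree and records alpha estimates plus skyline metrics.
#' Replicate seeds are derived deterministically from `seed`, so the same
#' seed reproduces the same table.  Defaults are desk-scale (5 replicates);
#' the full-scale study uses 50.
#'
#' @param alphas,ns,trajectories,schedules study factors.
#' @param replicates trees per factor combination.
#' @param methods subset of `c("blocksize", "hybrid", "mcmc")`; `blocksize`
#'   means the block-size pseudo-likelihood MLE of alpha followed by the
#'   Laplace skyline fit.
#' @param mcmc_iters MCMC iterations per tree.
#' @param D grid points for the skyline.
#' @param seed base seed.
#' @return data.frame, one row per (replicate x method).
#' @export
run_study <- function(alphas = c(1, 1.5, 1.8), ns = c(20, 50, 100),
                      trajectories = c("uniform", "exponential", "boombust"),
                      schedules = c("iso", "two", "four"),
                      replicates = 5,
                      methods = c("blocksize", "hybrid", "mcmc"),
                      mcmc_iters = 5000, D = 100, seed = 1) {
  rows <- list()
  cfg <- 0L
  for (a in alphas) for (n in ns) for (tr in trajectories) {
    truth <- study_truth(tr)
    for (sc in schedules) {
      cfg <- cfg + 1L
      for (r in seq_len(replicates)) {
        sim_seed <- (seed + 7919L * cfg + r) %% .Machine$integer.max
        sim <- simulate_genealogy(beta_measure(a), tr,
                                  study_schedule(sc, n),
                                  seed = sim_seed, tree = FALSE)
        for (meth in methods) {
          fit <- switch(meth,
            blocksize = {
              ab <- estimate_alpha_blocksize(sim$data)$alpha
              fit_ne_given_alpha(sim$data, alpha = ab, D = D)
            },
            hybrid = estimate_hybrid(sim$data, D = D),
            mcmc = run_mcmc(sim$data, D = D, iterations = mcmc_iters,
                            seed = sim_seed + 1L)$result,
            stop("unknown method: ", meth))
          met <- ne_metrics(fit, truth)
          rows[[length(rows) + 1L]] <- data.frame(
            alpha_true = a, n = n, trajectory = tr, schedule = sc,
            replicate = r, method = meth, alpha_hat = fit$alpha,
            coverage = met$coverage, bias = met$bias,
            deviance = met$deviance, mse = met$mse)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Aggregate a study table into per-cell summaries
#'
#' Pools sampling schedules and reports, per (alpha, n, trajectory, method),
#' the mean coverage and the median deviance and MSE.
#'
#' @param study a data.frame from [run_study()].
#' @export
summarize_study <- function(study) {
  agg <- function(x, f) stats::aggregate(
    x, by = study[c("alpha_true", "n", "trajectory", "method")], FUN = f)
  out <- agg(study["coverage"], mean)
  out$deviance <- agg(study["deviance"], stats::median)$deviance
  out$mse <- agg(study["mse"], stats::median)$mse
  out
}

#' Canonical study datasets
#'
#' One seedable genealogy per built-in trajectory (constant, exponential
#' growth, boom-bust), simulated at alpha = 1.5 with 50 tips; used as shared
#' fixtures by the test suite and examples.
#'
#' @param trajectory one of `"uniform"`, `"exponential"`, `"boombust"`.
#' @param seed integer seed.
#' @param n number of tips.
#' @return a [coal_data].
#' @export
canonical_dataset <- function(trajectory = c("uniform", "exponential",
                                             "boombust"),
                              seed = 1, n = 50) {
  trajectory <- match.arg(trajectory)
  off <- match(trajectory, c("uniform", "exponential", "boombust"))
  simulate_genealogy(beta_measure(1.5), trajectory, n,
                     seed = seed + 1000L * off, tree = FALSE)$data
}
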