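# Backward-in-time simulation of Lambda-coalescent genealogies with
# piecewise-constant (or discretized continuous) Ne(t) and heterochronous
# sampling.  Waiting times are drawn by analytic inversion of the cumulative
# hazard lambda_A * int du/Ne(u) cell by cell (constant hazard within a
# cell), with no thinning; crossing a sampling time restarts the draw, which
# is exact by memorylessness of the exponential.

# Internal step-function representation of Ne(t): left cell edges `breaks`
# (breaks[1] = 0), values `vals`, optional generating function `fn` used to
# extend the discretization past the current horizon (2000 cells per
# horizon-length chunk); without `fn` the last value extends to infinity.
ne_steps <- function(ne, horizon = 10, cells = 2000) {
  env <- new.env(parent = emptyenv())
  env$h <- horizon / cells
  if (is.character(ne)) {
    ne <- match.arg(ne, c("uniform", "exponential", "boombust"))
    if (ne == "uniform") {
      env$breaks <- 0; env$vals <- 100; env$fn <- NULL
      return(env)
    }
    fn <- switch(ne,
      exponential = function(t) 1000 * exp(-t),
      boombust = function(t) 1000 * exp(-abs(t - 1)))
    env$fn <- fn
  } else if (is.function(ne)) {
    env$fn <- ne
  } else if (inherits(ne, "ne_grid")) {
    if (is.null(ne$gamma)) stop("ne_grid has no gamma values")
    env$breaks <- ne$x[-ne$D]
    env$vals <- exp(ne$gamma)
    env$fn <- NULL
    return(env)
  } else if (is.numeric(ne) && length(ne) == 1L) {
    if (ne <= 0) stop("Ne must be positive")
    env$breaks <- 0; env$vals <- ne; env$fn <- NULL
    return(env)
  } else {
    stop("'ne' must be a trajectory name, function, ne_grid or scalar")
  }
  env$breaks <- numeric(0); env$vals <- numeric(0)
  ne_extend(env, horizon)
  env
}

ne_extend <- function(env, upto) {
  while (length(env$breaks) == 0 ||
         env$breaks[length(env$breaks)] + env$h < upto) {
    from <- if (length(env$breaks)) env$breaks[length(env$breaks)] + env$h else 0
    new_b <- seq(from, by = env$h, length.out = 2000L)
    v <- env$fn(new_b + env$h / 2)
    if (any(!is.finite(v) | v <= 0)) stop("Ne trajectory must be positive")
    env$breaks <- c(env$breaks, new_b)
    env$vals <- c(env$vals, v)
  }
  invisible(env)
}

# Inverse-hazard draw: first time t* > cur with
# lam * int_cur^{t*} du/Ne(u) = Exp(1).
draw_coal_time <- function(env, lam, cur) {
  E <- stats::rexp(1)
  t <- cur
  i <- findInterval(t, env$breaks)
  if (i < 1L) i <- 1L
  repeat {
    if (i > length(env$vals)) {
      if (is.null(env$fn)) {
        # tail extension: last value holds forever
        return(t + E * env$vals[length(env$vals)] / lam)
      }
      ne_extend(env, env$breaks[length(env$breaks)] + 2000 * env$h)
    }
    v <- env$vals[i]
    endt <- if (i < length(env$breaks)) env$breaks[i + 1L] else
      if (is.null(env$fn)) Inf else env$breaks[i] + env$h
    cap <- lam * (endt - t) / v
    if (E <= cap) return(t + E * v / lam)
    E <- E - cap
    t <- endt
    i <- i + 1L
  }
}

#' Simulate a Lambda-coalescent genealogy
#'
#' Generates a multifurcating genealogy backward in time under any base
#' measure, a variable effective population size and an arbitrary sampling
#' schedule.  While lineages remain, the next coalescent waiting time is
#' drawn from the time-inhomogeneous exponential with cumulative hazard
#' `lambda_A * int du/Ne(u)` (inverted analytically across Ne cells); if the
#' drawn time passes the next sampling time the process advances there and
#' the new tips join.  At an event the block size is drawn from
#' [block_size_pmf()] and the participating lineages are chosen uniformly.
#'
#' @param measure a [lambda_measure][beta_measure].
#' @param ne effective population size: a positive scalar, one of
#'   `"uniform"` (Ne = 100), `"exponential"` (Ne(t) = 1000 e^-t),
#'   `"boombust"` (Ne(t) = 1000 e^-|t-1|), a positive function of time, or
#'   an [ne_grid] with `gamma` set (last value extended into the past).
#' @param schedule a [sampling_schedule], or an integer for isochronous
#'   sampling at time 0.
#' @param seed optional integer seed (deterministic output under a fixed
#'   seed).
#' @param tree also build the `timed_tree` (set `FALSE` in large replicate
#'   studies that only need the sufficient statistics).
#' @return list with `data` (a [coal_data]), `newick`, and (if requested)
#'   `tree` (a [timed_tree]).
#' @examples
#' sim <- simulate_genealogy(beta_measure(1.5), "uniform", 20, seed = 1)
#' sim$data
#' @export
simulate_genealogy <- function(measure, ne, schedule, seed = NULL,
                               tree = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  if (!inherits(schedule, "sampling_schedule")) {
    schedule <- iso_schedule(schedule)
  }
  env <- ne_steps(ne)
  s <- schedule$s; ncnt <- schedule$n; L <- schedule$L
  tipno <- 0L
  add_tips <- function(j) {
    labs <- paste0("t", tipno + seq_len(ncnt[j]))
    tipno <<- tipno + ncnt[j]
    list(str = labs, time = rep(s[j], ncnt[j]))
  }
  tp <- add_tips(1L)
  node_str <- tp$str; node_time <- tp$time
  cur <- 0; nexts <- 2L
  tt <- numeric(0); mm <- integer(0)
  pmf_cache <- list()
  lam_cache <- list()
  repeat {
    A <- length(node_str)
    tc <- if (A >= 2L) {
      key <- as.character(A)
      if (is.null(lam_cache[[key]])) {
        lam_cache[[key]] <- total_rate(measure, A)
      }
      draw_coal_time(env, lam_cache[[key]], cur)
    } else Inf
    if (nexts <= L && tc > s[nexts]) {
      cur <- s[nexts]
      tp <- add_tips(nexts)
      node_str <- c(node_str, tp$str)
      node_time <- c(node_time, tp$time)
      nexts <- nexts + 1L
      next
    }
    if (!is.finite(tc)) break            # single lineage, no samples left
    key <- as.character(A)
    if (is.null(pmf_cache[[key]])) {
      pmf_cache[[key]] <- block_size_pmf(measure, A)
    }
    pmf <- pmf_cache[[key]]
    k <- if (A == 2L) 2L else sample.int(A - 1L, 1L, prob = pmf) + 1L
    pick <- sample.int(A, k)
    bl <- tc - node_time[pick]
    merged <- paste0("(", paste0(node_str[pick], ":",
                                 sprintf("%.12g", bl), collapse = ","), ")")
    node_str <- c(node_str[-pick], merged)
    node_time <- c(node_time[-pick], tc)
    tt <- c(tt, tc); mm <- c(mm, k); cur <- tc
    if (length(node_str) == 1L && nexts > L) break
  }
  newick <- paste0(node_str, ";")
  data <- coal_data(schedule, NULL, tt, mm)
  out <- list(data = data, newick = newick)
  if (tree) out$tree <- read_newick(newick)
  out
}

#' Average merger block size over simulated genealogies
#'
#' Simulates `replicates` isochronous genealogies at constant `Ne` and
#' averages all block sizes; replicate `r` uses seed `seed + r`.  Under
#' Kingman this is exactly 2; it grows as `alpha` decreases and shrinks with
#' the number of tips.
#'
#' @inheritParams simulate_genealogy
#' @param n number of tips.
#' @param replicates number of simulated trees.
#' @param ne constant effective population size.
#' @export
average_block_size <- function(measure, n, replicates = 500, seed = 1,
                               ne = 1) {
  m_all <- unlist(lapply(seq_len(replicates), function(r) {
    simulate_genealogy(measure, ne, n, seed = seed + r, tree = FALSE)$data$m
  }))
  mean(m_all)
}
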