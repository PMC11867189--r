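# Heterochronous multifurcating genealogies and their sufficient statistics.
#
# Time runs backward: 0 is the most recent tip and increases into the past.
# A genealogy with sampling times s (counts n), coalescent times t and block
# sizes m is summarized by the lineage-count step function
#   A(t) = sum_i n_i 1(s_i < t) - sum_k (m_k - 1) 1(t_k < t).

#' Sampling schedule of a serially sampled genealogy
#'
#' @param s strictly increasing sampling times with `s[1] == 0` (time 0 is
#'   the most recent sample, increasing into the past).
#' @param n positive integer sample counts, one per sampling time.
#' @return object of class `sampling_schedule`.
#' @export
sampling_schedule <- function(s, n) {
  s <- as.numeric(s); n <- as.integer(n)
  stopifnot(length(s) == length(n), length(s) >= 1)
  if (s[1] != 0) stop("first sampling time must be 0")
  if (any(diff(s) <= 0)) stop("sampling times must be strictly increasing")
  if (any(n < 1)) stop("sample counts must be positive")
  if (sum(n) < 2) stop("need at least 2 samples in total")
  structure(list(s = s, n = n, L = length(s)), class = "sampling_schedule")
}

#' @rdname sampling_schedule
#' @param n_total total number of tips, all sampled at time 0.
#' @export
iso_schedule <- function(n_total) sampling_schedule(0, n_total)

#' Split `n_total` tips across sampling times in given proportions.
#' Counts are rounded, with the remainder assigned to the first time.
#' @rdname sampling_schedule
#' @param props sampling proportions (summing to 1).
#' @param spacing spacing between consecutive sampling times.
#' @export
split_schedule <- function(n_total, props, spacing = 0.2) {
  stopifnot(abs(sum(props) - 1) < 1e-8)
  n <- floor(n_total * props)
  n[1] <- n[1] + (n_total - sum(n))
  sampling_schedule(seq(0, by = spacing, length.out = length(props)), n)
}

#' Sufficient statistics of a timed multifurcating genealogy
#'
#' Bundles the sampling schedule with the coalescent times `t` (strictly
#' increasing, > 0) and block sizes `m` (each >= 2).  Validates that the
#' most recent common ancestor is reached, `sum(m - 1) == sum(n) - 1`, and
#' that each event has at least `m[k]` extant lineages available.
#'
#' @param s,n sampling times and counts (or a [sampling_schedule]).
#' @param t coalescent times.
#' @param m block sizes.
#' @return object of class `coal_data`.
#' @export
coal_data <- function(s, n, t, m) {
  sched <- if (inherits(s, "sampling_schedule")) s else sampling_schedule(s, n)
  t <- as.numeric(t); m <- as.integer(m)
  stopifnot(length(t) == length(m), length(t) >= 1)
  o <- order(t)
  t <- t[o]; m <- m[o]
  if (any(t <= 0)) stop("coalescent times must be > 0")
  # exact ties between events (or with a sampling time) are a measure-zero
  # degeneracy of the point-process density; perturb pastward and warn
  guard <- 0L
  while ((any(diff(t) == 0) || any(t %in% sched$s)) && guard < 64L) {
    bad <- which(c(FALSE, diff(t) == 0) | t %in% sched$s)
    t[bad] <- t[bad] + 1e-9
    o <- order(t); t <- t[o]; m <- m[o]
    guard <- guard + 1L
    if (guard == 1L) warning("coincident event times perturbed by +1e-9")
  }
  if (any(m < 2)) stop("block sizes must be >= 2")
  if (sum(m - 1L) != sum(sched$n) - 1L) {
    stop("sum(m - 1) must equal n - 1 (genealogy must reach its MRCA)")
  }
  out <- structure(list(s = sched$s, n = sched$n, t = t, m = m,
                        n_total = sum(sched$n), K = length(t)),
                   class = "coal_data")
  A <- lineage_count(out, t)
  if (any(A < m)) stop("block size exceeds extant lineages at an event")
  out
}

#' @export
print.coal_data <- function(x, ...) {
  cat(sprintf("<coal_data> n = %d tips at %d sampling time(s), K = %d events, TMRCA = %.4g\n",
              x$n_total, length(x$s), x$K, max(x$t)))
  invisible(x)
}

#' Number of extant ancestral lineages A(t)
#'
#' Evaluates \eqn{A(t) = \sum_i n_i 1(s_i < t) - \sum_k (m_k - 1) 1(t_k < t)}.
#' The strict inequalities make `A` right-continuous in the process sense:
#' at a sampling time the newly added tips are not yet counted, and at a
#' coalescent time the merger has not yet been applied.
#'
#' @param data a [coal_data] object.
#' @param t vector of times (>= 0).
#' @return integer vector of lineage counts.
#' @export
lineage_count <- function(data, t) {
  vapply(t, function(tt) {
    sum(data$n[data$s < tt]) - sum((data$m - 1L)[data$t < tt])
  }, numeric(1))
}

# ---------------------------------------------------------------------------
# Newick I/O

#' Read a timed (possibly multifurcating) genealogy from Newick
#'
#' Internal branches of length at most `collapse_tol` are collapsed into
#' multifurcations (maximum-likelihood tree software typically encodes
#' polytomies as near-zero branches).  Node times are measured from the most
#' recent tip (time 0) into the past.  Tip labels may carry a decimal-year
#' date suffix `"name|2003.45"`; the latest date is then recorded as the
#' calendar anchor of time 0.
#'
#' @param x a Newick string or path to a Newick file.
#' @param collapse_tol branches of length <= this are collapsed.
#' @return object of class `timed_tree`: the `ape::phylo` tree plus node
#'   times.
#' @export
read_newick <- function(x, collapse_tol = 1e-8) {
  txt <- if (length(x) == 1L && !grepl("(", x, fixed = TRUE) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    x
  }
  phy <- tryCatch(suppressWarnings(ape::read.tree(text = txt)),
                  error = function(e) NULL)
  if (is.null(phy)) stop("malformed Newick input")
  if (is.null(phy$edge.length)) stop("Newick input must have branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch lengths are not allowed")
  timed_tree(phy, collapse_tol = collapse_tol)
}

#' @rdname read_newick
#' @param phy an `ape::phylo` object with branch lengths.
#' @export
timed_tree <- function(phy, collapse_tol = 1e-8) {
  stopifnot(inherits(phy, "phylo"))
  phy <- ape::di2multi(phy, tol = collapse_tol)
  ntip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  times <- max(depth[seq_len(ntip)]) - depth
  anchor <- NA_real_
  if (all(grepl("|", phy$tip.label, fixed = TRUE))) {
    dates <- suppressWarnings(
      as.numeric(sub("^.*\\|", "", phy$tip.label)))
    if (!anyNA(dates)) anchor <- max(dates)
  }
  structure(list(phylo = phy, times = times, n_tip = ntip,
                 collapse_tol = collapse_tol, calendar_anchor = anchor),
            class = "timed_tree")
}

#' @export
print.timed_tree <- function(x, ...) {
  cat(sprintf("<timed_tree> %d tips, %d internal nodes, TMRCA = %.4g\n",
              x$n_tip, x$phylo$Nnode, max(x$times)))
  invisible(x)
}

#' @rdname read_newick
#' @param tree a `timed_tree` (or `ape::phylo`).
#' @param file optional output path; if `NULL` the Newick string is returned.
#' @export
write_newick <- function(tree, file = NULL) {
  phy <- if (inherits(tree, "timed_tree")) tree$phylo else tree
  if (is.null(file)) ape::write.tree(phy) else ape::write.tree(phy, file = file)
}

#' Extract sufficient statistics (s, n, t, m) from a timed tree
#'
#' Tips are grouped into sampling times by clustering their node times with
#' tolerance `tol`; coalescent times are the internal-node times and block
#' sizes the internal-node out-degrees.
#'
#' @param tree a [timed_tree].
#' @param tol grouping tolerance for tip dates (defaults to the tree's
#'   collapse tolerance).
#' @return a [coal_data] object.
#' @export
sufficient_stats <- function(tree, tol = tree$collapse_tol) {
  phy <- tree$phylo
  ntip <- tree$n_tip
  tip_t <- tree$times[seq_len(ntip)]
  o <- order(tip_t)
  st <- tip_t[o]
  grp <- cumsum(c(TRUE, diff(st) > tol))
  s <- as.numeric(tapply(st, grp, min))
  s[1] <- 0
  n <- as.integer(table(grp))
  node_ids <- ntip + seq_len(phy$Nnode)
  t_int <- tree$times[node_ids]
  m <- tabulate(phy$edge[, 1], nbins = ntip + phy$Nnode)[node_ids]
  coal_data(s, n, t_int, m)
}

# ---------------------------------------------------------------------------
# Tabular export of sufficient statistics (TSV: event_type, time, value)

#' Read/write sufficient statistics as TSV
#'
#' Columns: `event_type` (`sample` or `coalescent`), `time`, and
#' `count_or_blocksize` (sample count at a sampling time, block size at a
#' coalescent time).
#'
#' @param data a [coal_data].
#' @param file path.
#' @export
write_stats <- function(data, file) {
  df <- rbind(
    data.frame(event_type = "sample", time = data$s,
               count_or_blocksize = data$n),
    data.frame(event_type = "coalescent", time = data$t,
               count_or_blocksize = data$m)
  )
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_stats
#' @export
read_stats <- function(file) {
  df <- utils::read.delim(file)
  need <- c("event_type", "time", "count_or_blocksize")
  if (!all(need %in% names(df))) stop("stats TSV must have columns: ",
                                      paste(need, collapse = ", "))
  sm <- df$event_type == "sample"
  coal_data(df$time[sm], df$count_or_blocksize[sm],
            df$time[!sm], df$count_or_blocksize[!sm])
}
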