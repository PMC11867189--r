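# Internal numerical helpers.

#' Numerically stable log(sum(exp(x)))
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Grouped logsumexp: one value per level of `g` (in `ug` order).
#' @noRd
logsumexp_by <- function(x, g, ug = sort(unique(g))) {
  f <- factor(g, levels = ug)
  gm <- vapply(split(x, f), max, numeric(1))
  s <- rowsum(exp(x - gm[as.integer(f)]), f)
  unname(gm + log(as.vector(s)))
}

#' Sum weights into cells 1..nc (cells with no weight get 0).
#' @noRd
cellsum <- function(w, cell, nc) {
  out <- numeric(nc)
  if (length(w)) {
    s <- rowsum(w, cell)
    out[as.integer(rownames(s))] <- as.vector(s)
  }
  out
}

# package-local cache (per-n rate tables on the alpha grid, etc.)
.ls_cache <- new.env(parent = emptyenv())

#' @noRd
cache_get_or <- function(key, fn) {
  if (!exists(key, envir = .ls_cache, inherits = FALSE)) {
    assign(key, fn(), envir = .ls_cache)
  }
  get(key, envir = .ls_cache, inherits = FALSE)
}
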