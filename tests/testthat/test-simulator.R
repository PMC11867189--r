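# Simulator calibration: waiting-time law, block-size law, special cases.

test_that("simulation is deterministic under a fixed seed", {
  s1 <- simulate_genealogy(beta_measure(1.5), "exponential",
                           split_schedule(20, c(0.5, 0.5)), seed = 9)
  s2 <- simulate_genealogy(beta_measure(1.5), "exponential",
                           split_schedule(20, c(0.5, 0.5)), seed = 9)
  expect_identical(s1$newick, s2$newick)
  expect_equal(s1$data$t, s2$data$t)
})

test_that("Kingman n = 2 TMRCA is exponential with mean Ne", {
  ne <- 40
  reps <- 4000
  tm <- vapply(seq_len(reps), function(r) {
    simulate_genealogy(kingman_measure(), ne, 2, seed = r, tree = FALSE)$data$t
  }, numeric(1))
  se <- stats::sd(tm) / sqrt(reps)
  expect_lt(abs(mean(tm) - ne), 3 * se)
})

test_that("star coalescent: one event merging everything, mean wait 1", {
  reps <- 2000
  sims <- lapply(seq_len(reps), function(r) {
    simulate_genealogy(star_measure(), 1, 10, seed = r, tree = FALSE)$data
  })
  expect_true(all(vapply(sims, function(d) d$K == 1L && d$m == 10L,
                         logical(1))))
  w <- vapply(sims, function(d) d$t, numeric(1))
  expect_lt(abs(mean(w) - 1), 3 * stats::sd(w) / sqrt(reps))
})

test_that("hazard-transformed waiting times are unit exponential", {
  # first inter-event hazard under exponential-growth Ne: the transform
  # lambda_A * int_0^t du/Ne(u) of the first waiting time must be Exp(1)
  reps <- 3000
  n <- 8
  lam <- total_rate(beta_measure(1.5), n)
  u <- vapply(seq_len(reps), function(r) {
    t1 <- simulate_genealogy(beta_measure(1.5), "exponential", n,
                             seed = 20000 + r, tree = FALSE)$data$t[1]
    lam * integrate(function(x) exp(x) / 1000, 0, t1, rel.tol = 1e-10)$value
  }, numeric(1))
  expect_gt(stats::ks.test(u, "pexp")$p.value, 0.01)
})

test_that("block sizes follow the block-size pmf", {
  # isochronous, constant Ne: condition on the first event from A = n
  n <- 12
  reps <- 4000
  m1 <- vapply(seq_len(reps), function(r) {
    simulate_genealogy(beta_measure(1.2), 1, n, seed = 50000 + r,
                       tree = FALSE)$data$m[1]
  }, integer(1))
  p <- block_size_pmf(beta_measure(1.2), n)
  obs <- tabulate(m1, nbins = n)[2:n]
  keep <- p * reps >= 5
  x <- obs[keep]; pp <- p[keep]
  if (any(!keep)) {
    x <- c(x, sum(obs[!keep])); pp <- c(pp, sum(p[!keep]))
  }
  chi <- stats::chisq.test(x = x, p = pp / sum(pp))
  expect_gt(chi$p.value, 0.01)
})

test_that("near-Kingman Beta trees are almost all binary", {
  m_all <- unlist(lapply(1:50, function(r) {
    simulate_genealogy(beta_measure(1.999), 1, 50, seed = 300 + r,
                       tree = FALSE)$data$m
  }))
  expect_lte(mean(m_all > 2), 0.01)
})

test_that("average block size decreases with alpha and with n", {
  expect_equal(average_block_size(kingman_measure(), 20, replicates = 20), 2)
  a_low <- average_block_size(beta_measure(1.1), 100, replicates = 120,
                              seed = 7)
  a_high <- average_block_size(beta_measure(1.9), 100, replicates = 120,
                               seed = 7)
  expect_lt(a_high, a_low)
  # sample-size effect: with more tips the process spends time in larger-A
  # states whose block-size law has a heavier mean, so the tree-average
  # block size grows with n (measured here; see the methods vignette for
  # discussion: verbal accounts of this direction vary)
  b_small <- average_block_size(beta_measure(1.5), 20, replicates = 200,
                                seed = 11)
  b_large <- average_block_size(beta_measure(1.5), 100, replicates = 200,
                                seed = 11)
  expect_gt(b_large, b_small)
})

test_that("smaller alpha gives stochastically longer genealogies", {
  # smaller alpha means smaller total rates, hence longer branches; the
  # signal lives in the total branch length (the TMRCA itself is dominated
  # by the final pairwise phase whose rate lambda_2 = 1 is alpha-free)
  reps <- 120
  tree_len <- function(d) {
    bp <- sort(unique(c(0, d$s, d$t)))
    mid <- (bp[-1] + bp[-length(bp)]) / 2
    sum(lineage_count(d, mid) * diff(bp))
  }
  tlen <- function(a) vapply(seq_len(reps), function(r) {
    tree_len(simulate_genealogy(beta_measure(a), "exponential", 20,
                                seed = 900 + r, tree = FALSE)$data)
  }, numeric(1))
  l10 <- tlen(1.0); l15 <- tlen(1.5); l18 <- tlen(1.8)
  expect_lt(stats::wilcox.test(l10, l15, alternative = "greater")$p.value,
            0.01)
  expect_lt(stats::wilcox.test(l15, l18, alternative = "greater")$p.value,
            0.01)
})

test_that("heterochronous simulation respects the schedule", {
  sch <- split_schedule(30, c(0.5, 0.3, 0.1, 0.1), spacing = 0.2)
  for (r in 1:5) {
    d <- simulate_genealogy(beta_measure(1.3), "boombust", sch,
                            seed = 40 + r, tree = FALSE)$data
    expect_equal(d$s, sch$s)
    expect_equal(d$n, sch$n)
    # no more mergers than lineages available at any event
    expect_true(all(lineage_count(d, d$t) >= d$m))
  }
})

test_that("ne_grid input and tail extension drive the simulator", {
  g <- ne_grid(c(0, 1, 2), gamma = log(c(5, 50)))
  d <- simulate_genealogy(kingman_measure(), g, 10, seed = 77,
                          tree = FALSE)$data
  expect_s3_class(d, "coal_data")
  expect_gt(max(d$t), 0)
})
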