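test_that("permutation correlation handles identities, symmetry and missing pairs", {
  x <- c(1.2, -0.5, 3.1, 0.4, 2.2, -1.7, 0.9, 1.1)
  pr <- perm_corr(x, x, n_perm = 200L, seed = 1L)
  expect_equal(pr$r_obs, 1)
  expect_equal(pr$p_perm, 1 / 201)
  # p is invariant to exchanging x and y
  set.seed(2)
  y <- rnorm(8)
  expect_equal(perm_corr(x, y, n_perm = 500L, seed = 3L)$p_perm,
               perm_corr(y, x, n_perm = 500L, seed = 3L)$p_perm,
               tolerance = 0.05)
  # NaN pairs are dropped pairwise with a message
  x2 <- c(x, NaN); y2 <- c(y, 5)
  expect_message(pr2 <- perm_corr(x2, y2, n_perm = 100L, seed = 4L), "dropped")
  expect_equal(pr2$n, 8L)
  expect_error(perm_corr(rep(1, 5), 1:5), "constant")
  expect_error(perm_corr(1:2, 2:1), "at least 3")
  # null quantiles bracket zero for independent data
  set.seed(5)
  pr3 <- perm_corr(rnorm(50), rnorm(50), n_perm = 500L, seed = 6L)
  expect_lt(pr3$null_quantiles[1L], 0)
  expect_gt(pr3$null_quantiles[2L], 0)
})

test_that("null permutation p-values are uniform to permutation granularity", {
  set.seed(20)
  ps <- vapply(1:400, function(i) {
    perm_corr(rnorm(20), rnorm(20), n_perm = 99L, seed = i)$p_perm
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("the dependent-correlation test matches an independent Steiger implementation", {
  # symmetry: equal correlations give z = 0, p = 1
  res0 <- dependent_corr_test(0.4, 0.4, 0.3, 80)
  expect_equal(res0$z, 0)
  expect_equal(res0$p, 1)
  # textbook configuration against a second implementation of the formula
  res <- dependent_corr_test(0.5, 0.3, 0.2, 100)
  expect_equal(res$z, steiger_oracle(0.5, 0.3, 0.2, 100), tolerance = 1e-10)
  set.seed(21)
  for (i in 1:20) {
    r12 <- runif(1, -0.8, 0.8); r13 <- runif(1, -0.8, 0.8)
    r23 <- runif(1, -0.5, 0.5); n <- sample(10:500, 1)
    expect_equal(dependent_corr_test(r12, r13, r23, n)$z,
                 steiger_oracle(r12, r13, r23, n), tolerance = 1e-10)
  }
  # |z| grows with n at fixed correlations
  zs <- vapply(c(20, 50, 200, 1000), function(n) {
    abs(dependent_corr_test(0.5, 0.3, 0.2, n)$z)
  }, 0)
  expect_true(all(diff(zs) > 0))
  expect_error(dependent_corr_test(1, 0.3, 0.2, 50), "degenerate")
})

test_that("period segmentation recovers planted breakpoints and echoes fixed bounds", {
  epochs <- snapshot_schedule(1000L)
  x <- log10(epochs)
  b <- c(10L, 30L)
  q <- numeric(length(epochs))
  q[1:b[1L]] <- 0.1
  q[(b[1L] + 1L):b[2L]] <- 0.1 + 0.08 * (x[(b[1L] + 1L):b[2L]] - x[b[1L]])
  peak <- q[b[2L]]
  q[(b[2L] + 1L):length(q)] <- peak - 0.03 * (x[(b[2L] + 1L):length(q)] - x[b[2L]])
  seg <- segment_periods(q, epochs, mode = "changepoint")
  expect_false(seg$degenerate)
  expect_lte(abs(max(seg$early) - b[1L]), 1L)
  expect_lte(abs(max(seg$middle) - b[2L]), 1L)
  # segments are contiguous, ordered and cover the schedule
  expect_identical(c(seg$early, seg$middle, seg$late), seq_along(epochs))

  # monotone trajectory (linear in log-epoch): still three contiguous
  # segments, flagged degenerate
  q_mono <- 0.1 + 0.1 * (x - x[1L]) / (max(x) - x[1L])
  expect_message(segm <- segment_periods(q_mono, epochs), "degenerate")
  expect_identical(c(segm$early, segm$middle, segm$late), seq_along(epochs))
  expect_true(segm$degenerate)

  # fixed mode is the identity on its bounds
  segf <- segment_periods(q, epochs, mode = "fixed", fixed_bounds = c(14, 700))
  expect_equal(segf$bounds_epoch, c(14, 700))
  expect_error(segment_periods(c(q[1:5], NA), epochs[1:6]), "non-finite")
})

test_that("per-period correlation tables skip degenerate periods informatively", {
  fr <- frozen_run()
  q_flat <- rep(0.1, length(fr$schedule))
  seg <- segment_periods(q_flat, fr$schedule, mode = "fixed",
                         fixed_bounds = c(3, 8))
  ip <- matrix(runif(196), 14, 14)
  res <- period_correlations(fr, q_flat, seg, ip, n_perm = 100L, seed = 1L)
  acc_rows <- res[res$analysis == "accuracy_vs_q", ]
  # frozen run: accuracy and Q are constant -> all skipped with notes
  expect_true(all(is.na(acc_rows$r)))
  expect_true(all(nzchar(acc_rows$note)))
  ec_rows <- res[res$analysis == "edge_change_vs_ip", ]
  expect_true(all(is.na(ec_rows$r)))   # frozen weights: constant zero maps
})

test_that("topology-information correlation tables align epochs and statistics", {
  run <- small_run()
  tr <- run$trace
  part <- louvain(symmetrize(assemble_adjacency(tr$weights[[1L]])), seed = 2L)
  profiles <- suppressWarnings(cartography_per_epoch(tr, part))[1:3]
  idm <- matrix(runif(196), 14, 14)
  res <- topology_info_correlations(profiles, idm, n_input = 196L,
                                    n_perm = 100L, seed = 5L)
  expect_equal(nrow(res), 6L)
  expect_setequal(unique(res$statistic), c("pc", "mz"))
  expect_true(all(res$null_lo <= res$null_hi))
})
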