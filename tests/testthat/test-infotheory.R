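test_that("plug-in MI matches the hand-summed table oracle", {
  # perfect half-split of 10 equiprobable classes carries exactly 1 bit
  labels <- rep(0:9, each = 20L)
  x <- labels < 5L
  expect_equal(mutual_information(x, labels), 1, tolerance = 1e-12)

  # arbitrary 2x3 tables against the direct formula
  set.seed(7)
  for (i in 1:30) {
    n <- 60L
    xs <- sample(c(TRUE, FALSE), n, replace = TRUE)
    ls <- sample(0:2, n, replace = TRUE)
    expect_equal(mutual_information(xs, ls),
                 mi_table_oracle(table(xs, ls)), tolerance = 1e-12)
  }
  # independence: MI vanishes up to estimator bias at large n
  set.seed(8)
  xi <- sample(c(TRUE, FALSE), 20000L, replace = TRUE)
  li <- sample(0:4, 20000L, replace = TRUE)
  expect_lt(mutual_information(xi, li), 0.002)
  expect_error(mutual_information(logical(0), integer(0)), "empty")
})

test_that("optimal binarization maximizes MI over the exhaustive midpoint scan", {
  labels <- rep(0:1, each = 50L)
  # a perfect predictor: intensity 200 iff class 0
  x <- ifelse(labels == 0L, 200, 0)
  ob <- optimal_binarize(x, labels)
  expect_equal(ob$mi, 1, tolerance = 1e-12)
  expect_equal(ob$threshold, 100)   # the single midpoint

  # constant pixel: zero information, threshold above the maximum
  obc <- optimal_binarize(rep(42, 100), labels)
  expect_equal(obc$mi, 0)
  expect_false(any(obc$binary))

  # random 3-class, 5-level series: equals a brute-force scan over midpoints
  set.seed(9)
  for (i in 1:20) {
    xs <- sample(c(0, 60, 120, 180, 240), 90L, replace = TRUE)
    ls <- sample(0:2, 90L, replace = TRUE)
    ob <- optimal_binarize(xs, ls)
    u <- sort(unique(xs))
    cuts <- (u[-length(u)] + u[-1L]) / 2
    brute <- vapply(cuts, function(cc) mi_table_oracle(table(xs > cc, ls)), 0)
    expect_equal(ob$mi, max(brute), tolerance = 1e-12)
    expect_equal(ob$threshold, cuts[which(brute >= max(brute) - 1e-15)][1L])
    # never below the median split
    med <- stats::median(xs)
    if (any(xs > med) && any(xs <= med)) {
      expect_gte(ob$mi, mi_table_oracle(table(xs > med, ls)) - 1e-12)
    }
  }
})

test_that("pixel-on partial information follows the pointwise-MI closed forms", {
  # pixel on iff class 0 among 10 equiprobable classes: I_D = log2(10)
  labels <- rep(0:9, each = 10L)
  x <- labels == 0L
  pw <- partial_info_on(x, labels)
  expect_equal(pw$i_d, log2(10), tolerance = 1e-12)
  expect_equal(pw$p_on, 0.1)

  # independent state: I_D = 0 within estimator noise
  set.seed(10)
  xi <- sample(c(TRUE, FALSE), 20000L, replace = TRUE)
  li <- sample(0:4, 20000L, replace = TRUE)
  expect_lt(abs(partial_info_on(xi, li)$i_d), 0.01)

  # never-on pixel: NaN by contract
  expect_true(is.nan(partial_info_on(rep(FALSE, 10), rep(0:1, 5))$i_d))
})

test_that("the information decomposition identity holds on random tables", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(c(40L, 90L, 200L), 1L)
    x <- sample(c(TRUE, FALSE), n, replace = TRUE,
                prob = c(p <- runif(1, 0.05, 0.95), 1 - p))
    l <- sample(seq_len(sample(2:6, 1L)), n, replace = TRUE)
    if (length(unique(x)) < 2L || length(unique(l)) < 2L) next
    ip <- mutual_information(x, l)
    pw <- partial_info_on(x, l)
    expect_lt(abs(ip - (pw$p_on * pw$i_d + (1 - pw$p_on) * pw$i_d_off)), 1e-12)
    # nonnegativity and the entropy bound
    h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
    expect_gte(ip, -1e-12)
    expect_lte(ip, min(h(table(x) / n), h(table(l) / n)) + 1e-12)
  }
})

test_that("pixel info maps recover the generating distribution", {
  spec <- noise_free_spec()
  ds <- make_glyph_dataset(spec, 200L)
  m <- suppressMessages(pixel_info_map(ds))
  stroke <- matrix(FALSE, 6, 6)
  for (msk in spec$stroke_masks) stroke[msk] <- TRUE
  expect_true(all(m$i_p[stroke] > 0))
  expect_true(all(m$i_p[!stroke] == 0))
  # estimator converges to the analytic map under noise at n = 10,000
  spec2 <- glyph_spec(seed = 42L)
  ds2 <- make_glyph_dataset(spec2, 10000L)
  m2 <- suppressMessages(pixel_info_map(ds2))
  gt <- ground_truth_pixel_info(spec2)
  expect_gt(cor(as.vector(m2$i_p), as.vector(gt)), 0.99)
  expect_lt(max(abs(m2$i_p - gt)), 0.05)
  # tidy export covers every pixel once
  tab <- pixel_info_table(m2)
  expect_equal(nrow(tab), 196L)
  expect_equal(tab$i_p[tab$pixel_row == 3 & tab$pixel_col == 7], m2$i_p[3, 7])
})

test_that("hidden-node information behaves at its closed-form anchors", {
  # a node whose activity separates two classes perfectly: 1 bit
  labels <- rep(0:1, each = 30L)
  act <- cbind(ifelse(labels == 0L, 0.9, 0.1), runif(60L, 0.4, 0.6))
  ih <- hidden_node_info(act, labels)
  expect_equal(ih[1L], 1, tolerance = 1e-12)
  expect_lte(max(ih), 1)

  # an untrained random network: small positive layer means, bounded by log2 C
  run <- small_run()
  tr <- run$trace
  ni <- node_info_trajectory(tr)
  expect_true(all(ni$layer_means$mean_i_h >= 0))
  expect_true(all(ni$layer_means$mean_i_h <= log2(tr$n_classes)))
  # training concentrates class information in the deep layer
  hl2 <- ni$layer_means[ni$layer_means$layer == "hl2", ]
  expect_gt(hl2$mean_i_h[nrow(hl2)], hl2$mean_i_h[1L])
})
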