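test_that("glyph generation is deterministic, balanced, and honours masks", {
  spec <- noise_free_spec()
  ds <- make_glyph_dataset(spec, 100L)
  # degenerate noise-free case: images are nonzero exactly on the class mask
  for (i in sample(seq_len(100L), 10L)) {
    img <- ds$images[i, , ]
    expected <- matrix(FALSE, 6, 6)
    mask <- spec$stroke_masks[[ds$labels[i] + 1L]]
    expected[mask] <- TRUE
    expect_identical(unname(img > 0), expected)
  }
  # exact round-robin class balance
  expect_true(all(tabulate(ds$labels + 1L, 2L) == 50L))
  # byte-identical regeneration from the same spec
  expect_identical(ds, make_glyph_dataset(spec, 100L))
  # intensity ranges respected
  expect_true(all(ds$images[ds$images > 0] >= spec$intensity_on[1]))
})

test_that("indistinguishable classes are rejected and invariants enforced", {
  m <- cbind(1L, 1:6)
  spec <- glyph_spec(n_classes = 2L, image_shape = c(6L, 6L),
                     stroke_masks = list(m, m))
  expect_error(make_glyph_dataset(spec, 10L), "indistinguishable")
  expect_error(glyph_spec(p_on_stroke = 0.2, p_on_background = 0.5),
               "p_on_background")
  expect_error(glyph_spec(n_classes = 2L, image_shape = c(4L, 4L),
                          stroke_masks = list(cbind(1L, 1L), cbind(9L, 1L))),
               "within image_shape")
  expect_error(image_dataset(array(0L, c(3, 2, 2)), c(0L, 1L), 2L),
               "item count")
  expect_error(image_dataset(array(0L, c(2, 2, 2)), c(0L, 5L), 2L), "labels")
})

test_that("empirical pixel on-frequencies converge to generating probabilities", {
  spec <- glyph_spec(seed = 99L)
  n <- 10000L
  ds <- make_glyph_dataset(spec, n)
  x_on <- annlens:::flatten_images(ds$images) >= spec$intensity_on[1L]
  w <- spec$image_shape[2L]
  # ~2,000 pixel-by-class comparisons: assert the 3-SE band in aggregate
  # (binomially ~99.7% should fall inside) plus a hard 6-SE cap
  z <- c()
  for (cls in 0:(spec$n_classes - 1L)) {
    idx <- ds$labels == cls
    freq <- colMeans(x_on[idx, , drop = FALSE])
    mask_px <- (spec$stroke_masks[[cls + 1L]][, 1L] - 1L) * w +
      spec$stroke_masks[[cls + 1L]][, 2L]
    p_true <- rep(spec$p_on_background, 196L)
    p_true[mask_px] <- spec$p_on_stroke
    z <- c(z, (freq - p_true) / sqrt(p_true * (1 - p_true) / sum(idx)))
  }
  expect_gte(mean(abs(z) < 3), 0.99)
  expect_lt(max(abs(z)), 6)
})

test_that("analytic pixel information ranks stroke pixels above background", {
  spec <- glyph_spec(seed = 1L)
  gt <- ground_truth_pixel_info(spec)
  w <- spec$image_shape[2L]
  stroke_px <- unique(unlist(lapply(spec$stroke_masks, function(m) {
    (m[, 1L] - 1L) * w + m[, 2L]
  })))
  gt_v <- as.vector(t(gt))
  expect_true(min(gt_v[stroke_px]) > max(gt_v[-stroke_px]))
  # one pixel on iff class 0, two equiprobable classes -> exactly 1 bit,
  # both analytically and via the estimator at n large
  spec2 <- glyph_spec(n_classes = 2L, image_shape = c(2L, 2L),
                      stroke_masks = list(cbind(1L, 1L), cbind(2L, 2L)),
                      p_on_stroke = 1, p_on_background = 0, seed = 3L)
  gt2 <- ground_truth_pixel_info(spec2)
  expect_equal(gt2[1L, 1L], 1, tolerance = 1e-12)
  ds2 <- make_glyph_dataset(spec2, 100L)
  est <- suppressMessages(pixel_info_map(ds2))
  expect_equal(est$i_p[1L, 1L], 1, tolerance = 1e-12)
})

test_that("IDX files round-trip and malformed files raise distinct errors", {
  ds <- make_glyph_dataset(noise_free_spec(0.8, 0.1), 10L)
  fi <- withr::local_tempfile(); fl <- withr::local_tempfile()
  write_idx(ds, fi, fl)
  back <- read_idx(fi, fl)
  expect_identical(ds$images, back$images)
  expect_identical(ds$labels, back$labels)

  # label count mismatch
  short <- image_dataset(ds$images[1:9, , , drop = FALSE], ds$labels[1:9], 2L)
  fl2 <- withr::local_tempfile()
  write_idx(short, withr::local_tempfile(), fl2)
  expect_error(read_idx(fi, fl2), "count mismatch")

  # truncated image payload
  fi3 <- withr::local_tempfile()
  raw_all <- readBin(fi, "raw", file.size(fi))
  writeBin(raw_all[seq_len(length(raw_all) - 5L)], fi3)
  expect_error(read_idx(fi3, fl), "truncated")

  # wrong magic number
  fi4 <- withr::local_tempfile()
  bad <- raw_all; bad[4] <- as.raw(9)
  writeBin(bad, fi4)
  expect_error(read_idx(fi4, fl), "magic")
})

test_that("dataset splitting is stratified, disjoint and seed-stable", {
  spec <- glyph_spec(seed = 2L)
  ds <- make_glyph_dataset(spec, 100L)
  sp <- split_dataset(ds, 0.2, seed = 4L)
  expect_equal(length(sp$train$labels), 80L)
  expect_true(all(tabulate(sp$test$labels + 1L, 5L) == 4L))
  expect_identical(split_dataset(ds, 0.2, seed = 4L), sp)
  # union preserves items
  expect_equal(length(sp$train$labels) + length(sp$test$labels), 100L)
  # 2 items per class at fraction 0.5 -> 1/1
  tiny <- make_glyph_dataset(noise_free_spec(), 4L)
  sp2 <- split_dataset(tiny, 0.5, seed = 1L)
  expect_true(all(tabulate(sp2$test$labels + 1L, 2L) == 1L))
  # a singleton class cannot be split
  one <- image_dataset(array(1L, c(3, 2, 2)), c(0L, 0L, 1L), 2L)
  expect_error(split_dataset(one, 0.5), "at least 2")
})
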