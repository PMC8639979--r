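test_that("PCA matches a brute-force covariance eigendecomposition", {
  set.seed(13)
  X <- matrix(rnorm(40 * 7), 40, 7)
  emb <- fit_pca(X)
  Xs <- scale(X)
  eig <- eigen(cov(Xs), symmetric = TRUE)
  expect_equal(emb$eigenvalues, eig$values[seq_along(emb$eigenvalues)],
               tolerance = 1e-8)
  for (k in seq_len(ncol(emb$vectors))) {
    # eigenvectors agree up to sign
    expect_equal(abs(sum(emb$vectors[, k] * eig$vectors[, k])), 1,
                 tolerance = 1e-8)
    # sign convention: largest-magnitude entry positive
    expect_gt(emb$vectors[which.max(abs(emb$vectors[, k])), k], 0)
  }
  # explained fractions sum to 1; full reconstruction of the scaled data
  expect_equal(sum(emb$explained), 1, tolerance = 1e-9)
  expect_equal(emb$scores %*% t(emb$vectors), unclass(Xs),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("rank structure is reflected in explained-variance fractions", {
  set.seed(14)
  basis <- matrix(rnorm(3 * 9), 3, 9)
  X <- matrix(rnorm(60 * 3), 60, 3) %*% basis
  emb <- fit_pca(X)
  expect_gte(sum(emb$explained[1:3]), 0.9999)
  # isotropic noise spreads variance evenly
  Xn <- matrix(rnorm(4000 * 6), 4000, 6)
  en <- fit_pca(Xn)
  expect_true(all(abs(en$explained - 1 / 6) < 0.05))
  # zero-variance features are dropped with a warning
  Xz <- cbind(X, 0)
  expect_warning(embz <- fit_pca(Xz), "zero-variance")
  expect_equal(length(embz$nodes_used), 9L)
  expect_error(fit_pca(X[1, , drop = FALSE]), "at least 2")
})

test_that("concatenated activity stacks snapshots with aligned metadata", {
  fr <- frozen_run()
  X <- concat_activity(fr)
  n_items <- length(fr$test_labels)
  n_nodes <- sum(c(196L, 20L, 20L, 5L))
  expect_equal(dim(X), c(length(fr$schedule) * n_items, n_nodes))
  expect_equal(attr(X, "epoch_of_row")[seq_len(n_items)],
               rep(fr$schedule[1L], n_items))
  expect_equal(table(attr(X, "node_layer"))[["input"]], 196L)
  # single-epoch trace reduces to that epoch's activity
  one <- fr; one$schedule <- one$schedule[1L]
  one$activities <- one$activities[1L]; one$accuracy <- one$accuracy[1L]
  X1 <- concat_activity(one)
  expect_equal(unclass(X1)[, 197L], unname(fr$activities[[1L]]$hl1_act[, 1L]))
  # three-layer mode drops the output nodes
  X3 <- concat_activity(fr, layers = c("input", "hl1", "hl2"))
  expect_equal(ncol(X3), 236L)
})

test_that("per-epoch explained variance is flat for frozen weights", {
  fr <- frozen_run()
  vd <- vd10_trajectory(fr)
  expect_equal(vd$vd10, rep(vd$vd10[1L], nrow(vd)), tolerance = 1e-10)
  # rank-deficient activity saturates vd10 at 1
  run <- small_run()
  tr <- run$trace
  expect_true(all(vd10_trajectory(tr)$vd10 <= 1 + 1e-12))
})

test_that("category distances follow their geometric definitions", {
  # two point-mass classes at distance d
  d <- 3.7
  sc <- rbind(matrix(0, 10, 3), cbind(rep(d, 10), 0, 0))
  lab <- rep(0:1, each = 10L)
  cd <- category_distances(sc, lab)
  expect_equal(cd$between, d, tolerance = 1e-12)
  expect_equal(cd$within, 0)
  # all items identical: both distances vanish
  cd0 <- category_distances(matrix(1, 20, 3), lab)
  expect_equal(cd0$between, 0)
  expect_equal(cd0$within, 0)
  # orthogonal rotation invariance
  set.seed(15)
  sc2 <- matrix(rnorm(60), 20, 3)
  qr_R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  cd_a <- category_distances(sc2, lab)
  cd_b <- category_distances(sc2 %*% qr_R, lab)
  expect_equal(cd_a$between, cd_b$between, tolerance = 1e-10)
  expect_equal(cd_a$within, cd_b$within, tolerance = 1e-10)
  # shuffling labels on mixed data collapses between-category distance
  set.seed(16)
  sc3 <- rbind(matrix(rnorm(300), 100, 3),
               matrix(rnorm(300, mean = 4), 100, 3))
  lab3 <- rep(0:1, each = 100L)
  shuf <- sample(lab3)
  expect_lt(category_distances(sc3, shuf)$between / 4,
            category_distances(sc3, lab3)$between / 4 * 0.25)
})

test_that("loading comparisons detect planted effects at controlled FDR", {
  set.seed(17)
  scores <- matrix(rnorm(400 * 12), 400, 12)
  emb <- structure(list(scores = scores, vectors = diag(12),
                        eigenvalues = rep(1, 12), explained = rep(1 / 12, 12),
                        nodes_used = 1:12, fit_mode = "concatenated"),
                   class = "activity_embedding")
  correct <- rep(c(TRUE, FALSE), each = 200L)
  # identical groups: no discoveries
  null_res <- loading_comparison(emb, correct)
  expect_true(all(!null_res$significant))
  # planted effect: incorrect items' scores shrunk on component 2
  emb2 <- emb
  emb2$scores[!correct, 2L] <- emb2$scores[!correct, 2L] * 0.5
  res2 <- loading_comparison(emb2, correct)
  expect_true(res2$significant[2L])
  # degenerate input: no incorrect items -> informative no-op
  noop <- loading_comparison(emb, rep(TRUE, 400L))
  expect_equal(nrow(noop), 0L)
  expect_match(attr(noop, "note"), "nothing to compare")
})

test_that("loading-topology correlations recover duplicated signals", {
  run <- small_run()
  tr <- run$trace
  X <- concat_activity(tr)
  emb <- suppressWarnings(fit_pca(X))
  part <- louvain(symmetrize(assemble_adjacency(tr$weights[[1L]])), seed = 2L)
  profiles <- suppressWarnings(cartography_per_epoch(tr, part))[1:2]
  lt <- loading_topology_correlation(emb, profiles, n_input = 196L,
                                     n_perm = 100L, seed = 3L)
  expect_equal(nrow(lt), 4L)
  expect_true(all(abs(lt$r) <= 1))
  # a statistic perfectly duplicating the loadings correlates at r = 1
  fake <- profiles[1L]
  fake[[1L]]$pc <- rep(0, length(fake[[1L]]$pc))
  fake[[1L]]$pc[emb$nodes_used[emb$nodes_used <= 196L]] <-
    emb$vectors[emb$nodes_used <= 196L, 1L]
  ltf <- suppressMessages(
    loading_topology_correlation(emb, fake, n_input = 196L, n_perm = 100L,
                                 seed = 4L))
  expect_equal(ltf$r[ltf$statistic == "pc"], 1, tolerance = 1e-12)
})

test_that("single-layer PCA tracks layer-specific structure", {
  fr <- frozen_run()
  p1 <- per_layer_pca(fr, "hl1")
  expect_equal(nrow(p1$vd10), length(fr$schedule))
  # duplicated layers give identical trajectories
  dup <- fr
  for (k in seq_along(dup$activities)) {
    dup$activities[[k]]$hl2_act <- dup$activities[[k]]$hl1_act
  }
  expect_equal(per_layer_pca(dup, "hl2")$vd10$vd10, p1$vd10$vd10,
               tolerance = 1e-10)
  # rank-1 activity loads everything on the first component
  r1 <- fr
  for (k in seq_along(r1$activities)) {
    base <- r1$activities[[k]]$hl1_act[, 1L]
    r1$activities[[k]]$hl1_act <- outer(base, seq(0.5, 1.5, length.out = 20L))
  }
  e1 <- suppressWarnings(per_layer_pca(r1, "hl1"))
  expect_gte(e1$embeddings[[1L]]$explained[1L], 0.9999)
})
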