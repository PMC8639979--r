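# PCA of node activities: concatenated multi-epoch embeddings, per-epoch
# explained-variance trajectories, eigenvector loadings, category untangling
# distances, and loading-based comparisons.

#' PCA of an activity matrix
#'
#' Features (nodes) are z-scored; zero-variance features are dropped with a
#' warning. The eigendecomposition of the feature covariance is computed via
#' SVD, with each eigenvector's sign fixed so its largest-magnitude entry is
#' positive, making results deterministic.
#'
#' @param X items x nodes activity matrix.
#' @param fit_mode label recorded on the result ("concatenated" or
#'   "per_epoch").
#' @return object of class `activity_embedding`: `eigenvalues` (descending),
#'   `vectors` (kept-nodes x components loadings), `explained` (fractions
#'   summing to 1), `scores` (items x components), `vd10` (cumulative top-10
#'   explained fraction), `nodes_used` (indices of kept features),
#'   `center`, `scale`, `fit_mode`.
#' @export
fit_pca <- function(X, fit_mode = "concatenated") {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 items for PCA")
  sds <- apply(X, 2L, stats::sd)
  keep <- which(sds > 0)
  if (length(keep) < ncol(X)) {
    warning(ncol(X) - length(keep), " zero-variance feature(s) dropped")
  }
  if (length(keep) == 0L) stop("all features have zero variance")
  mu <- colMeans(X[, keep, drop = FALSE])
  Xs <- scale(X[, keep, drop = FALSE], center = mu, scale = sds[keep])
  pr <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  eigenvalues <- pr$sdev^2
  vectors <- pr$rotation
  scores <- pr$x
  for (k in seq_len(ncol(vectors))) {
    j <- which.max(abs(vectors[, k]))
    if (vectors[j, k] < 0) {
      vectors[, k] <- -vectors[, k]
      scores[, k] <- -scores[, k]
    }
  }
  explained <- eigenvalues / sum(eigenvalues)
  structure(list(
    eigenvalues = eigenvalues, vectors = vectors, explained = explained,
    scores = scores, vd10 = sum(explained[seq_len(min(10L, length(explained)))]),
    nodes_used = keep, center = mu, scale = sds[keep], fit_mode = fit_mode
  ), class = "activity_embedding")
}

#' @export
print.activity_embedding <- function(x, ...) {
  cat(sprintf("<activity_embedding (%s): %d comps over %d nodes, vd10 = %.3f>\n",
              x$fit_mode, length(x$eigenvalues), length(x$nodes_used), x$vd10))
  invisible(x)
}

#' Concatenate test-set activity across scheduled epochs
#'
#' Stacks each scheduled epoch's test-set activations (chosen layers,
#' column-bound in node order) into one multi-epoch matrix. Attributes record
#' the epoch, item index and class label of every row, and the layer of every
#' column.
#'
#' @param trace a `training_trace`.
#' @param layers subset of c("input", "hl1", "hl2", "out"); the default uses
#'   all four layers (994 nodes for the 28x28/100/100/10 architecture); use
#'   c("input", "hl1", "hl2") to restrict to the first three.
#' @return matrix with attributes `epoch_of_row`, `label_of_row`,
#'   `node_layer`.
#' @export
concat_activity <- function(trace, layers = c("input", "hl1", "hl2", "out")) {
  stopifnot(inherits(trace, "training_trace"), length(trace$activities) >= 1L)
  layers <- match.arg(layers, c("input", "hl1", "hl2", "out"), several.ok = TRUE)
  pick <- function(act) {
    do.call(cbind, lapply(layers, function(l) act[[paste0(l, "_act")]]))
  }
  sizes <- vapply(trace$activities, function(a) nrow(a$input_act), 0L)
  if (length(unique(sizes)) != 1L) stop("inconsistent test-set size across epochs")
  X <- do.call(rbind, lapply(trace$activities, pick))
  n_item <- sizes[1L]
  attr(X, "epoch_of_row") <- rep(trace$schedule, each = n_item)
  attr(X, "label_of_row") <- rep(trace$test_labels, times = length(trace$schedule))
  layer_cols <- unlist(lapply(layers, function(l) {
    rep(l, ncol(trace$activities[[1L]][[paste0(l, "_act")]]))
  }))
  attr(X, "node_layer") <- layer_cols
  X
}

#' Per-epoch cumulative top-10 explained variance
#'
#' Fits a separate PCA on each scheduled epoch's activity and returns the
#' cumulative explained fraction of the top 10 components.
#'
#' @inheritParams concat_activity
#' @return data.frame(epoch, vd10).
#' @export
vd10_trajectory <- function(trace, layers = c("input", "hl1", "hl2", "out")) {
  stopifnot(inherits(trace, "training_trace"))
  layers <- match.arg(layers, c("input", "hl1", "hl2", "out"), several.ok = TRUE)
  vd <- vapply(trace$activities, function(act) {
    X <- do.call(cbind, lapply(layers, function(l) act[[paste0(l, "_act")]]))
    suppressWarnings(fit_pca(X, "per_epoch")$vd10)
  }, 0)
  data.frame(epoch = trace$schedule, vd10 = vd)
}

#' Between- and within-category distances in a top-3 embedding
#'
#' Between: mean Euclidean distance over unordered pairs of class centroids.
#' Within: mean Euclidean distance of items to their own class centroid.
#'
#' @param scores3 items x 3 (or more; first 3 used) embedding coordinates.
#' @param labels per-item class labels.
#' @return list(between, within).
#' @export
category_distances <- function(scores3, labels) {
  scores3 <- as.matrix(scores3)[, seq_len(min(3L, ncol(as.matrix(scores3)))), drop = FALSE]
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2L) stop("need at least 2 classes")
  if (any(tabulate(labels) == 0L)) stop("class with no items")
  cent <- rowsum(scores3, labels) / as.vector(table(labels))
  between <- mean(stats::dist(cent))
  within <- mean(sqrt(rowSums((scores3 - cent[labels, , drop = FALSE])^2)))
  list(between = between, within = within)
}

#' Category untangling trajectory in the concatenated embedding
#'
#' Projects each scheduled epoch's test-set activity into the top-3 space of
#' the concatenated embedding (same standardization) and computes the
#' between- and within-category distances per epoch.
#'
#' @param trace a `training_trace`.
#' @param embedding an `activity_embedding` fitted on [concat_activity()] of
#'   the same trace/layers; if NULL it is fitted here.
#' @param layers layers used for the embedding.
#' @return data.frame(epoch, between, within, accuracy).
#' @export
untangling_trajectory <- function(trace, embedding = NULL,
                                  layers = c("input", "hl1", "hl2", "out")) {
  X <- concat_activity(trace, layers)
  if (is.null(embedding)) embedding <- suppressWarnings(fit_pca(X, "concatenated"))
  ep_of_row <- attr(X, "epoch_of_row")
  lab_of_row <- attr(X, "label_of_row")
  Xs <- scale(X[, embedding$nodes_used, drop = FALSE],
              center = embedding$center, scale = embedding$scale)
  sc3 <- Xs %*% embedding$vectors[, seq_len(min(3L, ncol(embedding$vectors))), drop = FALSE]
  out <- do.call(rbind, lapply(seq_along(trace$schedule), function(k) {
    rows <- ep_of_row == trace$schedule[k]
    d <- category_distances(sc3[rows, , drop = FALSE], lab_of_row[rows])
    data.frame(epoch = trace$schedule[k], between = d$between, within = d$within,
               accuracy = trace$accuracy[k])
  }))
  out
}

#' Compare component loadings between correct and incorrect items
#'
#' For each of the leading components, the absolute item scores of correctly
#' and incorrectly classified items are compared with a rank-based two-sample
#' (Wilcoxon) test; p-values are Benjamini-Hochberg adjusted across the
#' components.
#'
#' @param embedding an `activity_embedding` (scores rows = items).
#' @param correct_mask logical per item, TRUE if classified correctly.
#' @param n_comp number of leading components to test (default 10).
#' @return data.frame(component, median_abs_correct, median_abs_incorrect,
#'   p, p_adj, significant); if one group is empty, a zero-row data.frame with
#'   attribute `note`.
#' @export
loading_comparison <- function(embedding, correct_mask, n_comp = 10L) {
  stopifnot(inherits(embedding, "activity_embedding"),
            nrow(embedding$scores) == length(correct_mask))
  n_comp <- min(n_comp, ncol(embedding$scores))
  if (all(correct_mask) || !any(correct_mask)) {
    out <- data.frame(component = integer(0), median_abs_correct = numeric(0),
                      median_abs_incorrect = numeric(0), p = numeric(0),
                      p_adj = numeric(0), significant = logical(0))
    attr(out, "note") <- "both correct and incorrect items required; nothing to compare"
    return(out)
  }
  res <- do.call(rbind, lapply(seq_len(n_comp), function(k) {
    a <- abs(embedding$scores[correct_mask, k])
    b <- abs(embedding$scores[!correct_mask, k])
    data.frame(component = k, median_abs_correct = stats::median(a),
               median_abs_incorrect = stats::median(b),
               p = suppressWarnings(stats::wilcox.test(a, b)$p.value))
  }))
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p_adj < 0.05
  res
}

#' Correlate input-layer loadings with per-epoch topology
#'
#' Pearson correlation (with permutation p-values) between the input-layer
#' entries of a leading eigenvector of the concatenated embedding and each
#' epoch's input-layer participation coefficient and module-degree z-score.
#'
#' @param embedding concatenated `activity_embedding` fitted on all layers.
#' @param profiles result of [cartography_per_epoch()].
#' @param n_input number of input-layer nodes.
#' @param component which eigenvector to use (default 1).
#' @param n_perm permutations per correlation.
#' @param seed master seed.
#' @return data.frame(epoch, statistic, r, p_perm).
#' @export
loading_topology_correlation <- function(embedding, profiles, n_input,
                                         component = 1L, n_perm = 1000L,
                                         seed = 1L) {
  idx_in_kept <- which(embedding$nodes_used <= n_input)
  load_in <- numeric(n_input)               # dropped features carry 0 loading
  load_in[embedding$nodes_used[idx_in_kept]] <-
    embedding$vectors[idx_in_kept, component]
  do.call(rbind, lapply(seq_along(profiles), function(k) {
    p <- profiles[[k]]
    do.call(rbind, lapply(c("pc", "mz"), function(st) {
      v <- p[[st]][seq_len(n_input)]
      pr <- perm_corr(load_in, v, n_perm = n_perm,
                      seed = sub_seed(seed, k * 10L + (st == "mz")))
      data.frame(epoch = as.integer(names(profiles)[k]), statistic = st,
                 r = pr$r_obs, p_perm = pr$p_perm)
    }))
  }))
}

#' Per-epoch PCA restricted to one hidden layer
#'
#' @param trace a `training_trace`.
#' @param layer "hl1" or "hl2".
#' @return list(embeddings = per-epoch `activity_embedding`,
#'   vd10 = data.frame(epoch, vd10)).
#' @export
per_layer_pca <- function(trace, layer = c("hl1", "hl2")) {
  layer <- match.arg(layer)
  embs <- lapply(trace$activities, function(act) {
    suppressWarnings(fit_pca(act[[paste0(layer, "_act")]], "per_epoch"))
  })
  list(embeddings = embs,
       vd10 = data.frame(epoch = trace$schedule,
                         vd10 = vapply(embs, function(e) e$vd10, 0)))
}
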