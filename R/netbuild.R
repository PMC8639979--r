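# Embedding a snapshot's three weight blocks in a node x node signed
# adjacency matrix, and summarising input->HL1 edge change over training.

#' Assemble the layered signed adjacency matrix
#'
#' The three signed weight blocks are placed in the upper triangle of an
#' N x N matrix (N = n_in + n_hl1 + n_hl2 + n_out; 994 for the 28x28 / 100 /
#' 100 / 10 architecture), with nodes ordered input (row-major pixel order),
#' HL1, HL2, output. The lower triangle is identically zero; the matrix is
#' kept asymmetric and un-thresholded here, and symmetrized only where graph
#' analyses require it (see [symmetrize()]).
#'
#' @param params a `layered_net`.
#' @return object of class `layered_adjacency`: `W` (N x N), `node_layer`
#'   (factor input/hl1/hl2/output per node), `layer_sizes`.
#' @export
assemble_adjacency <- function(params) {
  stopifnot(inherits(params, "layered_net"))
  ls <- params$layer_sizes
  n <- sum(ls)
  W <- matrix(0, n, n)
  o1 <- ls[1L]; o2 <- ls[1L] + ls[2L]; o3 <- ls[1L] + ls[2L] + ls[3L]
  W[seq_len(ls[1L]), (o1 + 1L):o2] <- params$alpha
  W[(o1 + 1L):o2, (o2 + 1L):o3] <- params$beta
  W[(o2 + 1L):o3, (o3 + 1L):n] <- params$gamma_w
  node_layer <- factor(rep(c("input", "hl1", "hl2", "output"), times = ls),
                       levels = c("input", "hl1", "hl2", "output"))
  structure(list(W = W, node_layer = node_layer, layer_sizes = ls),
            class = "layered_adjacency")
}

#' @export
print.layered_adjacency <- function(x, ...) {
  cat(sprintf("<layered_adjacency: %d nodes (%s)>\n", nrow(x$W),
              paste(x$layer_sizes, collapse = "+")))
  invisible(x)
}

#' Symmetrize a layered adjacency for undirected graph analyses
#'
#' Since only the upper triangle is populated, `W + t(W)` reproduces every
#' weight exactly once in each triangle and loses no information.
#'
#' @param adj a `layered_adjacency` or a square matrix.
#' @return symmetric numeric matrix.
#' @export
symmetrize <- function(adj) {
  W <- if (inherits(adj, "layered_adjacency")) adj$W else as.matrix(adj)
  W + t(W)
}

#' Recover the three weight blocks from a layered adjacency
#' @param adj a `layered_adjacency`.
#' @return list(alpha, beta, gamma_w).
#' @export
adjacency_blocks <- function(adj) {
  stopifnot(inherits(adj, "layered_adjacency"))
  ls <- adj$layer_sizes
  o1 <- ls[1L]; o2 <- o1 + ls[2L]; o3 <- o2 + ls[3L]; n <- o3 + ls[4L]
  list(alpha = adj$W[seq_len(o1), (o1 + 1L):o2, drop = FALSE],
       beta = adj$W[(o1 + 1L):o2, (o2 + 1L):o3, drop = FALSE],
       gamma_w = adj$W[(o2 + 1L):o3, (o3 + 1L):n, drop = FALSE])
}

#' Per-pixel map of input-edge change across training
#'
#' For each consecutive pair of scheduled snapshots inside `epoch_range`, the
#' absolute change of every alpha (input -> HL1) weight is computed. Each input
#' node then receives either the grand mean (`"mean_abs"`) or the standard
#' deviation (`"sd"`) of the per-pair per-edge absolute changes across its
#' outgoing alpha edges, and the vector is reshaped to the image grid.
#'
#' @param trace a `training_trace`.
#' @param epoch_range length-2 numeric range of epochs (inclusive); must
#'   contain at least two scheduled snapshots.
#' @param statistic `"mean_abs"` (default) or `"sd"`.
#' @return height x width matrix with attributes `statistic` and `epochs`.
#' @export
edge_change_map <- function(trace, epoch_range = range(trace$schedule),
                            statistic = c("mean_abs", "sd")) {
  stopifnot(inherits(trace, "training_trace"))
  statistic <- match.arg(statistic)
  sel <- which(trace$schedule >= epoch_range[1L] & trace$schedule <= epoch_range[2L])
  if (length(sel) < 2L) stop("epoch_range must contain at least 2 scheduled snapshots")
  n_in <- nrow(trace$weights[[sel[1L]]]$alpha)
  # per input node, pool |delta alpha| over pairs and over its outgoing edges
  deltas <- lapply(seq_len(length(sel) - 1L), function(k) {
    abs(trace$weights[[sel[k + 1L]]]$alpha - trace$weights[[sel[k]]]$alpha)
  })
  pooled <- do.call(cbind, deltas)           # n_in x (n_pairs * n_hl1)
  v <- if (statistic == "mean_abs") rowMeans(pooled) else apply(pooled, 1L, stats::sd)
  out <- pixel_grid(v, trace$image_shape)
  attr(out, "statistic") <- statistic
  attr(out, "epochs") <- trace$schedule[sel]
  out
}

#' Export an adjacency as a weighted edge list
#'
#' @param adj a `layered_adjacency`.
#' @param zero_based use 0-based node ids (default TRUE, the interchange
#'   convention); R-side structures are 1-based.
#' @return data.frame(i, j, w) of nonzero edges.
#' @export
adjacency_edge_list <- function(adj, zero_based = TRUE) {
  W <- if (inherits(adj, "layered_adjacency")) adj$W else as.matrix(adj)
  nz <- which(W != 0, arr.ind = TRUE)
  off <- if (zero_based) 1L else 0L
  data.frame(i = nz[, 1L] - off, j = nz[, 2L] - off, w = W[nz])
}
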