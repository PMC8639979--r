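# Cartographic node profiling against a module partition: module-degree
# z-score MZ = (k_i - mean_k_module) / sd_k_module (within-module strength,
# z-scored against the node's module with the population SD) and the
# participation coefficient PC = 1 - sum_s (k_is / k_i)^2 computed on the
# positive part of the weights (negative connections are removed first, the
# standard convention for signed brain networks).

#' Module-degree z-score per node
#'
#' Within-module strength of each node, z-scored within its module using the
#' population standard deviation. By default strengths use the positive part
#' of `W` (matching the participation coefficient's sign policy); set
#' `use_signed = TRUE` to use raw signed strengths. Modules of size 1, or with
#' zero strength spread, are degenerate and their nodes get MZ = 0 (with a
#' warning).
#'
#' @param W symmetric weight matrix.
#' @param partition a `partition` or an integer assignment vector.
#' @param use_signed use signed rather than positive-part strengths.
#' @return numeric MZ per node.
#' @export
module_degree_zscore <- function(W, partition, use_signed = FALSE) {
  a <- if (inherits(partition, "partition")) partition$assignments else as.integer(partition)
  W <- as.matrix(W)
  stopifnot(length(a) == nrow(W))
  Wu <- if (use_signed) W else pmax(W, 0)
  diag(Wu) <- 0
  same <- outer(a, a, "==")
  kappa_within <- rowSums(Wu * same)
  mz <- numeric(length(a))
  degenerate <- FALSE
  for (m in unique(a)) {
    idx <- which(a == m)
    k <- kappa_within[idx]
    sd_pop <- sqrt(mean((k - mean(k))^2))
    if (length(idx) < 2L || sd_pop == 0) {
      mz[idx] <- 0
      degenerate <- TRUE
    } else {
      mz[idx] <- (k - mean(k)) / sd_pop
    }
  }
  if (degenerate) warning("degenerate module(s): MZ set to 0 for their nodes")
  mz
}

#' Participation coefficient per node
#'
#' Computed on the positive part of `W` only. A node whose positive strength
#' is entirely within its own module scores 0; a node spreading its strength
#' evenly over M modules scores 1 - 1/M. Nodes with zero positive strength
#' get PC = 0 by convention.
#'
#' @inheritParams module_degree_zscore
#' @return numeric PC per node, in [0, 1).
#' @export
participation_coefficient <- function(W, partition) {
  a <- if (inherits(partition, "partition")) partition$assignments else as.integer(partition)
  W <- as.matrix(W)
  stopifnot(length(a) == nrow(W))
  Wp <- pmax(W, 0)
  diag(Wp) <- 0
  k_to_mod <- t(rowsum(t(Wp), a, reorder = TRUE))   # node x module positive strength
  k_tot <- rowSums(k_to_mod)
  pc <- ifelse(k_tot > 0, 1 - rowSums((k_to_mod / pmax(k_tot, .Machine$double.xmin))^2), 0)
  pmax(pc, 0)
}

#' Full cartographic profile of a graph under a partition
#'
#' @inheritParams module_degree_zscore
#' @return object of class `cartography_profile` with `mz`, `pc`,
#'   `kappa_within` (positive within-module strength), `kappa_to_module`
#'   (node x module), `kappa_total`, `partition_used`.
#' @export
cartography <- function(W, partition, use_signed = FALSE) {
  a <- if (inherits(partition, "partition")) partition$assignments else as.integer(partition)
  W <- as.matrix(W)
  Wp <- pmax(W, 0); diag(Wp) <- 0
  same <- outer(a, a, "==")
  k_to_mod <- t(rowsum(t(Wp), a, reorder = TRUE))
  structure(list(
    mz = suppressWarnings(module_degree_zscore(W, a, use_signed = use_signed)),
    pc = participation_coefficient(W, a),
    kappa_within = rowSums(Wp * same),
    kappa_to_module = k_to_mod,
    kappa_total = rowSums(k_to_mod),
    partition_used = a
  ), class = "cartography_profile")
}

#' Cartography at every scheduled epoch of a trace
#'
#' Builds each snapshot's symmetrized adjacency and profiles it either against
#' a per-epoch partition (list, one per snapshot) or a single consensus
#' partition applied to all epochs.
#'
#' @param trace a `training_trace`.
#' @param partitions a single `partition` (consensus mode) or a list with one
#'   partition per scheduled epoch.
#' @param use_signed passed to [module_degree_zscore()].
#' @return list of `cartography_profile`, one per scheduled epoch, with the
#'   trace schedule as names.
#' @export
cartography_per_epoch <- function(trace, partitions, use_signed = FALSE) {
  stopifnot(inherits(trace, "training_trace"))
  n_ep <- length(trace$schedule)
  plist <- if (inherits(partitions, "partition")) {
    rep(list(partitions), n_ep)
  } else partitions
  if (length(plist) != n_ep) {
    stop("need one partition per scheduled epoch (or a single consensus partition)")
  }
  out <- lapply(seq_len(n_ep), function(k) {
    W <- symmetrize(assemble_adjacency(trace$weights[[k]]))
    cartography(W, plist[[k]], use_signed = use_signed)
  })
  names(out) <- trace$schedule
  out
}

#' Input-layer slice of a per-node statistic as an image grid
#'
#' @param values per-node vector over the full layered node set.
#' @param layer_sizes c(n_in, n_hl1, n_hl2, n_out).
#' @param image_shape c(height, width) with prod equal to n_in.
#' @return height x width matrix.
#' @export
input_layer_grid <- function(values, layer_sizes, image_shape) {
  stopifnot(length(values) == sum(layer_sizes),
            prod(image_shape) == layer_sizes[1L])
  pixel_grid(values[seq_len(layer_sizes[1L])], image_shape)
}

#' Tidy per-epoch cartography table
#'
#' @param profiles result of [cartography_per_epoch()].
#' @param node_layer factor of per-node layer labels.
#' @return data.frame(epoch, node_id, layer, module_id, pc, mz).
#' @export
cartography_table <- function(profiles, node_layer) {
  do.call(rbind, lapply(names(profiles), function(ep) {
    p <- profiles[[ep]]
    data.frame(epoch = as.integer(ep), node_id = seq_along(p$pc),
               layer = as.character(node_layer), module_id = p$partition_used,
               pc = p$pc, mz = p$mz)
  }))
}
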