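# Discrete information measures over pixels and hidden nodes:
#   I_P  = MI(binarized pixel; class), with the per-pixel binarization
#          threshold chosen to maximize it;
#   I_D  = mean pointwise MI log2 p(class|pixel-on) / p(class) over the items
#          where the pixel is on (with a companion I_D_off over off items);
#   I_H  = MI(hidden node binarized at activity 0.5; class).
# All estimates are plug-in (maximum likelihood) from the observed
# contingency tables, in bits, with 0 log 0 = 0 and no bias correction.

xlogx2 <- function(p) ifelse(p > 0, p * log2(p), 0)

#' Plug-in mutual information between a discrete series and class labels
#'
#' @param x discrete series (logical, integer or factor).
#' @param labels class labels, same length.
#' @return MI in bits.
#' @export
mutual_information <- function(x, labels) {
  if (length(x) == 0L) stop("empty input")
  stopifnot(length(x) == length(labels))
  tab <- table(x, labels)
  p <- tab / sum(tab)
  pr <- rowSums(p); pc <- colSums(p)
  sum(xlogx2(p)) - sum(xlogx2(pr)) - sum(xlogx2(pc))
}

#' MI-maximizing binarization of a pixel's intensity series
#'
#' Scans every candidate threshold (the midpoints between consecutive sorted
#' unique intensities) and returns the cut maximizing the plug-in MI between
#' the indicator `intensity > threshold` and the class label; ties are broken
#' by the lowest threshold. A constant pixel has no candidate cut: its
#' threshold is placed above the maximum (all items off) and MI is 0.
#'
#' @param x numeric intensity series.
#' @param labels class labels.
#' @return list(threshold, binary (logical), mi).
#' @export
optimal_binarize <- function(x, labels) {
  stopifnot(length(x) == length(labels))
  u <- sort(unique(x))
  if (length(u) == 1L) {
    return(list(threshold = u + 1, binary = rep(FALSE, length(x)), mi = 0))
  }
  cuts <- (u[-length(u)] + u[-1L]) / 2
  n <- length(x)
  counts <- unclass(table(factor(x, levels = u), labels))  # levels x classes
  class_tot <- colSums(counts)
  # items "on" at cut k are those with intensity > cuts[k], i.e. levels k+1..K
  cum_lower <- apply(counts, 2L, cumsum)                   # counts at levels <= k
  on_counts <- sweep(-cum_lower[-nrow(counts), , drop = FALSE], 2L, class_tot, `+`)
  mis <- vapply(seq_along(cuts), function(k) {
    on <- on_counts[k, ]
    tab <- rbind(on, class_tot - on) / n
    pr <- rowSums(tab); pc <- colSums(tab)
    sum(xlogx2(tab)) - sum(xlogx2(pr)) - sum(xlogx2(pc))
  }, 0)
  best <- which(mis >= max(mis) - 1e-15)[1L]               # lowest threshold on ties
  list(threshold = cuts[best], binary = x > cuts[best], mi = mis[best])
}

#' Pixel-on (and pixel-off) partial information
#'
#' The mean pointwise mutual information log2 p(class_item | state) /
#' p(class_item), averaged over the items in each pixel state; probabilities
#' are plug-in from the same series. `i_d` averages over on-items (NaN if the
#' pixel is never on), `i_d_off` over off-items.
#'
#' @param binary logical pixel-state series.
#' @param labels class labels.
#' @return list(i_d, i_d_off, p_on).
#' @export
partial_info_on <- function(binary, labels) {
  stopifnot(length(binary) == length(labels))
  n <- length(binary)
  p_on <- mean(binary)
  labels <- as.integer(factor(labels))
  p_class <- tabulate(labels) / n
  pointwise_mean <- function(state) {
    idx <- which(binary == state)
    if (length(idx) == 0L) return(NaN)
    p_class_given <- tabulate(labels[idx], nbins = length(p_class)) / length(idx)
    mean(log2(p_class_given[labels[idx]] / p_class[labels[idx]]))
  }
  list(i_d = pointwise_mean(TRUE), i_d_off = pointwise_mean(FALSE), p_on = p_on)
}

#' Per-pixel information map of an image dataset
#'
#' Applies [optimal_binarize()], [mutual_information()] and
#' [partial_info_on()] to every pixel and reshapes the results to the image
#' grid. The decomposition I_P = p_on * I_D + (1 - p_on) * I_D_off holds
#' exactly wherever both partial terms are defined.
#'
#' @param dataset an `image_dataset`.
#' @return object of class `pixel_info_map`: matrices `threshold`, `i_p`,
#'   `i_d`, `i_d_off`, `p_on` (height x width), and `image_shape`.
#' @export
pixel_info_map <- function(dataset) {
  stopifnot(inherits(dataset, "image_dataset"), length(dataset$labels) > 0L)
  x <- flatten_images(dataset$images)
  npx <- ncol(x)
  thr <- ip <- id <- idoff <- pon <- numeric(npx)
  for (px in seq_len(npx)) {
    ob <- optimal_binarize(x[, px], dataset$labels)
    pw <- partial_info_on(ob$binary, dataset$labels)
    thr[px] <- ob$threshold; ip[px] <- ob$mi
    id[px] <- pw$i_d; idoff[px] <- pw$i_d_off; pon[px] <- pw$p_on
  }
  if (anyNA(id)) {
    message(sum(is.na(id)), " pixel(s) never active: I_D left NaN there")
  }
  sh <- dataset$image_shape
  structure(list(threshold = pixel_grid(thr, sh), i_p = pixel_grid(ip, sh),
                 i_d = pixel_grid(id, sh), i_d_off = pixel_grid(idoff, sh),
                 p_on = pixel_grid(pon, sh), image_shape = sh),
            class = "pixel_info_map")
}

#' @export
print.pixel_info_map <- function(x, ...) {
  cat(sprintf("<pixel_info_map: %dx%d, I_P in [%.3f, %.3f] bits>\n",
              x$image_shape[1L], x$image_shape[2L], min(x$i_p), max(x$i_p)))
  invisible(x)
}

#' Tidy export of a pixel info map
#' @param map a `pixel_info_map`.
#' @return data.frame(pixel_row, pixel_col, threshold, p_on, i_p, i_d, i_d_off).
#' @export
pixel_info_table <- function(map) {
  sh <- map$image_shape
  g <- expand.grid(pixel_col = seq_len(sh[2L]), pixel_row = seq_len(sh[1L]))
  data.frame(pixel_row = g$pixel_row, pixel_col = g$pixel_col,
             threshold = t(map$threshold)[cbind(g$pixel_col, g$pixel_row)],
             p_on = t(map$p_on)[cbind(g$pixel_col, g$pixel_row)],
             i_p = t(map$i_p)[cbind(g$pixel_col, g$pixel_row)],
             i_d = t(map$i_d)[cbind(g$pixel_col, g$pixel_row)],
             i_d_off = t(map$i_d_off)[cbind(g$pixel_col, g$pixel_row)])
}

#' Hidden-node information for one activity snapshot
#'
#' Each node's activity is binarized at 0.5 and its plug-in MI with the class
#' label computed.
#'
#' @param activity items x nodes matrix of activations in (0, 1).
#' @param labels per-item class labels.
#' @return numeric MI in bits per node.
#' @export
hidden_node_info <- function(activity, labels) {
  activity <- as.matrix(activity)
  stopifnot(nrow(activity) == length(labels))
  apply(activity > 0.5, 2L, mutual_information, labels = labels)
}

#' Hidden-node information trajectories over a training trace
#'
#' @param trace a `training_trace`.
#' @return list with `per_node` (list per epoch of list(hl1, hl2) MI vectors)
#'   and `layer_means` data.frame(epoch, layer, mean_i_h).
#' @export
node_info_trajectory <- function(trace) {
  stopifnot(inherits(trace, "training_trace"))
  per_node <- lapply(seq_along(trace$schedule), function(k) {
    act <- trace$activities[[k]]
    list(hl1 = hidden_node_info(act$hl1_act, trace$test_labels),
         hl2 = hidden_node_info(act$hl2_act, trace$test_labels))
  })
  names(per_node) <- trace$schedule
  layer_means <- do.call(rbind, lapply(seq_along(per_node), function(k) {
    data.frame(epoch = trace$schedule[k], layer = c("hl1", "hl2"),
               mean_i_h = c(mean(per_node[[k]]$hl1), mean(per_node[[k]]$hl2)))
  }))
  list(per_node = per_node, layer_means = layer_means)
}
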