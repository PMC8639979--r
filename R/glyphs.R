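# Synthetic glyph datasets with known class-discriminative pixel structure,
# plus IDX-format (MNIST dialect) readers and writers so real handwritten
# digit/letter datasets can be substituted anywhere a glyph set is used.

#' Specify a synthetic glyph-generating process
#'
#' A glyph dataset emulates the statistical skeleton of handwritten-digit
#' images: each class has a fixed set of "stroke" pixels that fire with high
#' probability when an item of that class is drawn, every other pixel fires
#' at a low background rate, and active/inactive pixels draw their grayscale
#' intensity from disjoint high/low ranges. Because the generating
#' probabilities are known, per-pixel class information has a closed form
#' (see [ground_truth_pixel_info()]), which makes a glyph task a
#' parameter-recovery instrument for the whole analysis pipeline.
#'
#' @param n_classes number of glyph classes.
#' @param image_shape integer c(height, width).
#' @param stroke_masks list (length `n_classes`) of two-column matrices of
#'   (row, col) pixel coordinates; defaults to [default_stroke_masks()].
#' @param p_on_stroke probability a stroke pixel is active for its own class.
#'   The default 0.70 emulates handwriting-like stroke variability: the task
#'   is learnable to ~0.95 test accuracy but keeps a sustained error signal.
#' @param p_on_background activation probability for all other pixels
#'   (default 0.20, background clutter).
#' @param intensity_on,intensity_off inclusive integer intensity ranges for
#'   active and inactive pixels. The defaults ([160, 255] and [0, 40]) keep
#'   the optimal binarization threshold recoverable but not degenerate.
#' @param seed integer seed; generation is fully reproducible from it.
#' @return An object of class `glyph_spec`.
#' @export
glyph_spec <- function(n_classes = 5L,
                       image_shape = c(14L, 14L),
                       stroke_masks = default_stroke_masks(n_classes, image_shape),
                       p_on_stroke = 0.70,
                       p_on_background = 0.20,
                       intensity_on = c(160L, 255L),
                       intensity_off = c(0L, 40L),
                       seed = 1L) {
  n_classes <- as.integer(n_classes)
  image_shape <- as.integer(image_shape)
  stopifnot(n_classes >= 2L, length(image_shape) == 2L, all(image_shape >= 1L))
  if (!(p_on_background >= 0 && p_on_background <= p_on_stroke && p_on_stroke <= 1)) {
    stop("need 0 <= p_on_background <= p_on_stroke <= 1")
  }
  if (length(stroke_masks) != n_classes) {
    stop("stroke_masks must have one entry per class")
  }
  for (m in stroke_masks) {
    m <- as.matrix(m)
    if (ncol(m) != 2L || any(m < 1L) || any(m[, 1L] > image_shape[1L]) ||
        any(m[, 2L] > image_shape[2L])) {
      stop("stroke mask coordinates must lie within image_shape")
    }
  }
  structure(list(
    n_classes = n_classes, image_shape = image_shape,
    stroke_masks = lapply(stroke_masks, function(m) {
      m <- as.matrix(m); storage.mode(m) <- "integer"
      colnames(m) <- c("row", "col"); m
    }),
    p_on_stroke = p_on_stroke, p_on_background = p_on_background,
    intensity_on = as.integer(intensity_on), intensity_off = as.integer(intensity_off),
    seed = as.integer(seed)
  ), class = "glyph_spec")
}

#' Default stroke masks: distinct line strokes per class
#'
#' Class strokes are straight lines through the grid (horizontal and vertical
#' midlines, the two diagonals, and horizontal/vertical lines at the third
#' positions), echoing how class-discriminative pixels in handwritten digits
#' lie along the main stroke lines. Supports up to 8 classes.
#'
#' @param n_classes number of classes (2..8).
#' @param image_shape c(height, width).
#' @return list of (row, col) coordinate matrices.
#' @export
default_stroke_masks <- function(n_classes, image_shape) {
  h <- image_shape[1L]; w <- image_shape[2L]
  mid_r <- ceiling(h / 2); mid_c <- ceiling(w / 2)
  d <- min(h, w)
  candidates <- list(
    cbind(mid_r, seq_len(w)),                      # horizontal midline
    cbind(seq_len(h), mid_c),                      # vertical midline
    cbind(seq_len(d), seq_len(d)),                 # main diagonal
    cbind(seq_len(d), d + 1L - seq_len(d)),        # anti-diagonal
    cbind(max(1L, round(h / 4)), seq_len(w)),      # upper horizontal
    cbind(seq_len(h), max(1L, round(w / 4))),      # left vertical
    cbind(min(h, round(3 * h / 4)), seq_len(w)),   # lower horizontal
    cbind(seq_len(h), min(w, round(3 * w / 4)))    # right vertical
  )
  if (n_classes > length(candidates)) {
    stop("default_stroke_masks supports at most ", length(candidates), " classes")
  }
  candidates[seq_len(n_classes)]
}

#' Generate a glyph image dataset from a spec
#'
#' Classes are assigned exactly uniformly (round-robin, then shuffled), so
#' class-marginal probabilities carry no sampling noise. For an item of class
#' c, every pixel in class c's stroke mask is active with `p_on_stroke` and
#' every other pixel with `p_on_background`; active pixels draw an integer
#' intensity uniformly from `intensity_on`, inactive from `intensity_off`.
#'
#' @param spec a [glyph_spec()].
#' @param n_items number of images (>= `n_classes`).
#' @param split_tag "train" or "test" label carried on the result.
#' @return An `image_dataset`: list with `images` (items x height x width
#'   integer array), `labels` (0-based class indices), `n_classes`,
#'   `image_shape`, `split_tag`.
#' @export
make_glyph_dataset <- function(spec, n_items, split_tag = "train") {
  stopifnot(inherits(spec, "glyph_spec"), n_items >= spec$n_classes)
  key <- vapply(spec$stroke_masks,
                function(m) paste(m[order(m[, 1], m[, 2]), ], collapse = ","), "")
  if (length(unique(key)) == 1L) {
    stop("all classes share an identical stroke mask; classes would be indistinguishable")
  }
  h <- spec$image_shape[1L]; w <- spec$image_shape[2L]; npx <- h * w
  # per-class activation probability over row-major pixel index
  p_on <- matrix(spec$p_on_background, spec$n_classes, npx)
  for (c in seq_len(spec$n_classes)) {
    m <- spec$stroke_masks[[c]]
    p_on[c, (m[, 1L] - 1L) * w + m[, 2L]] <- spec$p_on_stroke
  }
  with_seed(spec$seed + match(split_tag, c("train", "test"), nomatch = 3L) - 1L, {
    labels <- sample(rep_len(seq_len(spec$n_classes) - 1L, n_items))
    active <- matrix(stats::runif(n_items * npx), n_items, npx) < p_on[labels + 1L, , drop = FALSE]
    intens <- matrix(0L, n_items, npx)
    n_act <- sum(active)
    intens[active] <- sample(spec$intensity_on[1L]:spec$intensity_on[2L],
                             n_act, replace = TRUE)
    intens[!active] <- sample(spec$intensity_off[1L]:spec$intensity_off[2L],
                              n_items * npx - n_act, replace = TRUE)
    images <- array(0L, c(n_items, h, w))
    for (r in seq_len(h)) images[, r, ] <- intens[, ((r - 1L) * w + 1L):(r * w)]
    image_dataset(images, labels, spec$n_classes, split_tag)
  })
}

#' Construct and validate an image dataset container
#'
#' @param images items x height x width array of integer intensities 0..255.
#' @param labels per-item class index, 0-based.
#' @param n_classes class count (labels must all be < n_classes).
#' @param split_tag "train" or "test".
#' @return `image_dataset` object.
#' @export
image_dataset <- function(images, labels, n_classes, split_tag = "train") {
  stopifnot(length(dim(images)) == 3L)
  labels <- as.integer(labels)
  n_classes <- as.integer(n_classes)
  if (dim(images)[1L] != length(labels)) stop("images and labels differ in item count")
  if (any(labels < 0L) || any(labels >= n_classes)) stop("labels must lie in 0..n_classes-1")
  rng <- range(images)
  if (rng[1L] < 0 || rng[2L] > 255) stop("intensities must lie in [0, 255]")
  structure(list(images = images, labels = labels, n_classes = n_classes,
                 image_shape = dim(images)[2:3], split_tag = split_tag),
            class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  cat(sprintf("<image_dataset: %d items, %dx%d, %d classes, split=%s>\n",
              length(x$labels), x$image_shape[1L], x$image_shape[2L],
              x$n_classes, x$split_tag))
  invisible(x)
}

#' Analytic per-pixel class information of a glyph spec
#'
#' Closed-form mutual information MI(pixel-on indicator; class) in bits, from
#' the generating probabilities under exactly uniform class marginals. This is
#' the ground truth the plug-in estimator of [pixel_info_map()] converges to
#' (the intensity ranges are disjoint, so optimal binarization recovers the
#' on/off indicator exactly).
#'
#' @param spec a [glyph_spec()].
#' @return height x width matrix of MI values in bits.
#' @export
ground_truth_pixel_info <- function(spec) {
  stopifnot(inherits(spec, "glyph_spec"))
  h <- spec$image_shape[1L]; w <- spec$image_shape[2L]; npx <- h * w
  C <- spec$n_classes
  p_on_c <- matrix(spec$p_on_background, C, npx)
  for (c in seq_len(C)) {
    m <- spec$stroke_masks[[c]]
    p_on_c[c, (m[, 1L] - 1L) * w + m[, 2L]] <- spec$p_on_stroke
  }
  xlogx <- function(p) ifelse(p > 0, p * log2(p), 0)
  mi <- vapply(seq_len(npx), function(px) {
    p1 <- mean(p_on_c[, px])                      # P(on), classes uniform
    h_pix <- -xlogx(p1) - xlogx(1 - p1)
    h_cond <- mean(-xlogx(p_on_c[, px]) - xlogx(1 - p_on_c[, px]))
    h_pix - h_cond
  }, 0)
  pixel_grid(mi, spec$image_shape)
}

#' Stratified train/test split of an image dataset
#'
#' @param dataset an `image_dataset`.
#' @param test_fraction fraction of each class assigned to the test split.
#' @param seed integer seed.
#' @return list(train =, test =) of `image_dataset`s; disjoint, class-stratified,
#'   jointly covering the input items.
#' @export
split_dataset <- function(dataset, test_fraction, seed = 1L) {
  stopifnot(inherits(dataset, "image_dataset"),
            test_fraction > 0, test_fraction < 1)
  counts <- tabulate(dataset$labels + 1L, dataset$n_classes)
  if (any(counts < 2L)) stop("every class needs at least 2 items to split")
  with_seed(seed, {
    test_idx <- integer(0)
    for (c in seq_len(dataset$n_classes) - 1L) {
      idx <- which(dataset$labels == c)
      n_test <- max(1L, min(length(idx) - 1L, round(length(idx) * test_fraction)))
      test_idx <- c(test_idx, sample(idx, n_test))
    }
    test_idx <- sort(test_idx)
    train_idx <- setdiff(seq_along(dataset$labels), test_idx)
    list(
      train = image_dataset(dataset$images[train_idx, , , drop = FALSE],
                            dataset$labels[train_idx], dataset$n_classes, "train"),
      test = image_dataset(dataset$images[test_idx, , , drop = FALSE],
                           dataset$labels[test_idx], dataset$n_classes, "test")
    )
  })
}

# ---- IDX format (MNIST dialect, big-endian) ---------------------------------

IDX_MAGIC_IMAGES <- 2051L  # 0x00000803
IDX_MAGIC_LABELS <- 2049L  # 0x00000801

#' Read an IDX image/label file pair
#'
#' Reads the big-endian IDX containers used to distribute MNIST and eMNIST:
#' an image file (magic 0x00000803; dimensions items x rows x cols; uint8
#' payload in row-major order) and a label file (magic 0x00000801).
#'
#' @param image_path,label_path paths to the two files.
#' @param n_classes optional class count; defaults to `max(label) + 1`.
#' @param split_tag split label for the returned dataset.
#' @return an `image_dataset`.
#' @export
read_idx <- function(image_path, label_path, n_classes = NULL, split_tag = "train") {
  con <- file(image_path, "rb"); on.exit(close(con), add = TRUE)
  magic <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  if (!identical(magic, IDX_MAGIC_IMAGES)) {
    stop("bad image magic number ", magic, " (expected ", IDX_MAGIC_IMAGES, ")")
  }
  dims <- readBin(con, "integer", 3L, size = 4L, endian = "big")
  n <- dims[1L]; h <- dims[2L]; w <- dims[3L]
  payload <- readBin(con, "integer", n * h * w, size = 1L, signed = FALSE)
  if (length(payload) != n * h * w) {
    stop("truncated image payload: expected ", n * h * w, " bytes, got ",
         length(payload))
  }
  lcon <- file(label_path, "rb"); on.exit(close(lcon), add = TRUE)
  lmagic <- readBin(lcon, "integer", 1L, size = 4L, endian = "big")
  if (!identical(lmagic, IDX_MAGIC_LABELS)) {
    stop("bad label magic number ", lmagic, " (expected ", IDX_MAGIC_LABELS, ")")
  }
  n_lab <- readBin(lcon, "integer", 1L, size = 4L, endian = "big")
  labels <- readBin(lcon, "integer", n_lab, size = 1L, signed = FALSE)
  if (length(labels) != n_lab) {
    stop("truncated label payload: expected ", n_lab, " labels, got ",
         length(labels))
  }
  if (n_lab != n) stop("image/label count mismatch: ", n, " images vs ", n_lab, " labels")
  images <- array(0L, c(n, h, w))
  # payload is item-major then row-major within item
  pm <- matrix(payload, nrow = h * w, ncol = n)       # one column per item
  for (r in seq_len(h)) images[, r, ] <- t(pm[((r - 1L) * w + 1L):(r * w), , drop = FALSE])
  image_dataset(images, labels, n_classes %||% (max(labels) + 1L), split_tag)
}

#' Write an image dataset as an IDX file pair
#'
#' @param dataset an `image_dataset`.
#' @param image_path,label_path output paths.
#' @return invisibly, the two paths.
#' @export
write_idx <- function(dataset, image_path, label_path) {
  stopifnot(inherits(dataset, "image_dataset"))
  n <- length(dataset$labels)
  h <- dataset$image_shape[1L]; w <- dataset$image_shape[2L]
  con <- file(image_path, "wb"); on.exit(close(con), add = TRUE)
  writeBin(c(IDX_MAGIC_IMAGES, n, h, w), con, size = 4L, endian = "big")
  pm <- matrix(0L, nrow = h * w, ncol = n)
  for (r in seq_len(h)) pm[((r - 1L) * w + 1L):(r * w), ] <- t(dataset$images[, r, ])
  writeBin(as.raw(pm), con)
  lcon <- file(label_path, "wb"); on.exit(close(lcon), add = TRUE)
  writeBin(c(IDX_MAGIC_LABELS, n), lcon, size = 4L, endian = "big")
  writeBin(as.raw(dataset$labels), lcon)
  invisible(c(image_path, label_path))
}
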