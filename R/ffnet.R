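# A four-layer feed-forward classifier (input -> HL1 -> HL2 -> output) with
# sigmoid hidden units, a softmax readout, zero (untrained) biases, and plain
# mini-batch SGD on cross-entropy. Weight and activity snapshots are recorded
# on a logarithmically thinned epoch schedule so topology and information
# analyses can be run per training stage.

#' Initialize a layered network with uniform random weights
#'
#' Every weight is drawn independently and uniformly from [-1, 1]. Biases are
#' identically zero and are never trained, so the network is fully described
#' by its three signed weight blocks: alpha (input -> HL1), beta (HL1 -> HL2)
#' and gamma_w (HL2 -> output).
#'
#' @param layer_sizes integer c(n_in, n_hl1, n_hl2, n_out).
#' @param seed integer seed; initialization is reproducible from it.
#' @return object of class `layered_net` with elements `alpha`, `beta`,
#'   `gamma_w`, `layer_sizes`.
#' @export
init_network <- function(layer_sizes = c(784L, 100L, 100L, 10L), seed = 1L) {
  layer_sizes <- as.integer(layer_sizes)
  stopifnot(length(layer_sizes) == 4L)
  if (any(layer_sizes <= 0L)) stop("layer sizes must be positive")
  with_seed(seed, {
    structure(list(
      alpha = matrix(stats::runif(layer_sizes[1L] * layer_sizes[2L], -1, 1),
                     layer_sizes[1L], layer_sizes[2L]),
      beta = matrix(stats::runif(layer_sizes[2L] * layer_sizes[3L], -1, 1),
                    layer_sizes[2L], layer_sizes[3L]),
      gamma_w = matrix(stats::runif(layer_sizes[3L] * layer_sizes[4L], -1, 1),
                       layer_sizes[3L], layer_sizes[4L]),
      layer_sizes = layer_sizes
    ), class = "layered_net")
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass through the network
#'
#' Pixel intensities are standardized by division by 255 before the input
#' layer. Hidden layers apply the logistic sigmoid; the output layer applies
#' softmax, and the predicted class is the argmax output node (ties broken by
#' lowest class index). The "input activity" of a node is its standardized
#' intensity.
#'
#' @param params a `layered_net`.
#' @param images items x height x width array (intensities 0..255), or an
#'   already-flattened items x n_in matrix of standardized values.
#' @return object of class `forward_activations`: `input_act`, `hl1_act`,
#'   `hl2_act`, `out_act` (rows sum to 1) and `predicted` (0-based).
#' @export
forward <- function(params, images) {
  stopifnot(inherits(params, "layered_net"))
  x <- if (length(dim(images)) == 3L) flatten_images(images) / 255 else as.matrix(images)
  if (ncol(x) != params$layer_sizes[1L]) {
    stop("input has ", ncol(x), " features but the network expects ",
         params$layer_sizes[1L])
  }
  h1 <- sigmoid(x %*% params$alpha)
  h2 <- sigmoid(h1 %*% params$beta)
  out <- softmax_rows(h2 %*% params$gamma_w)
  structure(list(input_act = x, hl1_act = h1, hl2_act = h2, out_act = out,
                 predicted = max.col(out, ties.method = "first") - 1L),
            class = "forward_activations")
}

# Cross-entropy loss and analytic gradients for one mini-batch.
# x: b x n_in standardized inputs; y: 0-based labels.
net_gradients <- function(params, x, y) {
  b <- nrow(x)
  h1 <- sigmoid(x %*% params$alpha)
  h2 <- sigmoid(h1 %*% params$beta)
  out <- softmax_rows(h2 %*% params$gamma_w)
  p_true <- out[cbind(seq_len(b), y + 1L)]
  loss <- -mean(log(pmax(p_true, 1e-300)))
  d3 <- out
  d3[cbind(seq_len(b), y + 1L)] <- d3[cbind(seq_len(b), y + 1L)] - 1
  d3 <- d3 / b
  g_gamma <- crossprod(h2, d3)
  d2 <- (d3 %*% t(params$gamma_w)) * h2 * (1 - h2)
  g_beta <- crossprod(h1, d2)
  d1 <- (d2 %*% t(params$beta)) * h1 * (1 - h1)
  g_alpha <- crossprod(x, d1)
  list(loss = loss, g_alpha = g_alpha, g_beta = g_beta, g_gamma = g_gamma)
}

#' The logarithmically thinned snapshot schedule
#'
#' Epochs at which weights and test-set activities are recorded: the first
#' 30 epochs; every 10 to 100; every 100 to 1,000; every 1,000 to 10,000; and
#' every 10,000 to 100,000 — 64 epochs in total at `max_epoch = 100000`. For
#' smaller `max_epoch` the same rule is truncated (and `max_epoch` itself is
#' always included so the final state is snapshotted).
#'
#' @param max_epoch last training epoch (>= 1).
#' @return strictly increasing integer vector of epochs.
#' @export
snapshot_schedule <- function(max_epoch) {
  stopifnot(max_epoch >= 1)
  full <- c(1:30, seq(40L, 100L, 10L), seq(200L, 1000L, 100L),
            seq(2000L, 10000L, 1000L), seq(20000L, 100000L, 10000L))
  sched <- full[full <= max_epoch]
  if (length(sched) == 0L || sched[length(sched)] < max_epoch) {
    sched <- c(sched, as.integer(max_epoch))
  }
  sched
}

#' Train the network with mini-batch SGD, recording snapshots
#'
#' One epoch is one full pass over the (shuffled) training set in mini-batches;
#' the loss is cross-entropy on the softmax output. Biases stay zero and no
#' regularization is applied. After each scheduled epoch's updates, the weight
#' blocks, the forward activations on the held-out test set, and the test
#' accuracy (fraction of items whose argmax output matches the label) are
#' recorded.
#'
#' @param params initial `layered_net` (see [init_network()]).
#' @param train_set,test_set `image_dataset`s with matching shapes.
#' @param lr SGD learning rate.
#' @param batch_size mini-batch size.
#' @param max_epoch number of full passes.
#' @param schedule epochs to snapshot; defaults to [snapshot_schedule()].
#' @param seed integer seed driving the per-epoch shuffles.
#' @return object of class `training_trace`: `schedule`, `accuracy`,
#'   `weights` (list of `layered_net` per scheduled epoch), `activities`
#'   (list of `forward_activations` on the test set), `train_loss` (per epoch),
#'   `test_labels`, `n_classes`, `image_shape`, `seed`, `hyperparams`.
#' @export
train <- function(params, train_set, test_set, lr = 0.05, batch_size = 32L,
                  max_epoch = 300L, schedule = snapshot_schedule(max_epoch),
                  seed = 1L) {
  stopifnot(inherits(params, "layered_net"),
            inherits(train_set, "image_dataset"),
            inherits(test_set, "image_dataset"))
  if (any(schedule < 1L) || any(schedule > max_epoch)) {
    stop("schedule must lie within [1, max_epoch]")
  }
  schedule <- sort(unique(as.integer(schedule)))
  x_train <- flatten_images(train_set$images) / 255
  y_train <- train_set$labels
  x_test <- flatten_images(test_set$images) / 255
  n <- nrow(x_train)
  weights <- vector("list", length(schedule))
  activities <- vector("list", length(schedule))
  accuracy <- numeric(length(schedule))
  train_loss <- numeric(max_epoch)
  with_seed(seed, {
    for (epoch in seq_len(max_epoch)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batch_size)
      eloss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, n)]
        g <- net_gradients(params, x_train[idx, , drop = FALSE], y_train[idx])
        if (!is.finite(g$loss)) {
          stop("training diverged at epoch ", epoch, ": non-finite loss")
        }
        params$alpha <- params$alpha - lr * g$g_alpha
        params$beta <- params$beta - lr * g$g_beta
        params$gamma_w <- params$gamma_w - lr * g$g_gamma
        eloss <- eloss + g$loss * length(idx)
      }
      train_loss[epoch] <- eloss / n
      pos <- match(epoch, schedule)
      if (!is.na(pos)) {
        weights[[pos]] <- params
        act <- forward(params, x_test)
        activities[[pos]] <- act
        accuracy[pos] <- mean(act$predicted == test_set$labels)
      }
    }
  })
  structure(list(
    schedule = schedule, accuracy = accuracy, weights = weights,
    activities = activities, train_loss = train_loss,
    test_labels = test_set$labels, n_classes = train_set$n_classes,
    image_shape = train_set$image_shape, seed = as.integer(seed),
    hyperparams = list(lr = lr, batch_size = as.integer(batch_size),
                       max_epoch = as.integer(max_epoch))
  ), class = "training_trace")
}

#' @export
print.training_trace <- function(x, ...) {
  cat(sprintf(
    "<training_trace: %d snapshots over %d epochs, final accuracy %.3f>\n",
    length(x$schedule), x$hyperparams$max_epoch,
    x$accuracy[length(x$accuracy)]))
  invisible(x)
}

#' Export a trace's accuracy table
#'
#' @param trace a `training_trace`.
#' @return data.frame(epoch, accuracy).
#' @export
accuracy_table <- function(trace) {
  data.frame(epoch = trace$schedule, accuracy = trace$accuracy)
}
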