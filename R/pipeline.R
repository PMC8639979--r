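# End-to-end orchestration: generate (or load) data, train the classifier,
# snapshot on the epoch schedule, and run the topology / information /
# geometry analyses into a deterministic artifact directory.

#' Build a run configuration
#'
#' All pipeline stages consume only this configuration (plus the snapshot
#' store it produces), so a run directory is reproducible from its embedded
#' config and master seed. Defaults define the package's reference synthetic
#' task: 14x14 five-class glyphs, 2,000 training and 500 test items, a
#' 196/100/100/5 network trained 300 epochs with SGD (lr 0.5, batches of 32;
#' the relatively high rate compensates for the small update count per epoch
#' so weight-growth dynamics are observable within the desk-scale schedule).
#'
#' @param glyph list of overrides for [glyph_spec()] (ignored when IDX paths
#'   are given).
#' @param idx_paths optional list(train_images, train_labels, test_images,
#'   test_labels) of IDX files to use instead of synthetic glyphs.
#' @param n_train,n_test synthetic item counts.
#' @param hidden sizes of the two hidden layers.
#' @param lr,batch_size,max_epoch training hyperparameters.
#' @param gamma_res modularity resolution parameter.
#' @param n_runs_q Louvain runs per epoch; the Q trajectory is the mean Q over
#'   runs (low-noise, like a many-run consensus) and the best-Q partition is
#'   kept for cartography.
#' @param n_runs_consensus runs behind the consensus partition.
#' @param tau consensus agreement threshold.
#' @param pca_layers layers entering the concatenated PCA.
#' @param edge_statistic "mean_abs" or "sd" for edge-change maps.
#' @param n_perm permutations for inference.
#' @param seed master seed; every stage derives sub-seeds from it.
#' @return object of class `run_config`.
#' @export
run_config <- function(glyph = list(), idx_paths = NULL,
                       n_train = 2000L, n_test = 500L,
                       hidden = c(100L, 100L), lr = 0.5, batch_size = 32L,
                       max_epoch = 300L, gamma_res = 1.0, n_runs_q = 20L,
                       n_runs_consensus = 50L, tau = 0.5,
                       pca_layers = c("input", "hl1", "hl2", "out"),
                       edge_statistic = "mean_abs", n_perm = 10000L,
                       seed = 1L) {
  cfg <- list(glyph = glyph, idx_paths = idx_paths, n_train = as.integer(n_train),
              n_test = as.integer(n_test), hidden = as.integer(hidden), lr = lr,
              batch_size = as.integer(batch_size), max_epoch = as.integer(max_epoch),
              gamma_res = gamma_res, n_runs_q = as.integer(n_runs_q),
              n_runs_consensus = as.integer(n_runs_consensus), tau = tau,
              pca_layers = pca_layers, edge_statistic = edge_statistic,
              n_perm = as.integer(n_perm), seed = as.integer(seed))
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages: data (generate glyphs or read IDX), train (SGD with scheduled
#' snapshots), modularity (per-epoch Louvain Q trajectory and a consensus
#' partition on the final snapshot), cartography, information maps,
#' PCA/untangling, period segmentation and period correlations. Tabular
#' artifacts are written as CSV, the manifest and segmentation as JSON, and
#' the full trace as an RDS snapshot store.
#'
#' @param config a `run_config`.
#' @param out_dir output directory (created if needed).
#' @param keep_trace also save the full trace as trace.rds (default TRUE).
#' @return invisibly, a list with all in-memory results and `out_dir`.
#' @export
run_all <- function(config, out_dir, keep_trace = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- data ------------------------------------------------------------------
  data_sets <- stage("data", {
    if (!is.null(config$idx_paths)) {
      list(train = read_idx(config$idx_paths$train_images,
                            config$idx_paths$train_labels, split_tag = "train"),
           test = read_idx(config$idx_paths$test_images,
                           config$idx_paths$test_labels, split_tag = "test"),
           spec = NULL)
    } else {
      spec <- do.call(glyph_spec, utils::modifyList(
        list(seed = sub_seed(config$seed, 1L)), config$glyph))
      list(train = make_glyph_dataset(spec, config$n_train, "train"),
           test = make_glyph_dataset(spec, config$n_test, "test"),
           spec = spec)
    }
  })
  train_set <- data_sets$train; test_set <- data_sets$test
  n_classes <- train_set$n_classes
  image_shape <- train_set$image_shape

  # -- training --------------------------------------------------------------
  trace <- stage("train", {
    net0 <- init_network(c(prod(image_shape), config$hidden, n_classes),
                         seed = sub_seed(config$seed, 2L))
    train(net0, train_set, test_set, lr = config$lr,
          batch_size = config$batch_size, max_epoch = config$max_epoch,
          seed = sub_seed(config$seed, 3L))
  })
  utils::write.csv(accuracy_table(trace), file.path(out_dir, "accuracy.csv"),
                   row.names = FALSE)

  # -- modularity trajectory -------------------------------------------------
  q_result <- stage("modularity", {
    per_epoch <- lapply(seq_along(trace$schedule), function(k) {
      W <- symmetrize(assemble_adjacency(trace$weights[[k]]))
      runs <- lapply(seq_len(config$n_runs_q), function(r) {
        louvain(W, config$gamma_res, n_restarts = 2L,
                seed = sub_seed(config$seed, 100L + k * 100L + r))
      })
      qs <- vapply(runs, function(p) p$q, 0)
      list(partition = runs[[which.max(qs)]], q_mean = mean(qs))
    })
    list(partitions = lapply(per_epoch, `[[`, "partition"),
         q = vapply(per_epoch, `[[`, 0, "q_mean"))
  })
  utils::write.csv(
    data.frame(epoch = trace$schedule, q = q_result$q,
               n_modules = vapply(q_result$partitions, function(p) p$n_modules, 0)),
    file.path(out_dir, "modularity.csv"), row.names = FALSE)

  consensus <- stage("consensus", {
    W_final <- symmetrize(assemble_adjacency(
      trace$weights[[length(trace$schedule)]]))
    consensus_partition(W_final, config$gamma_res,
                        n_runs = config$n_runs_consensus,
                        seed = sub_seed(config$seed, 4L), tau = config$tau)
  })

  # -- cartography -----------------------------------------------------------
  node_layer <- assemble_adjacency(trace$weights[[1L]])$node_layer
  profiles <- stage("cartography", {
    suppressWarnings(cartography_per_epoch(trace, q_result$partitions))
  })
  utils::write.csv(cartography_table(profiles, node_layer),
                   file.path(out_dir, "cartography.csv"), row.names = FALSE)

  # -- information -----------------------------------------------------------
  info <- stage("information", {
    list(pixel = pixel_info_map(train_set),
         nodes = node_info_trajectory(trace),
         ground_truth = if (!is.null(data_sets$spec)) {
           ground_truth_pixel_info(data_sets$spec)
         } else NULL)
  })
  utils::write.csv(pixel_info_table(info$pixel),
                   file.path(out_dir, "pixel_info.csv"), row.names = FALSE)
  utils::write.csv(info$nodes$layer_means,
                   file.path(out_dir, "node_info.csv"), row.names = FALSE)

  # -- low-dimensional geometry ---------------------------------------------
  lowdim <- stage("pca", {
    X <- concat_activity(trace, config$pca_layers)
    emb <- suppressWarnings(fit_pca(X, "concatenated"))
    final_act <- trace$activities[[length(trace$schedule)]]
    correct <- final_act$predicted == trace$test_labels
    final_rows <- attr(X, "epoch_of_row") == trace$schedule[length(trace$schedule)]
    emb_final <- emb; emb_final$scores <- emb$scores[final_rows, , drop = FALSE]
    list(embedding = emb,
         vd10 = vd10_trajectory(trace, config$pca_layers),
         untangling = untangling_trajectory(trace, emb, config$pca_layers),
         loadings = loading_comparison(emb_final, correct),
         hl = list(hl1 = per_layer_pca(trace, "hl1")$vd10,
                   hl2 = per_layer_pca(trace, "hl2")$vd10))
  })
  utils::write.csv(lowdim$vd10, file.path(out_dir, "vd10.csv"), row.names = FALSE)
  utils::write.csv(lowdim$untangling, file.path(out_dir, "distances.csv"),
                   row.names = FALSE)
  if (nrow(lowdim$loadings) > 0L) {
    utils::write.csv(lowdim$loadings, file.path(out_dir, "loading_comparison.csv"),
                     row.names = FALSE)
  }

  # -- segmentation and period statistics ------------------------------------
  periods <- stage("periods", {
    m <- length(trace$schedule)
    if (m >= 6L) {
      segment_periods(q_result$q, trace$schedule, mode = "changepoint")
    } else {
      # too few snapshots for a changepoint fit: split the schedule in thirds
      b1 <- max(1L, floor(m / 3))
      b2 <- min(m - 1L, max(b1 + 1L, ceiling(2 * m / 3)))
      segment_periods(q_result$q, trace$schedule, mode = "fixed",
                      fixed_bounds = trace$schedule[c(b1, b2)])
    }
  })
  i_p_ref <- info$ground_truth %||% info$pixel$i_p
  period_stats <- stage("period_correlations", {
    period_correlations(trace, q_result$q, periods, i_p_ref,
                        statistic = config$edge_statistic,
                        n_perm = config$n_perm,
                        seed = sub_seed(config$seed, 5L))
  })
  utils::write.csv(period_stats, file.path(out_dir, "period_correlations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(bounds_epoch = periods$bounds_epoch, provenance = periods$provenance,
         degenerate = periods$degenerate),
    file.path(out_dir, "segmentation.json"), auto_unbox = TRUE)

  # -- manifest and snapshot store -------------------------------------------
  if (keep_trace) saveRDS(trace, file.path(out_dir, "trace.rds"))
  manifest <- list(
    config = unclass(config),
    n_snapshots = length(trace$schedule),
    final_accuracy = trace$accuracy[length(trace$accuracy)],
    config_hash = config_hash(config),
    r_version = as.character(getRversion()),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(config = config, datasets = data_sets, trace = trace,
                 q = q_result$q, partitions = q_result$partitions,
                 consensus = consensus, profiles = profiles, info = info,
                 lowdim = lowdim, periods = periods,
                 period_stats = period_stats, out_dir = out_dir))
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))), collapse = "\n")
  # small deterministic polynomial hash; avoids external digest dependencies
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Summarise a completed run directory
#'
#' Reads the tabular artifacts of [run_all()] and writes a plain-markdown
#' summary (summary.md). If ggplot2 is installed, canonical figures (accuracy
#' and Q vs epoch; vd10 and distance trajectories) are rendered to PDF.
#'
#' @param run_dir a directory produced by [run_all()].
#' @return invisibly, the summary file path.
#' @export
report <- function(run_dir) {
  need <- c("accuracy.csv", "modularity.csv", "vd10.csv", "distances.csv",
            "period_correlations.csv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing) > 0L) {
    stop("missing artifacts in ", run_dir, ": ", paste(missing, collapse = ", "))
  }
  acc <- utils::read.csv(file.path(run_dir, "accuracy.csv"))
  mod <- utils::read.csv(file.path(run_dir, "modularity.csv"))
  vd <- utils::read.csv(file.path(run_dir, "vd10.csv"))
  dist <- utils::read.csv(file.path(run_dir, "distances.csv"))
  pstats <- utils::read.csv(file.path(run_dir, "period_correlations.csv"))
  lines <- c(
    "# Run summary", "",
    sprintf("- snapshots: %d (epochs %g..%g)", nrow(acc), min(acc$epoch),
            max(acc$epoch)),
    sprintf("- final test accuracy: %.4f", acc$accuracy[nrow(acc)]),
    sprintf("- Q range: %.4f .. %.4f", min(mod$q), max(mod$q)),
    sprintf("- vd10 range: %.4f .. %.4f", min(vd$vd10), max(vd$vd10)),
    sprintf("- between-category distance: %.3f (first) -> %.3f (final)",
            dist$between[1L], dist$between[nrow(dist)]),
    "", "## Period correlations", "",
    utils::capture.output(print(pstats, row.names = FALSE))
  )
  if (file.exists(file.path(run_dir, "loading_comparison.csv"))) {
    lc <- utils::read.csv(file.path(run_dir, "loading_comparison.csv"))
    lines <- c(lines, "", sprintf(
      "## Loading comparison: %d of %d components significant at FDR 0.05",
      sum(lc$significant), nrow(lc)))
  } else {
    lines <- c(lines, "", "## Loading comparison: no incorrect items; no-op")
  }
  out <- file.path(run_dir, "summary.md")
  writeLines(lines, out)
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    report_figures(run_dir, acc, mod, vd, dist)
  }
  invisible(out)
}

report_figures <- function(run_dir, acc, mod, vd, dist) {
  gg <- ggplot2::ggplot
  aes <- ggplot2::aes
  p1 <- gg(merge(acc, mod), aes(x = epoch)) +
    ggplot2::geom_line(aes(y = accuracy), color = "steelblue") +
    ggplot2::geom_line(aes(y = q / max(q)), color = "darkorange") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(y = "accuracy (blue) / scaled Q (orange)",
                  title = "Accuracy and modularity across training")
  p2 <- gg(vd, aes(epoch, vd10)) + ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(title = "Top-10 explained variance per epoch")
  p3 <- gg(dist, aes(epoch)) +
    ggplot2::geom_line(aes(y = between), color = "darkgreen") +
    ggplot2::geom_line(aes(y = within), color = "purple") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(y = "between (green) / within (purple)",
                  title = "Category untangling distances")
  grDevices::pdf(file.path(run_dir, "figures.pdf"), width = 7, height = 5)
  print(p1); print(p2); print(p3)
  grDevices::dev.off()
}
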