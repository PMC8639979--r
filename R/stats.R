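# Permutation inference for Pearson correlations, Steiger's test for
# dependent correlations, and segmentation of the modularity trajectory into
# early / middle / late training periods.

#' Permutation test for a Pearson correlation
#'
#' Shuffles `y` `n_perm` times and compares the observed correlation with the
#' null distribution. The two-sided p-value is
#' (1 + #\{|r_null| >= |r_obs|\}) / (n_perm + 1); one-sided variants count the
#' signed exceedances. Pairs with missing values are dropped (with a message).
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @param alternative "two.sided", "greater" or "less".
#' @return object of class `permutation_result`: `r_obs`, `p_perm`, `n_perm`,
#'   `null_quantiles` (5th and 95th percentiles of the null), `n`, `seed`,
#'   `alternative`.
#' @export
perm_corr <- function(x, y, n_perm = 10000L, seed = 1L,
                      alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) {
    message(sum(!ok), " incomplete pair(s) dropped")
    x <- x[ok]; y <- y[ok]
  }
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input vector")
  r_obs <- stats::cor(x, y)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) stats::cor(x, sample(y)), 0)
  })
  exceed <- switch(alternative,
    two.sided = sum(abs(null) >= abs(r_obs)),
    greater = sum(null >= r_obs),
    less = sum(null <= r_obs))
  structure(list(
    r_obs = r_obs, p_perm = (1 + exceed) / (n_perm + 1),
    n_perm = as.integer(n_perm),
    null_quantiles = stats::quantile(null, c(0.05, 0.95), names = FALSE),
    n = length(x), seed = seed, alternative = alternative
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<perm_corr: r = %.4f, p_perm = %.4g (%s, n = %d, %d perms)>\n",
              x$r_obs, x$p_perm, x$alternative, x$n, x$n_perm))
  invisible(x)
}

#' Steiger's test for two dependent correlations sharing a variable
#'
#' Tests whether r12 and r13 (correlations of variables 2 and 3 with the
#' shared variable 1) differ, accounting for r23, via Fisher-z transformed
#' correlations with the shared-variable covariance correction
#' (Steiger 1980, Psychological Bulletin 87:245-251).
#'
#' @param r12,r13 the two correlations being compared.
#' @param r23 correlation between variables 2 and 3.
#' @param n sample size (> 3).
#' @return list(z, p) with a two-sided p-value.
#' @export
dependent_corr_test <- function(r12, r13, r23, n) {
  stopifnot(abs(r12) <= 1, abs(r13) <= 1, abs(r23) <= 1, n > 3)
  if (abs(r12) == 1 || abs(r13) == 1) stop("degenerate |r| = 1 input")
  z12 <- atanh(r12); z13 <- atanh(r13)
  rbar <- (r12 + r13) / 2
  psi <- r23 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r23^2)
  cov_term <- psi / (1 - rbar^2)^2
  z <- (z12 - z13) * sqrt((n - 3) / (2 - 2 * cov_term))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Segment a modularity trajectory into early / middle / late periods
#'
#' Fixed mode echoes the supplied boundaries. Changepoint mode fits a
#' continuous piecewise-linear function of Q against log10(epoch) with two
#' breakpoints, scanning all interior breakpoint pairs at least 2 schedule
#' indices apart, and returns the least-squares-best boundaries. A monotone
#' trajectory still yields three contiguous segments (the middle may be
#' minimal); this degeneracy is flagged in the result.
#'
#' @param q_by_epoch numeric Q values on the schedule.
#' @param epochs the scheduled epochs (same length).
#' @param mode "changepoint" or "fixed".
#' @param fixed_bounds for fixed mode: c(last early epoch, last middle epoch).
#' @return object of class `period_segmentation`: `early`, `middle`, `late`
#'   (schedule index ranges), `bounds_epoch` (epoch values of the two
#'   boundaries), `provenance`, `degenerate`.
#' @export
segment_periods <- function(q_by_epoch, epochs, mode = c("changepoint", "fixed"),
                            fixed_bounds = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(q_by_epoch) == length(epochs))
  if (any(!is.finite(q_by_epoch))) stop("non-finite Q values")
  m <- length(epochs)
  if (mode == "fixed") {
    stopifnot(length(fixed_bounds) == 2L)
    b1 <- max(which(epochs <= fixed_bounds[1L]))
    b2 <- max(which(epochs <= fixed_bounds[2L]))
    stopifnot(b1 >= 1L, b2 > b1, b2 < m)
    return(new_segmentation(b1, b2, m, epochs, "fixed", FALSE))
  }
  if (m < 6L) stop("changepoint mode needs at least 6 points")
  x <- log10(epochs)
  best <- NULL; best_rss <- Inf
  for (b1 in 2L:(m - 4L)) for (b2 in (b1 + 2L):(m - 2L)) {
    h1 <- pmax(x - x[b1], 0); h2 <- pmax(x - x[b2], 0)
    fit <- stats::lm.fit(cbind(1, x, h1, h2), q_by_epoch)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) { best_rss <- rss; best <- c(b1, b2) }
  }
  # slope per segment from the best fit to detect a degenerate (monotone) middle
  h1 <- pmax(x - x[best[1L]], 0); h2 <- pmax(x - x[best[2L]], 0)
  cf <- stats::lm.fit(cbind(1, x, h1, h2), q_by_epoch)$coefficients
  slopes <- c(cf[2L], cf[2L] + cf[3L], cf[2L] + cf[3L] + cf[4L])
  # slope comparisons need a scale-aware tolerance: an exactly linear
  # trajectory fits with numerically tiny, sign-arbitrary kinks
  eps <- 1e-8 * max(abs(q_by_epoch), 1e-12) / max(diff(range(x)), 1e-12)
  degenerate <- !(slopes[2L] > slopes[1L] + eps && slopes[3L] < slopes[2L] - eps)
  if (degenerate) message("trajectory is not flat-rise-fall; segmentation is degenerate")
  new_segmentation(best[1L], best[2L], m, epochs, "changepoint", degenerate)
}

new_segmentation <- function(b1, b2, m, epochs, provenance, degenerate) {
  structure(list(
    early = 1L:b1, middle = (b1 + 1L):b2, late = (b2 + 1L):m,
    bounds_epoch = c(epochs[b1], epochs[b2]),
    provenance = provenance, degenerate = degenerate
  ), class = "period_segmentation")
}

#' @export
print.period_segmentation <- function(x, ...) {
  cat(sprintf(
    "<periods (%s): early <= epoch %g, middle <= epoch %g, late beyond%s>\n",
    x$provenance, x$bounds_epoch[1L], x$bounds_epoch[2L],
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Per-period correlation analyses of a training run
#'
#' For each period of a segmentation, computes (with permutation inference):
#' the accuracy-Q correlation across the period's scheduled epochs, and the
#' correlation between the period's input-edge-change map and the per-pixel
#' information map I_P. Periods with fewer than 3 epochs, or with constant
#' inputs, are skipped with a note.
#'
#' @param trace a `training_trace`.
#' @param q_by_epoch Q per scheduled epoch.
#' @param segmentation a `period_segmentation`.
#' @param i_p_map height x width I_P matrix ([pixel_info_map()]`$i_p` or
#'   [ground_truth_pixel_info()]).
#' @param statistic edge-change statistic, see [edge_change_map()].
#' @param n_perm permutations.
#' @param seed master seed.
#' @return data.frame(analysis, period, r, p_perm, n, n_perm, note).
#' @export
period_correlations <- function(trace, q_by_epoch, segmentation, i_p_map,
                                statistic = "mean_abs", n_perm = 10000L,
                                seed = 1L) {
  stopifnot(inherits(trace, "training_trace"),
            inherits(segmentation, "period_segmentation"))
  periods <- list(early = segmentation$early, middle = segmentation$middle,
                  late = segmentation$late)
  rows <- list()
  for (pn in names(periods)) {
    idx <- periods[[pn]]
    # accuracy vs Q within the period
    row <- data.frame(analysis = "accuracy_vs_q", period = pn, r = NA_real_,
                      p_perm = NA_real_, n = length(idx), n_perm = n_perm,
                      note = "")
    if (length(idx) < 3L) {
      row$note <- "fewer than 3 epochs; skipped"
    } else if (stats::sd(trace$accuracy[idx]) == 0 || stats::sd(q_by_epoch[idx]) == 0) {
      row$note <- "constant accuracy or Q; skipped"
    } else {
      pr <- perm_corr(trace$accuracy[idx], q_by_epoch[idx], n_perm = n_perm,
                      seed = sub_seed(seed, match(pn, names(periods))))
      row$r <- pr$r_obs; row$p_perm <- pr$p_perm
    }
    rows[[length(rows) + 1L]] <- row
    # edge-change map vs I_P over pixels
    row <- data.frame(analysis = "edge_change_vs_ip", period = pn, r = NA_real_,
                      p_perm = NA_real_, n = length(i_p_map), n_perm = n_perm,
                      note = "")
    if (length(idx) < 2L) {
      row$note <- "fewer than 2 epochs; no edge-change map"
    } else {
      ecm <- edge_change_map(trace, range(trace$schedule[idx]), statistic)
      if (stats::sd(as.vector(ecm)) == 0) {
        row$note <- "constant edge-change map; skipped"
      } else {
        pr <- perm_corr(as.vector(ecm), as.vector(i_p_map), n_perm = n_perm,
                        seed = sub_seed(seed, 10L + match(pn, names(periods))))
        row$r <- pr$r_obs; row$p_perm <- pr$p_perm
      }
    }
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}

#' Per-epoch correlations of topology with pixel-on information
#'
#' Correlates each epoch's input-layer participation coefficient and
#' module-degree z-score with the I_D map, with permutation null bounds.
#' Pixels with undefined I_D are dropped pairwise.
#'
#' @param profiles result of [cartography_per_epoch()].
#' @param i_d_map height x width I_D matrix (row-major pixel order matches
#'   input-node order).
#' @param n_input number of input nodes.
#' @param n_perm permutations per epoch.
#' @param seed master seed.
#' @return data.frame(epoch, statistic, r, p_perm, null_lo, null_hi).
#' @export
topology_info_correlations <- function(profiles, i_d_map, n_input,
                                       n_perm = 1000L, seed = 1L) {
  idv <- as.vector(t(i_d_map))          # row-major, matching node order
  do.call(rbind, lapply(seq_along(profiles), function(k) {
    p <- profiles[[k]]
    do.call(rbind, lapply(c("pc", "mz"), function(st) {
      v <- p[[st]][seq_len(n_input)]
      pr <- suppressMessages(
        perm_corr(v, idv, n_perm = n_perm,
                  seed = sub_seed(seed, k * 10L + (st == "mz"))))
      data.frame(epoch = as.integer(names(profiles)[k]), statistic = st,
                 r = pr$r_obs, p_perm = pr$p_perm,
                 null_lo = pr$null_quantiles[1L], null_hi = pr$null_quantiles[2L])
    }))
  }))
}
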