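# Signed, weighted modularity and its Louvain maximisation, multi-run
# consensus partitioning, and a resolution-parameter stability sweep.
#
# The quality function is the signed modularity
#   Q = (1/v+) sum_ij (w+_ij - g e+_ij) d(M_i, M_j)
#     - (1/(v+ + v-)) sum_ij (w-_ij - g e-_ij) d(M_i, M_j)
# where w+/w- are the positive part and the magnitude of the negative part of
# the (symmetric) weight matrix, e+-_ij = s_i s_j / v is the strength-product
# null for each sign, v+- the total weight of each sign, and g the resolution
# parameter scaling the null term. Positive within-module weight is rewarded
# at full rate while negative within-module weight is penalised at the
# discounted 1/(v+ + v-) rate, so positive structure dominates.

#' Signed weighted modularity of a partition
#'
#' @param W symmetric signed weight matrix (symmetrize layered adjacencies
#'   first, e.g. with [symmetrize()]).
#' @param assignments integer module id per node (contiguous ids not required
#'   here).
#' @param gamma_res resolution parameter scaling the null model.
#' @return scalar Q.
#' @export
modularity_signed <- function(W, assignments, gamma_res = 1) {
  W <- as.matrix(W)
  n <- nrow(W)
  stopifnot(n == ncol(W), length(assignments) == n)
  if (all(W == 0)) stop("modularity is undefined for an all-zero matrix")
  Wp <- pmax(W, 0); Wn <- pmax(-W, 0)
  sp <- rowSums(Wp); sn <- rowSums(Wn)
  vp <- sum(sp); vn <- sum(sn)
  same <- outer(assignments, assignments, "==")
  qp <- if (vp > 0) sum((Wp - gamma_res * outer(sp, sp) / vp)[same]) / vp else 0
  qn <- if (vn > 0) sum((Wn - gamma_res * outer(sn, sn) / vn)[same]) / (vp + vn) else 0
  qp - qn
}

# Greedy local-move phase: sweeps nodes in random order, moving each to the
# community with the best signed-modularity gain, until no move improves.
# Maintains node-to-community strength matrices incrementally so each gain
# evaluation is O(#communities) and each move O(n). Returns list(comm,
# moved_any).
move_phase <- function(W, gamma_res, comm) {
  n <- nrow(W)
  comm <- match(comm, sort(unique(comm)))       # contiguous 1..K
  K <- max(comm)
  Wp <- pmax(W, 0); Wn <- pmax(-W, 0)
  dp <- diag(Wp); dn <- diag(Wn)
  sp <- rowSums(Wp); sn <- rowSums(Wn)
  vp <- sum(sp); vn <- sum(sn)
  cp <- if (vp > 0) gamma_res / vp else 0
  cn <- if (vn > 0) gamma_res / vn else 0
  scale_p <- if (vp > 0) 1 / vp else 0
  scale_n <- if (vp + vn > 0) 1 / (vp + vn) else 0
  Sp <- Sn <- numeric(K)
  Sp[seq_len(K)] <- as.vector(rowsum(sp, comm, reorder = TRUE))
  Sn[seq_len(K)] <- as.vector(rowsum(sn, comm, reorder = TRUE))
  # node x community strengths (includes any self-loop in the own column)
  Kp <- t(rowsum(t(Wp), comm, reorder = TRUE))
  Kn <- t(rowsum(t(Wn), comm, reorder = TRUE))
  moved_any <- FALSE
  repeat {
    improved <- FALSE
    for (i in sample.int(n)) {
      a <- comm[i]
      kp_i <- Kp[i, ]; kn_i <- Kn[i, ]
      kp_i[a] <- kp_i[a] - dp[i]; kn_i[a] <- kn_i[a] - dn[i]
      # community totals with i removed
      Sp_i <- Sp; Sn_i <- Sn
      Sp_i[a] <- Sp_i[a] - sp[i]; Sn_i[a] <- Sn_i[a] - sn[i]
      gain <- scale_p * (2 * kp_i - 2 * cp * sp[i] * Sp_i) -
              scale_n * (2 * kn_i - 2 * cn * sn[i] * Sn_i)
      b <- which.max(gain)
      if (gain[b] <= gain[a] + 1e-13) b <- a
      if (b != a) {
        comm[i] <- b
        Sp[a] <- Sp[a] - sp[i]; Sn[a] <- Sn[a] - sn[i]
        Sp[b] <- Sp[b] + sp[i]; Sn[b] <- Sn[b] + sn[i]
        Kp[, a] <- Kp[, a] - Wp[, i]; Kp[, b] <- Kp[, b] + Wp[, i]
        Kn[, a] <- Kn[, a] - Wn[, i]; Kn[, b] <- Kn[, b] + Wn[, i]
        improved <- TRUE; moved_any <- TRUE
      }
    }
    if (!improved) break
  }
  list(comm = comm, moved_any = moved_any)
}

# One full Louvain pass on a symmetric signed matrix: multi-level node moves
# + aggregation, followed by flat fine-tuning sweeps on the original graph
# (single-node moves from the multi-level solution, which can escape the
# lock-in of aggregated modules). Random visitation order from the ambient RNG.
louvain_once <- function(W, gamma_res, init = NULL) {
  n0 <- nrow(W)
  final <- seq_len(n0)   # assignment of original nodes
  level_W <- W
  first <- TRUE
  repeat {
    n <- nrow(level_W)
    start <- if (first && !is.null(init)) init else seq_len(n)
    first <- FALSE
    mp <- move_phase(level_W, gamma_res, start)
    comm <- match(mp$comm, sort(unique(mp$comm)))
    final <- comm[final]
    if (!mp$moved_any || max(comm) == n) break
    # aggregate rows then columns by community (comm is contiguous 1..K)
    A <- rowsum(level_W, comm, reorder = TRUE)
    level_W <- unname(t(rowsum(t(A), comm, reorder = TRUE)))
    if (nrow(level_W) == 1L) break
  }
  repeat {
    ft <- move_phase(W, gamma_res, final)
    final <- match(ft$comm, sort(unique(ft$comm)))
    if (!ft$moved_any) break
  }
  final
}

#' Louvain maximisation of signed modularity
#'
#' Greedy two-phase Louvain (local node moves until no single-node move
#' improves Q, then module aggregation, repeated) on the signed quality
#' function, with a configurable number of random-restart sweeps from which
#' the best-Q partition is kept. Node visitation order is randomised from
#' `seed`, making the run fully reproducible.
#'
#' @param W symmetric signed weight matrix.
#' @param gamma_res resolution parameter.
#' @param seed integer seed (NULL uses the ambient RNG).
#' @param n_restarts independent restarts; the highest-Q result is returned.
#' @return object of class `partition`: `assignments` (1-based contiguous
#'   module ids), `q` (equal to [modularity_signed()] of the assignment),
#'   `gamma_res`, `n_modules`.
#' @export
louvain <- function(W, gamma_res = 1, seed = NULL, n_restarts = 10L) {
  W <- as.matrix(W)
  if (all(W == 0)) stop("modularity is undefined for an all-zero matrix")
  if (max(abs(W - t(W))) > 1e-10 * max(abs(W))) {
    stop("W must be symmetric; symmetrize() layered adjacencies first")
  }
  n <- nrow(W)
  run <- function() {
    best <- NULL; best_q <- -Inf
    for (r in seq_len(n_restarts)) {
      # odd restarts grow from singletons; even restarts start from a random
      # coarse partition, which escapes traps the greedy growth falls into
      init <- if (r %% 2L == 0L && n > 2L) {
        sample.int(sample(2:min(n, 8L), 1L), n, replace = TRUE)
      } else NULL
      a <- louvain_once(W, gamma_res, init = init)
      q <- modularity_signed(W, a, gamma_res)
      if (q > best_q) { best_q <- q; best <- a }
    }
    partition(best, best_q, gamma_res)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

partition <- function(assignments, q, gamma_res) {
  assignments <- match(assignments, sort(unique(assignments)))
  structure(list(assignments = assignments, q = q, gamma_res = gamma_res,
                 n_modules = max(assignments)),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition: %d modules over %d nodes, Q = %.4f (gamma = %g)>\n",
              x$n_modules, length(x$assignments), x$q, x$gamma_res))
  invisible(x)
}

co_assignment <- function(assignments) {
  outer(assignments, assignments, "==") * 1
}

#' Consensus partition over repeated Louvain runs
#'
#' Runs Louvain `n_runs` times with distinct sub-seeds, builds the node x node
#' co-assignment frequency (agreement) matrix, and iteratively re-clusters the
#' agreement matrix thresholded at `tau` until every re-clustering run returns
#' the same partition. If thresholding empties the agreement matrix, the
#' threshold is lowered to the permutation-null expectation of agreement.
#'
#' @param W symmetric signed weight matrix.
#' @param gamma_res resolution parameter for the underlying runs.
#' @param n_runs number of Louvain runs.
#' @param seed master seed; run r uses a derived sub-seed.
#' @param tau agreement threshold in [0, 1).
#' @param max_iter iteration cap for the re-clustering loop.
#' @return object of class `consensus_result`: `consensus_partition`
#'   (a `partition` whose `q` is evaluated on `W`), `agreement`, `n_runs`.
#' @export
consensus_partition <- function(W, gamma_res = 1, n_runs = 50L, seed = 1L,
                                tau = 0.5, max_iter = 50L) {
  stopifnot(n_runs >= 1L)
  runs <- lapply(seq_len(n_runs), function(r) {
    louvain(W, gamma_res, seed = sub_seed(seed, r))$assignments
  })
  agreement <- Reduce(`+`, lapply(runs, co_assignment)) / n_runs
  current <- runs
  iter <- 0L
  while (length(unique(lapply(current, function(a) match(a, unique(a))))) > 1L) {
    iter <- iter + 1L
    if (iter > max_iter) {
      stop("consensus did not converge after ", max_iter, " iterations")
    }
    ag <- Reduce(`+`, lapply(current, co_assignment)) / length(current)
    thr <- tau
    ag_t <- ag; ag_t[ag_t < thr] <- 0; diag(ag_t) <- 0
    if (all(ag_t == 0)) {
      # fall back to the permutation-null expected agreement
      thr <- mean(ag[upper.tri(ag)])
      ag_t <- ag; ag_t[ag_t < thr] <- 0; diag(ag_t) <- 0
    }
    diag(ag_t) <- 1
    current <- lapply(seq_len(n_runs), function(r) {
      louvain(ag_t, 1, seed = sub_seed(seed, 10000L + iter * n_runs + r))$assignments
    })
  }
  cons <- current[[1L]]
  structure(list(
    consensus_partition = partition(cons, modularity_signed(W, cons, gamma_res),
                                    gamma_res),
    agreement = agreement, n_runs = as.integer(n_runs)
  ), class = "consensus_result")
}

#' Resolution-parameter stability sweep
#'
#' For each gamma in `gamma_grid`, Louvain is run `n_runs` times; partition
#' stability is summarised as the mean pairwise Pearson correlation of the
#' runs' vectorised co-assignment matrices (1 when all runs agree), alongside
#' the mean Q. The gamma with the highest mean similarity is flagged as the
#' least-variable resolution.
#'
#' @param W symmetric signed weight matrix.
#' @param gamma_grid resolutions to scan (default 0.5 to 2.5).
#' @param n_runs Louvain runs per gamma.
#' @param seed master seed.
#' @return data.frame(gamma, mean_similarity, mean_q, mean_n_modules) with
#'   attribute `best_gamma`.
#' @export
gamma_sweep <- function(W, gamma_grid = seq(0.5, 2.5, by = 0.25),
                        n_runs = 20L, seed = 1L) {
  stopifnot(length(gamma_grid) >= 1L)
  rows <- lapply(seq_along(gamma_grid), function(gi) {
    g <- gamma_grid[gi]
    parts <- lapply(seq_len(n_runs), function(r) {
      louvain(W, g, seed = sub_seed(seed, gi * 1000L + r))
    })
    vecs <- vapply(parts, function(p) {
      ca <- co_assignment(p$assignments); ca[upper.tri(ca)]
    }, numeric(sum(upper.tri(diag(nrow(W))))))
    sims <- c()
    if (n_runs > 1L) {
      for (a in seq_len(n_runs - 1L)) for (b in (a + 1L):n_runs) {
        va <- vecs[, a]; vb <- vecs[, b]
        sims <- c(sims, if (all(va == vb)) {
          1
        } else if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
          0
        } else stats::cor(va, vb))
      }
    } else sims <- 1
    data.frame(gamma = g, mean_similarity = mean(sims),
               mean_q = mean(vapply(parts, function(p) p$q, 0)),
               mean_n_modules = mean(vapply(parts, function(p) p$n_modules, 0)))
  })
  out <- do.call(rbind, rows)
  attr(out, "best_gamma") <- out$gamma[which.max(out$mean_similarity)]
  out
}
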