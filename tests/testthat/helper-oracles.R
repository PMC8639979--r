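# Independent oracles: brute-force / closed-form implementations kept
# deliberately separate from the package's code paths.

# All set partitions of n elements as restricted-growth strings.
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(a, mx) {
    if (length(a) == n) {
      out[[length(out) + 1L]] <<- a
      return()
    }
    for (v in seq_len(mx + 1L)) rec(c(a, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# Direct double-summation of the signed modularity quality function.
modularity_oracle <- function(W, a, gamma_res = 1) {
  n <- nrow(W)
  Wp <- pmax(W, 0); Wn <- pmax(-W, 0)
  sp <- rowSums(Wp); sn <- rowSums(Wn)
  vp <- sum(sp); vn <- sum(sn)
  qp <- 0; qn <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (a[i] == a[j]) {
      if (vp > 0) qp <- qp + Wp[i, j] - gamma_res * sp[i] * sp[j] / vp
      if (vn > 0) qn <- qn + Wn[i, j] - gamma_res * sn[i] * sn[j] / vn
    }
  }
  (if (vp > 0) qp / vp else 0) - (if (vn > 0) qn / (vp + vn) else 0)
}

# Naive double-loop participation coefficient on the positive part.
pc_oracle <- function(W, a) {
  n <- nrow(W)
  Wp <- pmax(W, 0); diag(Wp) <- 0
  mods <- sort(unique(a))
  vapply(seq_len(n), function(i) {
    k_tot <- 0
    k_s <- numeric(length(mods))
    for (j in seq_len(n)) {
      k_tot <- k_tot + Wp[i, j]
      k_s[match(a[j], mods)] <- k_s[match(a[j], mods)] + Wp[i, j]
    }
    if (k_tot == 0) return(0)
    1 - sum((k_s / k_tot)^2)
  }, 0)
}

# Hand-summed plug-in mutual information of a contingency table, in bits.
mi_table_oracle <- function(tab) {
  p <- tab / sum(tab)
  total <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) {
      total <- total + p[i, j] * log2(p[i, j] / (sum(p[i, ]) * sum(p[, j])))
    }
  }
  total
}

# Steiger's (1980) Z-bar-1* statistic, written out afresh from the published
# formula for comparing r12 against r13 with shared variable 1.
steiger_oracle <- function(r12, r13, r23, n) {
  rm2 <- ((r12 + r13) / 2)^2
  psi <- r23 * (1 - 2 * rm2) - 0.5 * rm2 * (1 - 2 * rm2 - r23^2)
  s <- psi / (1 - rm2)^2
  (atanh(r12) - atanh(r13)) * sqrt(n - 3) / sqrt(2 * (1 - s))
}

# A random symmetric signed test graph.
random_signed_graph <- function(n, p_zero = 0.3, p_neg = 0.4) {
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  m <- sum(ut)
  vals <- ifelse(stats::runif(m) < 1 - p_neg,
                 stats::runif(m, 0.2, 1), -stats::runif(m, 0.2, 1))
  vals[stats::runif(m) < p_zero] <- 0
  W[ut] <- vals
  W + t(W)
}
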