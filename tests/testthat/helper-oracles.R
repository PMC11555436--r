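# Independent brute-force implementations used as oracles. Deliberately
# naive: they re-derive each quantity from first principles and never share
# code with the package internals they check.

# recovery-curve AUC: walk the ranking position by position
oracle_aucell_cell <- function(expr, targets_idx, top_fraction, tiebreak) {
  n <- length(expr)
  N <- floor(top_fraction * n)
  ord <- order(-expr, tiebreak)
  hits <- ord %in% targets_idx
  auc_sum <- 0
  for (k in seq_len(N)) auc_sum <- auc_sum + sum(hits[seq_len(k)])
  auc_sum / (N * min(length(targets_idx), N))
}

# Jensen-Shannon divergence in bits by direct summation
oracle_jsd <- function(p, q) {
  m <- (p + q) / 2
  term <- function(a) {
    out <- 0
    for (i in seq_along(a)) if (a[i] > 0) out <- out + a[i] * log2(a[i] / m[i])
    out
  }
  (term(p) + term(q)) / 2
}

# absorption probabilities by Monte-Carlo trajectory simulation
oracle_mc_absorption <- function(P, absorbing_idx, lineage_of, start,
                                 n_traj = 1e5, max_steps = 1e4) {
  P <- as.matrix(P)
  n <- nrow(P)
  counts <- numeric(max(lineage_of))
  state <- rep(start, n_traj)
  alive <- rep(TRUE, n_traj)
  absorbed_lineage <- integer(n_traj)
  for (step in seq_len(max_steps)) {
    if (!any(alive)) break
    for (s in unique(state[alive])) {
      sel <- alive & state == s
      state[sel] <- sample.int(n, sum(sel), replace = TRUE, prob = P[s, ])
    }
    hit <- alive & state %in% absorbing_idx
    absorbed_lineage[hit] <- lineage_of[match(state[hit], absorbing_idx)]
    alive[hit] <- FALSE
  }
  tabulate(absorbed_lineage, nbins = max(lineage_of)) / n_traj
}

# neighbour-mean smoothing by explicit loops
oracle_knn_average <- function(X, nn) {
  out <- X * 0
  for (i in seq_len(nrow(X)))
    out[i, ] <- colMeans(X[c(i, nn[i, ]), , drop = FALSE])
  out
}

# standardized-variance HVG ranking, independent binning implementation
oracle_hvg_rank <- function(lognorm_dense, gene_ids, n_bins = 20L) {
  mu <- apply(lognorm_dense, 1, mean)
  v <- apply(lognorm_dense, 1, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  # equal-frequency bins; ties in mean broken by original order
  r <- rank(mu, ties.method = "first")
  bin <- ceiling(r / length(mu) * n_bins)
  z <- numeric(length(mu))
  for (b in unique(bin)) {
    idx <- which(bin == b)
    s <- stats::sd(disp[idx])
    z[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - mean(disp[idx])) / s
  }
  z[v == 0] <- -Inf
  z <- round(z, 9)
  gene_ids[order(-z, gene_ids)]
}

# dense row-softmax velocity transition row
oracle_softmax_row <- function(v, ms_self, ms_neighbors, scale) {
  cs <- apply(ms_neighbors, 1, function(msj) {
    d <- msj - ms_self
    nd <- sqrt(sum(d^2)); nv <- sqrt(sum(v^2))
    if (nd == 0 || nv == 0) 0 else sum(d * v) / (nd * nv)
  })
  e <- exp(scale * cs)
  e / sum(e)
}

# adjusted rand index (contingency-table formula)
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp_idx <- si * sj / n
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}
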