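#' QC parameters
#' @param min_genes_per_cell keep cells detecting at least this many genes.
#' @param max_mito_fraction keep cells with mitochondrial fraction at most
#'   this value.
#' @param mito_prefix case-insensitive gene-id prefix marking mitochondrial
#'   genes.
#' @export
qc_params <- function(min_genes_per_cell = 200L, max_mito_fraction = 0.10,
                      mito_prefix = "mt-") {
  if (max_mito_fraction < 0 || max_mito_fraction > 1)
    stop("max_mito_fraction must be in [0, 1]", call. = FALSE)
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 max_mito_fraction = max_mito_fraction,
                 mito_prefix = mito_prefix), class = "QCParams")
}

#' Quality-control filter on cells
#'
#' Retains cells with at least `min_genes_per_cell` detected genes AND a
#' mitochondrial count fraction of at most `max_mito_fraction` (cells
#' detecting fewer genes, or exceeding the mitochondrial fraction, are
#' excluded). Genes are untouched. With no mitochondrial-prefixed genes the
#' fraction is 0 for every cell and only the gene rule applies.
#'
#' @param m CountMatrix with a counts layer.
#' @param q a [qc_params()].
#' @return filtered CountMatrix; removed-cell counts in
#'   `attr(, "qc_removed")`.
#' @export
qc_filter <- function(m, q = qc_params()) {
  counts <- cm_layer(m, "counts")
  detected <- Matrix::colSums(counts > 0)
  mito <- grepl(paste0("^", q$mito_prefix), m$gene_ids, ignore.case = TRUE)
  tot <- Matrix::colSums(counts)
  mfrac <- if (any(mito))
    ifelse(tot > 0, Matrix::colSums(counts[mito, , drop = FALSE]) / tot, 0)
  else rep(0, ncol(counts))
  keep <- detected >= q$min_genes_per_cell & mfrac <= q$max_mito_fraction
  if (!any(keep))
    stop("qc_filter removed every cell (min_genes=", q$min_genes_per_cell,
         ", max_mito=", q$max_mito_fraction, ")", call. = FALSE)
  out <- cm_subset(m, cells = which(keep))
  attr(out, "qc_removed") <- c(low_genes = sum(detected < q$min_genes_per_cell),
                               high_mito = sum(mfrac > q$max_mito_fraction),
                               removed = sum(!keep))
  out
}

#' Log-normalize counts to log1p counts-per-10K
#'
#' Adds a `lognorm` layer: each cell scaled to `scale_factor` total counts,
#' then log1p. Raw counts are retained.
#'
#' @param m CountMatrix with counts layer.
#' @param scale_factor per-cell target total (default 1e4).
#' @export
normalize_log <- function(m, scale_factor = 1e4) {
  counts <- cm_layer(m, "counts")
  tot <- Matrix::colSums(counts)
  if (any(tot == 0))
    stop("zero-count cell found (cells should be QC-filtered first): ",
         m$cell_ids[which(tot == 0)[1]], call. = FALSE)
  ln <- counts %*% Matrix::Diagonal(x = scale_factor / tot)
  ln@x <- log1p(ln@x)
  cm_set_layer(m, "lognorm", ln)
}

#' Select highly variable genes by binned standardized variance
#'
#' Genes are ranked by the within-bin z-score of their dispersion
#' (variance/mean of the lognorm layer): gene means are cut into
#' `n_bins` equal-frequency bins and dispersions standardized within each
#' bin. Ties (and zero-variance genes) break deterministically by gene id.
#'
#' @param m CountMatrix with lognorm layer.
#' @param n number of genes to return.
#' @param n_bins equal-frequency mean bins (default 20).
#' @return character vector of gene ids, ranked.
#' @export
select_hvgs <- function(m, n = 3000L, n_bins = 20L) {
  X <- cm_layer(m, "lognorm")
  if (n > nrow(X)) {
    warning("n = ", n, " exceeds gene count ", nrow(X), "; clamped")
    n <- nrow(X)
  }
  mu <- Matrix::rowMeans(X)
  v <- Matrix::rowMeans(X^2) - mu^2
  v <- v * ncol(X) / max(1, ncol(X) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  # equal-frequency bins over gene means (rank-based, stable in gene id)
  rk <- rank(mu, ties.method = "first")
  bin <- ceiling(rk / length(mu) * n_bins)
  z <- disp
  for (b in unique(bin)) {
    i <- bin == b
    s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  z[v == 0] <- -Inf                      # flat genes rank last
  z <- round(z, 9)                       # stable ordering under fp noise
  ord <- order(-z, m$gene_ids)
  m$gene_ids[ord][seq_len(n)]
}

#' PCA embedding of cells
#'
#' Z-scales the selected genes across cells (clipping at +/- `clip`), then
#' computes principal components by SVD. Component signs follow a fixed
#' convention: the gene loading with largest magnitude is made positive, so
#' results are reproducible across platforms.
#'
#' @param m CountMatrix with lognorm layer.
#' @param hvgs genes to use (default: all).
#' @param n_pcs components (default 20; clamped to the data rank).
#' @param clip absolute z-score clip (default 10).
#' @return cell x PC score matrix with attribute `"loadings"` (gene x PC) and
#'   `"sdev"`.
#' @export
pca_embed <- function(m, hvgs = NULL, n_pcs = 20L, clip = 10) {
  X <- cm_layer(m, "lognorm")
  if (!is.null(hvgs)) {
    hvgs <- intersect(hvgs, m$gene_ids)
    if (!length(hvgs)) stop("no HVGs present in the matrix", call. = FALSE)
    X <- X[hvgs, , drop = FALSE]
  }
  X <- as.matrix(X)
  mu <- rowMeans(X)
  sd <- apply(X, 1, stats::sd)
  keep <- sd > 0
  Z <- (X[keep, , drop = FALSE] - mu[keep]) / sd[keep]
  Z[Z > clip] <- clip
  Z[Z < -clip] <- -clip
  n_pcs <- min(n_pcs, nrow(Z) - 1L, ncol(Z) - 1L)
  sv <- svd(t(Z), nu = n_pcs, nv = n_pcs)   # cells x genes
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  load <- sv$v
  for (k in seq_len(n_pcs)) {              # deterministic sign convention
    j <- which.max(abs(load[, k]))
    if (load[j, k] < 0) {
      load[, k] <- -load[, k]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(scores) <- m$cell_ids
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  rownames(load) <- rownames(Z)
  attr(scores, "loadings") <- load
  attr(scores, "sdev") <- sv$d[seq_len(n_pcs)] / sqrt(max(1, ncol(Z) - 1))
  scores
}

# exact k-nearest neighbours by Euclidean distance (row indices, self excluded)
knn_indices <- function(emb, k) {
  n <- nrow(emb)
  if (k >= n) stop("k = ", k, " must be smaller than the number of cells ", n,
                   call. = FALSE)
  d2 <- as.matrix(stats::dist(emb))^2
  diag(d2) <- Inf
  t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
}

#' Shared-nearest-neighbor modularity clustering
#'
#' Builds a KNN graph on the embedding, weights edges by the Jaccard overlap
#' of the two cells' neighbourhoods (self included), prunes weights below
#' `prune`, and optimises modularity (Louvain) at the given resolution.
#'
#' @param embedding cell x dimension matrix.
#' @param k neighbours (default 20).
#' @param resolution modularity resolution.
#' @param prune Jaccard pruning threshold (default 1/15).
#' @param seed seed controlling the (stochastic) modularity optimisation.
#' @return integer cluster labels named by cell.
#' @export
snn_cluster <- function(embedding, k = 20L, resolution = 0.8,
                        prune = 1 / 15, seed = 7L) {
  nn <- knn_indices(embedding, k)
  n <- nrow(nn)
  # neighbourhood sets include the cell itself (standard SNN convention)
  sets <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
  memb <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k + 1L),
                               j = unlist(sets), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(memb)
  shared <- methods::as(shared, "TsparseMatrix")
  i <- shared@i + 1L; j <- shared@j + 1L; s <- shared@x
  jac <- s / (2 * (k + 1L) - s)
  keep <- jac >= prune & i != j
  g <- igraph::graph_from_data_frame(
    data.frame(from = i[keep], to = j[keep], weight = jac[keep]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  g <- igraph::simplify(g, edge.attr.comb = "max")
  cl <- withr::with_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  lab <- igraph::membership(cl)
  out <- integer(n)
  out[as.integer(igraph::V(g)$name)] <- as.integer(lab)
  names(out) <- rownames(embedding)
  out
}

#' Aggregate same-class cells into pseudo-cells
#'
#' Within each class, cells are randomly permuted (seeded) and partitioned
#' into consecutive groups of `group_size`; each pseudo-cell is the
#' element-wise sum of its members' counts. Leftover cells that do not fill a
#' group are dropped; classes smaller than `group_size` are dropped with a
#' warning. Pseudo-cells inherit species/stage/class tags.
#'
#' @param m CountMatrix with counts layer.
#' @param labels class label per cell (default: `cell_meta$class`).
#' @param group_size cells per pseudo-cell (default 10).
#' @param seed permutation seed.
#' @return list with `matrix` (pseudo-cell CountMatrix) and `membership`
#'   (data.frame pseudo_cell_id, member_cell_ids).
#' @export
make_pseudocells <- function(m, labels = m$cell_meta$class, group_size = 10L,
                             seed = 7L) {
  stopifnot(length(labels) == length(m$cell_ids))
  counts <- cm_layer(m, "counts")
  classes <- sort(unique(labels))
  assign <- withr::with_seed(seed, {
    out <- list()
    for (cl in classes) {
      idx <- which(labels == cl)
      if (length(idx) < group_size) {
        warning("class '", cl, "' has ", length(idx),
                " cells (< group size ", group_size, "); dropped")
        next
      }
      idx <- sample(idx)
      ngrp <- length(idx) %/% group_size
      for (gi in seq_len(ngrp))
        out[[length(out) + 1L]] <-
          list(class = cl, members = idx[(gi - 1L) * group_size + seq_len(group_size)])
    }
    out
  })
  if (!length(assign)) stop("no class had enough cells for pseudo-cells",
                            call. = FALSE)
  G <- Matrix::sparseMatrix(i = unlist(lapply(assign, `[[`, "members")),
                            j = rep(seq_along(assign), each = group_size),
                            x = 1, dims = c(ncol(counts), length(assign)))
  pc <- counts %*% G
  sp <- m$cell_meta$species[vapply(assign, function(a) a$members[1], 1L)]
  st <- m$cell_meta$stage[vapply(assign, function(a) a$members[1], 1L)]
  cls <- vapply(assign, `[[`, "", "class")
  ids <- sprintf("pc_%s_%s_%03d", ifelse(is.na(sp), "na", sp), cls,
                 stats::ave(seq_along(cls), cls, FUN = seq_along))
  pm <- count_matrix(pc, gene_ids = m$gene_ids, cell_ids = ids,
                     cell_meta = data.frame(species = sp, stage = st,
                                            class = cls))
  membership <- data.frame(
    pseudo_cell_id = ids,
    member_cell_ids = vapply(assign, function(a)
      paste(m$cell_ids[a$members], collapse = ","), ""))
  list(matrix = pm, membership = membership)
}

# per-gene ranks and tie terms, computed once per matrix
wilcox_prepare <- function(X) {
  R <- t(apply(X, 1, rank))
  tie_term <- apply(X, 1, function(x) {
    cnt <- rle(sort(x))$lengths
    sum(cnt^3 - cnt)
  })
  list(R = R, tie_term = tie_term, n = ncol(X))
}

# vectorised two-sided Wilcoxon rank-sum (normal approximation, tie
# correction, continuity correction) of every gene, group `in_mask` vs rest
wilcox_rows <- function(prep, in_mask) {
  n <- prep$n
  n1 <- sum(in_mask); n2 <- n - n1
  R1 <- rowSums(prep$R[, in_mask, drop = FALSE])
  mu <- n1 * (n + 1) / 2
  sig2 <- n1 * n2 / 12 * ((n + 1) - prep$tie_term / (n * (n - 1)))
  z <- (abs(R1 - mu) - 0.5) / sqrt(pmax(sig2, 0))
  p <- 2 * stats::pnorm(-pmax(0, z))
  p[sig2 <= 0] <- 1
  pmin(1, p)
}

#' One-vs-rest Wilcoxon differential expression
#'
#' For each class, each gene is tested class-vs-rest with a two-sided
#' Wilcoxon rank-sum (normal approximation with tie and continuity
#' correction). P-values are adjusted across genes within each class
#' (Benjamini-Hochberg by default; Bonferroni available). Rows are kept at
#' `adj_p < alpha`, and with `positive_only` also require the in-class mean
#' (lognorm) to exceed the out-class mean.
#'
#' @param m CountMatrix with lognorm layer.
#' @param labels class label per cell.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param positive_only keep positive markers only (default TRUE).
#' @param adjust `"bh"` or `"bonferroni"`.
#' @param genes optional gene subset to test.
#' @return DEG table: data.frame(gene, class, lfc, p, adj_p, direction).
#' @export
wilcoxon_degs <- function(m, labels = m$cell_meta$class, alpha = 0.05,
                          positive_only = TRUE, adjust = c("bh", "bonferroni"),
                          genes = NULL) {
  adjust <- match.arg(adjust)
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop("wilcoxon_degs needs at least two classes", call. = FALSE)
  X <- cm_layer(m, "lognorm")
  if (!is.null(genes)) X <- X[intersect(genes, m$gene_ids), , drop = FALSE]
  X <- as.matrix(X)
  prep <- wilcox_prepare(X)
  out <- vector("list", length(classes))
  for (ci in seq_along(classes)) {
    mask <- labels == classes[ci]
    p <- wilcox_rows(prep, mask)
    m_in <- rowMeans(X[, mask, drop = FALSE])
    m_out <- rowMeans(X[, !mask, drop = FALSE])
    adj <- stats::p.adjust(p, method = if (adjust == "bh") "BH" else "bonferroni")
    df <- data.frame(gene = rownames(X), class = classes[ci],
                     lfc = m_in - m_out, p = p, adj_p = adj,
                     direction = ifelse(m_in >= m_out, "up", "down"))
    df <- df[df$adj_p < alpha, , drop = FALSE]
    if (positive_only) df <- df[df$direction == "up", , drop = FALSE]
    out[[ci]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$class, res$adj_p, res$gene), ]
}
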