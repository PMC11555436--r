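#' Remove cells with too few unspliced reads
#'
#' Keeps cells whose unspliced fraction `u / (s + u)` is at least `min_frac`.
#' Overall and per-class unspliced proportions of the surviving cells are
#' reported in attributes (`"overall_frac"`, `"class_frac"`).
#'
#' @param spliced,unspliced CountMatrix pair sharing the cell axis.
#' @param min_frac minimum unspliced fraction (default 0.07).
#' @return list(spliced, unspliced) filtered.
#' @export
filter_unspliced_cells <- function(spliced, unspliced, min_frac = 0.07) {
  stopifnot(identical(spliced$cell_ids, unspliced$cell_ids))
  s <- Matrix::colSums(cm_layer(spliced))
  u <- Matrix::colSums(cm_layer(unspliced))
  tot <- s + u
  frac <- ifelse(tot > 0, u / tot, 0)
  keep <- frac >= min_frac
  if (!any(keep))
    stop("unspliced-fraction filter removed every cell (min_frac = ",
         min_frac, ")", call. = FALSE)
  out <- list(spliced = cm_subset(spliced, cells = which(keep)),
              unspliced = cm_subset(unspliced, cells = which(keep)))
  attr(out, "overall_frac") <- sum(u[keep]) / sum(tot[keep])
  cls <- spliced$cell_meta$class[keep]
  attr(out, "class_frac") <- tapply(u[keep], cls, sum) /
    tapply(tot[keep], cls, sum)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Keep genes with sufficient spliced and unspliced counts
#'
#' A gene is retained when both its spliced total and its unspliced total
#' exceed `min_shared` (strictly).
#'
#' @param spliced,unspliced CountMatrix pair.
#' @param min_shared count bound (default 10).
#' @return character vector of retained gene ids.
#' @export
gene_filter_shared_counts <- function(spliced, unspliced, min_shared = 10L) {
  stopifnot(identical(spliced$gene_ids, unspliced$gene_ids))
  s <- Matrix::rowSums(cm_layer(spliced))
  u <- Matrix::rowSums(cm_layer(unspliced))
  spliced$gene_ids[s > min_shared & u > min_shared]
}

#' KNN-smoothed first-order moments of spliced/unspliced abundance
#'
#' Both layers are scaled by a common per-cell size factor (spliced totals
#' over their median, preserving the per-cell unspliced/spliced ratio), a PCA
#' embedding is computed from log1p spliced HVGs, and each cell's moments
#' `Ms`, `Mu` are the mean of its k nearest neighbours (self included) in
#' that embedding.
#'
#' @param spliced,unspliced CountMatrix pair (already cell/gene filtered).
#' @param n_hvgs HVGs for the embedding (default 2000).
#' @param n_pcs embedding dimensions (default 30).
#' @param k neighbours (default 30).
#' @return list(Ms, Mu) cell x gene dense matrices, `graph` (symmetric
#'   sparse connectivity), `nn` (row-wise neighbour index matrix),
#'   `embedding`.
#' @export
knn_moments <- function(spliced, unspliced, n_hvgs = 2000L, n_pcs = 30L,
                        k = 30L) {
  stopifnot(identical(spliced$cell_ids, unspliced$cell_ids),
            identical(spliced$gene_ids, unspliced$gene_ids))
  n <- length(spliced$cell_ids)
  if (k >= n) stop("k = ", k, " must be below the cell count ", n, call. = FALSE)
  S <- cm_layer(spliced)
  U <- cm_layer(unspliced)
  tot <- Matrix::colSums(S)
  if (any(tot == 0)) stop("cell with zero spliced counts", call. = FALSE)
  sf <- tot / stats::median(tot)
  Sn <- S %*% Matrix::Diagonal(x = 1 / sf)
  Un <- U %*% Matrix::Diagonal(x = 1 / sf)
  logm <- Sn
  logm@x <- log1p(logm@x)
  helper <- count_matrix(S, spliced$gene_ids, spliced$cell_ids,
                         spliced$cell_meta)
  helper <- cm_set_layer(helper, "lognorm", logm)
  hvgs <- select_hvgs(helper, min(n_hvgs, length(spliced$gene_ids)))
  emb <- pca_embed(helper, hvgs, n_pcs = n_pcs)
  nn <- knn_indices(emb, k)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k), j = as.vector(t(nn)),
                            x = 1, dims = c(n, n))
  conn <- A + Matrix::t(A)               # symmetric KNN connectivity
  conn <- methods::as(conn, "CsparseMatrix")
  conn@x <- pmin(conn@x, 1)
  W <- A + Matrix::Diagonal(n)           # neighbour average includes self
  W <- Matrix::Diagonal(x = 1 / Matrix::rowSums(W)) %*% W
  Ms <- as.matrix(W %*% Matrix::t(Sn))
  Mu <- as.matrix(W %*% Matrix::t(Un))
  dimnames(Ms) <- dimnames(Mu) <- list(spliced$cell_ids, spliced$gene_ids)
  list(Ms = Ms, Mu = Mu, graph = methods::as(conn, "CsparseMatrix"), nn = nn,
       embedding = emb)
}

#' Steady-state velocity estimation
#'
#' For each gene, cells in the top and bottom `extreme_quantile` of smoothed
#' spliced abundance are assumed near steady state; the degradation/splicing
#' ratio is the least-squares slope through the origin,
#' `gamma = <Mu, Ms> / <Ms, Ms>` over those cells, and velocity is the
#' residual `V = Mu - gamma * Ms` for every cell. Genes with non-positive or
#' undefined slope, or fewer than `min_cells` selected cells, are dropped.
#'
#' @param Ms,Mu cell x gene moment matrices.
#' @param extreme_quantile tail fraction used for the fit (default 0.05).
#' @param min_cells minimum selected cells per gene (default 10).
#' @return VelocityModel: list(gamma named vector, V cell x gene, genes,
#'   Ms, Mu restricted to retained genes).
#' @export
fit_steady_state_gamma <- function(Ms, Mu, extreme_quantile = 0.05,
                                   min_cells = 10L) {
  stopifnot(identical(dim(Ms), dim(Mu)))
  genes <- colnames(Ms)
  gam <- rep(NA_real_, ncol(Ms))
  for (g in seq_len(ncol(Ms))) {
    x <- Ms[, g]; y <- Mu[, g]
    qs <- stats::quantile(x, c(extreme_quantile, 1 - extreme_quantile))
    sel <- x <= qs[1] | x >= qs[2]
    if (sum(sel) < min_cells) next
    ss <- sum(x[sel]^2)
    if (ss == 0) next
    gam[g] <- sum(x[sel] * y[sel]) / ss
  }
  keep <- which(!is.na(gam) & gam > 0)
  if (!length(keep)) stop("no gene yielded a positive steady-state slope",
                          call. = FALSE)
  V <- Mu[, keep, drop = FALSE] -
    sweep(Ms[, keep, drop = FALSE], 2, gam[keep], `*`)
  list(gamma = stats::setNames(gam[keep], genes[keep]),
       V = V, genes = genes[keep],
       Ms = Ms[, keep, drop = FALSE], Mu = Mu[, keep, drop = FALSE])
}

row_softmax_sparse <- function(i_list, p_list, n, ids) {
  Matrix::sparseMatrix(i = rep(seq_len(n), lengths(i_list)),
                       j = unlist(i_list), x = unlist(p_list),
                       dims = c(n, n), dimnames = list(ids, ids))
}

#' Velocity-based transition kernel
#'
#' For cell i and each neighbour j, the displacement
#' `delta_ij = Ms_j - Ms_i` is compared with the velocity vector `V_i` by
#' cosine similarity, and row transition probabilities are
#' `softmax(softmax_scale * cos)` over the neighbours. A zero-velocity cell
#' receives a uniform row over its neighbours.
#'
#' @param model VelocityModel from [fit_steady_state_gamma()].
#' @param nn neighbour index matrix (rows = cells), e.g. from
#'   [knn_moments()].
#' @param softmax_scale inverse temperature (default 4).
#' @return sparse row-stochastic cell x cell matrix supported on the KNN
#'   graph.
#' @export
velocity_kernel <- function(model, nn, softmax_scale = 4.0) {
  Ms <- model$Ms; V <- model$V
  n <- nrow(Ms)
  i_list <- vector("list", n); p_list <- vector("list", n)
  for (i in seq_len(n)) {
    js <- nn[i, ]
    vi <- V[i, ]
    nv <- sqrt(sum(vi^2))
    if (nv == 0) {
      p <- rep(1 / length(js), length(js))
    } else {
      delta <- Ms[js, , drop = FALSE] -
        matrix(Ms[i, ], length(js), ncol(Ms), byrow = TRUE)
      nd <- sqrt(rowSums(delta^2))
      cs <- as.vector(delta %*% vi) / (nv * pmax(nd, .Machine$double.eps))
      cs[nd == 0] <- 0
      e <- exp(softmax_scale * (cs - max(cs)))
      p <- e / sum(e)
    }
    i_list[[i]] <- js; p_list[[i]] <- p
  }
  row_softmax_sparse(i_list, p_list, n, rownames(Ms))
}

#' Row-normalized connectivity kernel
#' @param graph symmetric sparse connectivity (e.g. from [knn_moments()]).
#' @export
connectivity_kernel <- function(graph) {
  rs <- Matrix::rowSums(graph)
  if (any(rs == 0)) stop("connectivity graph has an isolated cell", call. = FALSE)
  out <- Matrix::Diagonal(x = 1 / rs) %*% graph
  dimnames(out) <- dimnames(graph)
  methods::as(out, "CsparseMatrix")
}

#' Convex combination of velocity and similarity kernels
#'
#' `T = (1 - w_sim) * T_vel + w_sim * T_conn`, row-stochastic on the union
#' support.
#'
#' @param T_vel,T_conn row-stochastic kernels with identical cell ordering.
#' @param w_sim similarity weight in [0, 1] (default 0.2).
#' @export
combine_kernels <- function(T_vel, T_conn, w_sim = 0.2) {
  if (w_sim < 0 || w_sim > 1)
    stop("w_sim must lie in [0, 1]", call. = FALSE)
  (1 - w_sim) * T_vel + w_sim * T_conn
}

stationary_mass <- function(T, n_power_iters, tol) {
  n <- nrow(T)
  pi <- rep(1 / n, n)
  Tt <- Matrix::t(T)
  # lazy-chain iteration (T + I)/2: identical stationary vector, but immune
  # to periodic chains on which the plain power iteration oscillates
  for (it in seq_len(n_power_iters)) {
    nxt <- 0.5 * as.vector(Tt %*% pi) + 0.5 * pi
    nxt <- nxt / sum(nxt)
    delta <- max(abs(nxt - pi))
    pi <- nxt
    if (delta < tol) return(pi)
  }
  stop(sprintf("power iteration did not converge in %d steps (residual %.3g)",
               n_power_iters, delta), call. = FALSE)
}

#' Identify terminal and initial states from the transition kernel
#'
#' A stationary-like mass is obtained by power iteration on the transposed
#' kernel; classes whose mean mass exceeds the global mean are terminal, and
#' the top `top_quantile` cells by mass within each terminal class are the
#' terminal cells. The reversed (transposed, row-renormalized) kernel yields
#' the initial mass; the class with the highest mean initial mass is the
#' root, with its top cells as initial cells.
#'
#' @param T row-stochastic transition kernel.
#' @param labels class per cell.
#' @param top_quantile fraction of cells flagged per state (default 0.05).
#' @param n_power_iters,tol power-iteration controls.
#' @return list(terminal = class -> cell indices, initial = cell indices,
#'   root_class, pi, pi_rev).
#' @export
terminal_initial_states <- function(T, labels, top_quantile = 0.05,
                                    n_power_iters = 20000L, tol = 1e-8) {
  pi <- stationary_mass(T, n_power_iters, tol)
  T_rev <- connectivity_kernel(Matrix::t(T))
  pi_rev <- stationary_mass(T_rev, n_power_iters, tol)
  cls_mean <- tapply(pi, labels, mean)
  terminal_classes <- names(cls_mean)[cls_mean > mean(pi)]
  top_cells <- function(mass, idx) {
    ntake <- max(1L, ceiling(top_quantile * length(idx)))
    idx[order(-mass[idx])][seq_len(ntake)]
  }
  terminal <- stats::setNames(lapply(terminal_classes, function(cl)
    top_cells(pi, which(labels == cl))), terminal_classes)
  rev_mean <- tapply(pi_rev, labels, mean)
  root_class <- names(rev_mean)[which.max(rev_mean)]
  initial <- top_cells(pi_rev, which(labels == root_class))
  list(terminal = terminal, initial = initial, root_class = root_class,
       pi = pi, pi_rev = pi_rev)
}

#' Absorption (fate) probabilities toward terminal states
#'
#' Terminal cells are made absorbing; with the transition kernel partitioned
#' into transient-transient `Q` and transient-absorbing `R`, the absorption
#' probabilities solve `(I - Q) B = R`, and absorbing columns are summed per
#' lineage (terminal class).
#'
#' @param T row-stochastic transition kernel.
#' @param terminal named list (lineage -> absorbing cell indices), disjoint.
#' @return FateProbabilities: cell x lineage matrix; terminal cells are
#'   one-hot on their own lineage.
#' @export
absorption_probabilities <- function(T, terminal) {
  stopifnot(length(terminal) >= 1)
  allabs <- unlist(terminal)
  if (anyDuplicated(allabs)) stop("terminal sets must be disjoint", call. = FALSE)
  n <- nrow(T)
  trans <- setdiff(seq_len(n), allabs)
  lineages <- names(terminal)
  B <- matrix(0, n, length(lineages),
              dimnames = list(rownames(T), lineages))
  for (li in seq_along(lineages)) B[terminal[[li]], li] <- 1
  if (length(trans)) {
    Q <- T[trans, trans, drop = FALSE]
    R <- T[trans, allabs, drop = FALSE]
    lin_of <- rep(seq_along(lineages), lengths(terminal))
    Ragg <- vapply(seq_along(lineages), function(li)
      Matrix::rowSums(R[, lin_of == li, drop = FALSE]), numeric(length(trans)))
    Ragg <- matrix(Ragg, nrow = length(trans))
    sol <- tryCatch(
      as.matrix(Matrix::solve(Matrix::Diagonal(length(trans)) - Q, Ragg)),
      error = function(e)
        stop("absorption system is singular; transient cells may be ",
             "disconnected from every terminal state (", conditionMessage(e),
             ")", call. = FALSE))
    rs <- rowSums(sol)
    bad <- !is.finite(rs) | abs(rs - 1) > 1e-6
    if (any(bad)) {
      warning(sum(bad), " transient cell(s) unreachable from terminal states;",
              " uniform fallback")
      sol[bad, ] <- 1 / length(lineages)
    }
    B[trans, ] <- sol
  }
  B
}

#' Diffusion pseudotime from a connectivity graph
#'
#' Builds the symmetrized diffusion operator `D^{-1/2} W D^{-1/2}`, takes its
#' leading eigenvectors, rescales components 2..n_comps by
#' `lambda / (1 - lambda)`, and returns the Euclidean distance of each cell
#' from the root in that space, normalized to [0, 1]. Cells disconnected
#' from the root get NA (warned).
#'
#' @param graph symmetric sparse connectivity.
#' @param root root cell index.
#' @param n_comps diffusion components (default 10).
#' @export
dpt_pseudotime <- function(graph, root, n_comps = 10L) {
  n <- nrow(graph)
  g <- igraph::graph_from_adjacency_matrix(graph > 0, mode = "undirected")
  comp <- igraph::components(g)$membership
  in_comp <- comp == comp[root]
  if (!all(in_comp))
    warning(sum(!in_comp), " cell(s) disconnected from the root; NA assigned")
  W <- graph[in_comp, in_comp, drop = FALSE]
  d <- Matrix::rowSums(W)
  Dm <- Matrix::Diagonal(x = 1 / sqrt(d))
  S <- as.matrix(Dm %*% W %*% Dm)
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  k <- min(n_comps, ncol(eig$vectors))
  lam <- eig$values[2:k]
  lam <- pmin(lam, 1 - 1e-10)
  phi <- as.matrix(Dm %*% eig$vectors[, 2:k, drop = FALSE])
  phi <- sweep(phi, 2, lam / (1 - lam), `*`)
  ridx <- sum(in_comp[seq_len(root)])
  dd <- sqrt(rowSums(sweep(phi, 2, phi[ridx, ], `-`)^2))
  out <- rep(NA_real_, n)
  out[in_comp] <- if (max(dd) > 0) dd / max(dd) else dd
  names(out) <- rownames(graph)
  out
}

#' Rank putative driver genes by correlation with fate probability
#'
#' Per gene, the Pearson correlation between smoothed expression and the
#' lineage's fate probability over all cells not assigned to a terminal
#' state; the `top_n` genes by correlation are retained (zero-variance genes
#' excluded). The median correlation of the retained set is reported in
#' `attr(, "median_correlation")`.
#'
#' @param Ms cell x gene smoothed expression.
#' @param fate FateProbabilities matrix.
#' @param lineage lineage (column of `fate`) to rank against.
#' @param terminal optional named list of terminal cell indices to exclude.
#' @param top_n genes retained (default 100).
#' @return DriverTable: data.frame(gene, lineage, correlation, rank).
#' @export
rank_drivers <- function(Ms, fate, lineage, terminal = NULL, top_n = 100L) {
  stopifnot(lineage %in% colnames(fate))
  use <- setdiff(seq_len(nrow(Ms)), unlist(terminal))
  y <- fate[use, lineage]
  X <- Ms[use, , drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  ok <- sds > 0 & stats::sd(y) > 0
  co <- rep(NA_real_, ncol(X))
  co[ok] <- suppressWarnings(as.vector(stats::cor(X[, ok, drop = FALSE], y)))
  df <- data.frame(gene = colnames(Ms), lineage = lineage, correlation = co)
  df <- df[!is.na(df$correlation), , drop = FALSE]
  df <- df[order(-df$correlation, df$gene), , drop = FALSE]
  df <- utils::head(df, top_n)
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  attr(df, "median_correlation") <- stats::median(df$correlation)
  df
}

#' Fate-weighted smooth expression trend along pseudotime
#'
#' Penalized weighted cubic spline regression (a generalized additive model
#' with `df` basis functions) of expression on pseudotime, each cell weighted
#' by its fate probability; evaluated on a 100-point grid.
#'
#' @param expr expression vector.
#' @param pseudotime pseudotime vector.
#' @param weights per-cell weights (e.g. fate probabilities).
#' @param df spline basis size (default 6).
#' @param n_grid grid points (default 100).
#' @return data.frame(grid_t, value).
#' @export
fit_fate_weighted_trend <- function(expr, pseudotime, weights, df = 6L,
                                    n_grid = 100L) {
  stopifnot(length(expr) == length(pseudotime),
            length(expr) == length(weights))
  if (all(weights == 0)) stop("all weights are zero", call. = FALSE)
  use <- weights > 0
  dat <- data.frame(y = expr[use], t = pseudotime[use], w = weights[use])
  k <- min(df, length(unique(dat$t)) - 1L)
  fit <- mgcv::gam(y ~ s(t, k = max(3L, k)), data = dat, weights = dat$w)
  grid <- seq(min(dat$t), max(dat$t), length.out = n_grid)
  data.frame(grid_t = grid,
             value = as.vector(stats::predict(fit,
                                              newdata = data.frame(t = grid))))
}

#' Intersections of driver genes and regulators across species
#'
#' Computes, per homologous class, the shared putative drivers (intersection
#' of per-species top lists after mapping to the common namespace) and, per
#' species and class, the driver-regulators (top drivers that are also
#' class-specific regulators).
#'
#' @param drivers named list: species -> (class -> character vector of
#'   top driver genes, common namespace).
#' @param regulators named list: species -> (class -> regulator gene ids,
#'   common namespace).
#' @return list(shared = class -> genes, shared_counts = data.frame,
#'   driver_regulators = species -> class -> genes).
#' @export
driver_regulator_intersection <- function(drivers, regulators) {
  species <- names(drivers)
  classes <- Reduce(union, lapply(drivers, names))
  shared <- stats::setNames(lapply(classes, function(cl) {
    sets <- lapply(drivers, function(d) d[[cl]])
    sets <- Filter(Negate(is.null), sets)
    if (length(sets) < 2) character(0) else sort(Reduce(intersect, sets))
  }), classes)
  counts <- data.frame(class = classes,
                       n_shared = vapply(shared, length, 0L))
  dr <- stats::setNames(lapply(species, function(sp) {
    cls <- names(drivers[[sp]])
    stats::setNames(lapply(cls, function(cl)
      sort(intersect(drivers[[sp]][[cl]],
                     if (is.null(regulators[[sp]][[cl]])) character(0)
                     else regulators[[sp]][[cl]]))), cls)
  }), species)
  list(shared = shared, shared_counts = counts, driver_regulators = dr)
}
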