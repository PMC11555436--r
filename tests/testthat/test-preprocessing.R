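make_qc_toy <- function() {
  # 10 cells with controlled detected-gene counts and mito fractions
  set.seed(1)
  n_genes <- 400
  genes <- c(sprintf("mt-%02d", 1:5), sprintf("g%03d", 1:(n_genes - 5)))
  counts <- matrix(0L, n_genes, 10)
  detected <- c(199L, 200L, 250L, 300L, 280L, 260L, 240L, 220L, 210L, 205L)
  mito_frac <- c(0, 0, 0.05, 0.10, 0.11, 0.5, 0, 0.09, 0.2, 0.101)
  for (j in 1:10) {
    picked <- 5 + sample.int(n_genes - 5, detected[j])
    counts[picked, j] <- 10L
    tot_rest <- sum(counts[, j])
    mt <- round(mito_frac[j] * tot_rest / (1 - mito_frac[j]))
    counts[1, j] <- as.integer(mt)    # recount: one mito gene carries it all
  }
  list(m = count_matrix(counts, genes, sprintf("c%02d", 1:10)),
       detected = detected + (counts[1, ] > 0),
       mito_frac = counts[1, ] / colSums(counts))
}

test_that("qc keeps >=200 detected genes and <=10% mito, boundaries included", {
  toy <- make_qc_toy()
  expected_keep <- toy$detected >= 200 & toy$mito_frac <= 0.10
  out <- qc_filter(toy$m)
  expect_setequal(out$cell_ids, toy$m$cell_ids[expected_keep])
  # boundary semantics: 199 detected is excluded, exactly 200 kept
  expect_false("c01" %in% out$cell_ids)
  expect_true(toy$detected[2] >= 200 && "c02" %in% out$cell_ids)
  rem <- attr(out, "qc_removed")
  expect_equal(unname(rem["removed"]), sum(!expected_keep))
})

test_that("qc with no mitochondrial genes applies only the gene rule", {
  set.seed(2)
  counts <- matrix(rpois(100 * 6, 2), 100, 6)
  counts[, 1] <- 0; counts[1:30, 1] <- 1         # 30 detected genes
  m <- count_matrix(counts, sprintf("g%03d", 1:100), sprintf("c%d", 1:6))
  out <- qc_filter(m, qc_params(min_genes_per_cell = 50L))
  expect_false("c1" %in% out$cell_ids)
  expect_equal(length(out$cell_ids), 5L)
})

test_that("qc is idempotent and errors when nothing survives", {
  toy <- make_qc_toy()
  once <- qc_filter(toy$m)
  twice <- qc_filter(once)
  expect_identical(twice$cell_ids, once$cell_ids)
  expect_identical(as.matrix(cm_layer(twice)), as.matrix(cm_layer(once)))
  expect_error(qc_filter(toy$m, qc_params(min_genes_per_cell = 1000L)),
               "every cell")
})

test_that("log-normalization scales to CP10K then log1p, keeping counts", {
  counts <- matrix(c(1, 0, 3, 2, 2, 0), 3, 2)
  m <- count_matrix(counts, c("a", "b", "c"), c("c1", "c2"))
  ln <- normalize_log(m)
  expect_true("counts" %in% names(ln$layers))
  dense <- as.matrix(cm_layer(ln, "lognorm"))
  expect_equal(dense[, 1], log1p(c(1, 0, 3) / 4 * 1e4),
               ignore_attr = TRUE)
  # exp - 1 recovers counts-per-10K exactly
  cp10k <- expm1(dense)
  expect_equal(cp10k[, 2], c(2, 2, 0) / 4 * 1e4, tolerance = 1e-12,
               ignore_attr = TRUE)
  # a cell with a single expressed gene gets log1p(1e4)
  m2 <- count_matrix(matrix(c(7, 0), 2, 1), c("a", "b"), "c1")
  expect_equal(max(cm_layer(normalize_log(m2), "lognorm")), log1p(1e4))
  # zero-count cells are an error
  m3 <- count_matrix(matrix(c(1, 0), 1, 2), "a", c("c1", "c2"))
  expect_error(normalize_log(m3), "zero-count")
})

test_that("HVG selection ranks flat genes last and planted bimodal first", {
  set.seed(3)
  n <- 80
  X <- matrix(rpois(50 * n, 5), 50, n)
  X[1, ] <- 4                                 # identical in all cells
  X[2, ] <- c(rep(0, n / 2), rep(60, n / 2))  # planted bimodal
  m <- count_matrix(X, sprintf("g%03d", 1:50), sprintf("c%03d", 1:n))
  m <- cm_set_layer(m, "lognorm", X)          # test the ranking rule directly
  ranked <- select_hvgs(m, 50)
  expect_equal(ranked[1], "g002")
  expect_equal(ranked[50], "g001")
})

test_that("HVG ranking matches an independent binning oracle", {
  set.seed(4)
  X <- matrix(rnbinom(50 * 40, mu = exp(rnorm(50, 1, 1)), size = 3),
              50, 40)
  m <- as_cm(X)
  ours <- select_hvgs(m, 50)
  oracle <- oracle_hvg_rank(as.matrix(cm_layer(m, "lognorm")), m$gene_ids)
  expect_identical(ours, oracle)
  # clamping warns
  expect_warning(select_hvgs(m, 100), "clamped")
})

test_that("PCA embedding is orthonormal, sign-fixed, and matches SVD", {
  set.seed(5)
  # a strong two-group mean shift dominates PC1
  X <- matrix(rpois(600, 5), 30, 20)
  X[1:15, 1:10] <- X[1:15, 1:10] + 40
  m <- as_cm(X)
  emb <- pca_embed(m, n_pcs = 5)
  sdev <- attr(emb, "sdev")
  expect_gt(sdev[1]^2 / sum(sdev^2), 0.5)
  L <- attr(emb, "loadings")
  expect_equal(crossprod(L), diag(ncol(L)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # sign convention: dominant loading positive
  for (k in seq_len(ncol(L))) expect_gt(L[which.max(abs(L[, k])), k], 0)
  # scores match a direct SVD of the same standardized matrix
  Z <- t(scale(t(as.matrix(cm_layer(m, "lognorm")))))
  Z <- Z[apply(Z, 1, function(r) !anyNA(r)), ]
  Z[Z > 10] <- 10; Z[Z < -10] <- -10
  sv <- svd(t(Z))
  recon_err <- sum((t(Z) - emb %*% t(L))^2)
  best_err <- sum(sv$d[-(1:5)]^2)
  expect_equal(recon_err, best_err, tolerance = 1e-8)

  # rank-1 exact toy: PC1 explains > 99.9%
  X1 <- outer(1:12, seq(2, 4, length.out = 10))
  m1 <- count_matrix(round(X1 * 10), sprintf("g%02d", 1:12),
                     sprintf("c%02d", 1:10))
  m1 <- cm_set_layer(m1, "lognorm", round(X1 * 10))
  e1 <- pca_embed(m1, n_pcs = 3, clip = 1e9)
  s1 <- attr(e1, "sdev")
  expect_gt(s1[1]^2 / sum(s1^2), 0.999)
})

test_that("SNN clustering separates Gaussian blobs and respects resolution", {
  set.seed(6)
  blob <- rbind(matrix(rnorm(60 * 2, 0), ncol = 2),
                matrix(rnorm(60 * 2, 8), ncol = 2))
  rownames(blob) <- sprintf("c%03d", 1:120)
  lab <- snn_cluster(blob, k = 15, resolution = 0.3)
  expect_equal(length(unique(lab)), 2L)
  expect_equal(oracle_ari(lab, rep(1:2, each = 60)), 1)
  # vanishing resolution on connected data collapses to one cluster
  set.seed(7)
  one <- matrix(rnorm(80 * 2), ncol = 2)
  rownames(one) <- sprintf("c%03d", 1:80)
  lab1 <- snn_cluster(one, k = 15, resolution = 1e-4)
  expect_equal(length(unique(lab1)), 1L)
  expect_error(snn_cluster(one, k = 80), "smaller")
})

test_that("pseudo-cells conserve counts, drop leftovers, inherit labels", {
  set.seed(8)
  counts <- matrix(rpois(40 * 45, 3), 40, 45)
  labels <- rep(c("A", "B", "C"), c(20, 25, 0))
  labels <- c(labels, rep("C", 0))
  m <- count_matrix(counts, sprintf("g%02d", 1:40), sprintf("c%02d", 1:45),
                    cell_meta = data.frame(species = "sp1", stage = "s1",
                                           class = labels))
  pc <- make_pseudocells(m, group_size = 10L, seed = 3L)
  expect_equal(sum(pc$matrix$cell_meta$class == "A"), 2L)  # 20 -> 2 groups
  expect_equal(sum(pc$matrix$cell_meta$class == "B"), 2L)  # 25 -> 2, 5 dropped
  # exact count conservation per class: pseudo-cells + dropped = members
  members <- strsplit(pc$membership$member_cell_ids, ",")
  for (i in seq_along(members)) {
    summed <- Matrix::rowSums(cm_layer(m)[, members[[i]], drop = FALSE])
    expect_equal(as.vector(cm_layer(pc$matrix)[, i]), unname(summed))
  }
  used <- unlist(members)
  expect_equal(sum(cm_layer(pc$matrix)),
               sum(cm_layer(m)[, used]))
  expect_equal(length(setdiff(m$cell_ids[labels == "B"],
                              used)), 5L)
  expect_true(all(pc$matrix$cell_meta$species == "sp1"))
})

test_that("a class smaller than the group size is dropped with a warning", {
  counts <- matrix(1L, 5, 12)
  m <- count_matrix(counts, sprintf("g%d", 1:5), sprintf("c%02d", 1:12),
                    cell_meta = data.frame(species = NA, stage = NA,
                                           class = rep(c("A", "B"), c(10, 2))))
  expect_warning(pc <- make_pseudocells(m, group_size = 10L), "dropped")
  expect_equal(unique(pc$matrix$cell_meta$class), "A")
  # ten one-hot cells sum to a vector of ten ones
  onehot <- count_matrix(diag(10), sprintf("g%d", 1:10), sprintf("c%d", 1:10),
                         cell_meta = data.frame(species = NA, stage = NA,
                                                class = "A"))
  suppressWarnings(pc1 <- make_pseudocells(onehot, group_size = 10L))
  expect_equal(as.vector(cm_layer(pc1$matrix)), rep(1, 10))
})

test_that("pseudo-cell grouping is deterministic given the seed", {
  sim <- test_panel()
  m <- sim$matrices$sp1
  a <- make_pseudocells(m, seed = 5L)
  b <- make_pseudocells(m, seed = 5L)
  expect_identical(a$membership, b$membership)
  c <- make_pseudocells(m, seed = 6L)
  expect_false(identical(a$membership, c$membership))
})

test_that("one-vs-rest Wilcoxon flags exclusive genes and not null genes", {
  set.seed(9)
  n <- 100
  X <- matrix(rpois(30 * n, 2), 30, n)
  X[1, ] <- c(rpois(50, 8), rep(0, 50))    # exclusive to class A
  X[2, ] <- rpois(n, 5)                    # identical distribution
  labels <- rep(c("A", "B"), each = 50)
  m <- as_cm(X, classes = labels)
  deg <- wilcoxon_degs(m, labels)
  a <- deg[deg$class == "A", ]
  expect_true("g001" %in% a$gene)
  expect_equal(a$gene[which.min(a$adj_p)], "g001")
  expect_false("g002" %in% deg$gene)
  expect_true(all(deg$adj_p >= deg$p))
  expect_error(wilcoxon_degs(m, rep("A", n)), "two classes")
})

test_that("normal-approximation p-values track the exact distribution", {
  # 8 vs 8, tie-free: compare with the exact permutation null
  set.seed(10)
  for (rep in 1:5) {
    x <- sample(seq_len(100), 16)
    labels <- rep(c("A", "B"), each = 8)
    m <- count_matrix(matrix(x, 1, 16), "g001", sprintf("c%02d", 1:16))
    m <- cm_set_layer(m, "lognorm", matrix(x, 1, 16))
    deg <- wilcoxon_degs(m, labels, alpha = 1.01, positive_only = FALSE)
    p_exact <- stats::wilcox.test(x[1:8], x[9:16], exact = TRUE)$p.value
    p_ours <- deg$p[deg$class == "A"]
    expect_equal(p_ours, p_exact, tolerance = 0.1)
  }
})

test_that("planted DEGs are recovered with few false positives", {
  sim <- test_panel()
  m <- normalize_log(sim$matrices$sp2)
  deg <- wilcoxon_degs(m, alpha = 0.05)
  planted <- sim$truth$conserved_degs
  hits <- 0; total <- 0
  for (cl in names(planted)) {
    genes <- planted[[cl]]$genes$sp2
    hits <- hits + sum(genes %in% deg$gene[deg$class == cl])
    total <- total + length(genes)
  }
  expect_gte(hits / total, 0.9)
  # false positives: background genes flagged anywhere
  bg <- setdiff(m$gene_ids,
                c(unlist(lapply(planted, function(x) x$genes$sp2)),
                  unlist(sim$truth$specific_degs$sp2),
                  grep("og", m$gene_ids, value = TRUE)[1:0]))
  planted_any <- unique(c(unlist(lapply(planted, function(x) x$genes$sp2)),
                          unlist(sim$truth$specific_degs$sp2)))
  regulon_genes <- unlist(lapply(sim$truth$regulons, function(r) {
    map <- sim$ortholog_map
    map$gene[map$species == "sp2" &
               map$cluster_id %in% c(r$regulator_cluster, r$target_clusters)]
  }))
  bg <- setdiff(m$gene_ids, c(planted_any, regulon_genes))
  fp <- mean(bg %in% deg$gene)
  expect_lte(fp, 0.1)
})
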