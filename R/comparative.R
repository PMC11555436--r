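#' Map a count matrix into the shared ortholog namespace
#'
#' Renames genes to their one-to-one ortholog cluster ids; genes without an
#' ortholog are dropped (count recorded in `attr(, "n_unmapped")`). Cells are
#' untouched.
#'
#' @param m CountMatrix.
#' @param map ortholog map data.frame (cluster_id, species, gene).
#' @param species species of `m` (default: unique species tag of its cells).
#' @export
map_to_ortholog_space <- function(m, map, species = NULL) {
  if (is.null(species)) {
    species <- unique(m$cell_meta$species)
    if (length(species) != 1 || is.na(species))
      stop("species of the matrix is ambiguous; pass `species`", call. = FALSE)
  }
  sub <- map[map$species == species, , drop = FALSE]
  hit <- match(m$gene_ids, sub$gene)
  keep <- which(!is.na(hit))
  if (!length(keep))
    stop("no gene of species '", species, "' is covered by the ortholog map",
         call. = FALSE)
  out <- cm_subset(m, genes = keep)
  new_ids <- sub$cluster_id[hit[keep]]
  out$gene_ids <- new_ids
  out$layers <- lapply(out$layers, function(L) {
    rownames(L) <- new_ids
    L
  })
  attr(out, "n_unmapped") <- length(m$gene_ids) - length(keep)
  out
}

#' Column-concatenate ortholog-space matrices from several species
#'
#' Restricts to the intersection of gene sets (canonically sorted), prefixes
#' duplicated cell ids with the species tag, and records species in
#' `cell_meta`.
#'
#' @param matrices named list of ortholog-space CountMatrix objects (names =
#'   species, used when `cell_meta$species` is absent).
#' @export
integrate_panels <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  genes <- sort(Reduce(intersect, lapply(matrices, `[[`, "gene_ids")))
  if (!length(genes)) stop("no shared genes across panels", call. = FALSE)
  tags <- names(matrices)
  if (is.null(tags)) tags <- paste0("study", seq_along(matrices))
  matrices <- lapply(seq_along(matrices), function(i) {
    m <- cm_subset(matrices[[i]], genes = genes)
    if (all(is.na(m$cell_meta$species))) m$cell_meta$species <- tags[i]
    m
  })
  all_ids <- unlist(lapply(matrices, `[[`, "cell_ids"))
  if (anyDuplicated(all_ids))
    matrices <- lapply(matrices, function(m) {
      ids <- paste(m$cell_meta$species, m$cell_ids, sep = ":")
      m$cell_ids <- ids
      m$layers <- lapply(m$layers, function(L) { colnames(L) <- ids; L })
      rownames(m$cell_meta) <- ids
      m
    })
  tagsets <- Reduce(intersect, lapply(matrices, function(m) names(m$layers)))
  primary <- matrices[[1]]$layer_tag
  vals <- do.call(cbind, lapply(matrices, cm_layer, tag = tagsets[1]))
  out <- count_matrix(vals,
                      gene_ids = genes,
                      cell_ids = unlist(lapply(matrices, `[[`, "cell_ids")),
                      cell_meta = do.call(rbind, lapply(matrices, `[[`, "cell_meta")),
                      layer_tag = if (tagsets[1] %in% c("counts", "spliced", "unspliced"))
                        tagsets[1] else "counts")
  for (tg in tagsets)
    out <- cm_set_layer(out, tg, do.call(cbind, lapply(matrices, cm_layer, tag = tg)))
  out$layer_tag <- primary
  out
}

#' Cross-study highly variable genes for neighbor voting
#'
#' Keeps genes whose within-study variance quantile (among detected genes)
#' falls in the top decile in every study; the decile threshold is relaxed in
#' 0.1 steps until at least `min_n` genes qualify.
#'
#' @param matrices list of ortholog-space CountMatrix objects with a lognorm
#'   layer (one per study).
#' @param min_n minimum returned gene count (default 200).
#' @export
metaneighbor_hvgs <- function(matrices, min_n = 200L) {
  genes <- Reduce(intersect, lapply(matrices, `[[`, "gene_ids"))
  if (!length(genes)) stop("no common genes across studies", call. = FALSE)
  qmat <- vapply(matrices, function(m) {
    X <- cm_layer(m, "lognorm")[genes, , drop = FALSE]
    mu <- Matrix::rowMeans(X)
    v <- Matrix::rowMeans(X^2) - mu^2
    detected <- Matrix::rowSums(X > 0) > 0
    q <- rep(NA_real_, length(genes))
    q[detected] <- rank(v[detected], ties.method = "average") / sum(detected)
    q
  }, numeric(length(genes)))
  thr <- 0.9
  repeat {
    ok <- rowSums(qmat > thr, na.rm = TRUE) == ncol(qmat) &
      !apply(qmat, 1, anyNA)
    if (sum(ok) >= min_n || thr <= 0.05) break
    thr <- thr - 0.1
  }
  sort(genes[ok])
}

rank_auroc <- function(scores, positive) {
  ok <- !is.na(scores)
  scores <- scores[ok]; positive <- positive[ok]
  n1 <- sum(positive); n2 <- sum(!positive)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Cross-species cell-class replicability AUROC (neighbor voting)
#'
#' Computes cell-cell Spearman correlations on the supplied HVGs,
#' rank-standardizes each cell's incoming correlations to [0,1]
#' (self-correlation excluded), and scores each (study, class) pair against
#' every other: test cells of one study receive votes equal to their mean
#' standardized correlation to the training cells of a candidate class in
#' another study, and the AUROC measures how well those votes separate the
#' true class. Entries are averaged over the two train/test directions.
#'
#' @param joint integrated CountMatrix (lognorm layer used if present).
#' @param study_labels study (species) per cell.
#' @param class_labels class per cell.
#' @param hvgs genes to use.
#' @return square AurocMatrix over `study|class` pairs, values in [0,1]; a
#'   class present in only one study yields NA rows/columns against itself.
#' @export
metaneighbor_us <- function(joint, study_labels = joint$cell_meta$species,
                            class_labels = joint$cell_meta$class, hvgs) {
  studies <- sort(unique(study_labels))
  if (length(studies) < 2) stop("need at least two studies", call. = FALSE)
  hvgs <- intersect(hvgs, joint$gene_ids)
  if (!length(hvgs)) stop("no HVGs present in joint matrix", call. = FALSE)
  tag <- if ("lognorm" %in% names(joint$layers)) "lognorm" else joint$layer_tag
  X <- as.matrix(cm_layer(joint, tag)[hvgs, , drop = FALSE])
  co <- stats::cor(X, method = "spearman")
  diag(co) <- NA
  std <- apply(co, 2, function(col) {
    r <- rank(col, na.last = "keep")
    r / max(r, na.rm = TRUE)
  })
  pairs <- unique(data.frame(study = study_labels, class = class_labels))
  pairs <- pairs[order(pairs$study, pairs$class), ]
  key <- paste(pairs$study, pairs$class, sep = "|")
  np <- nrow(pairs)
  A <- matrix(NA_real_, np, np, dimnames = list(key, key))
  votes_cache <- list()
  vote_for <- function(s2, c2) {
    k <- paste(s2, c2, sep = "|")
    if (is.null(votes_cache[[k]])) {
      train <- which(study_labels == s2 & class_labels == c2)
      votes_cache[[k]] <<- if (length(train))
        rowMeans(std[, train, drop = FALSE], na.rm = TRUE)
      else rep(NA_real_, nrow(std))
    }
    votes_cache[[k]]
  }
  for (a in seq_len(np)) for (b in seq_len(np)) {
    s1 <- pairs$study[a]; c1 <- pairs$class[a]
    s2 <- pairs$study[b]; c2 <- pairs$class[b]
    if (s1 != s2) {
      test <- study_labels == s1
      A[a, b] <- rank_auroc(vote_for(s2, c2)[test], class_labels[test] == c1)
    } else {
      others <- setdiff(studies, s1)
      vals <- vapply(others, function(s3) {
        test <- study_labels == s1
        rank_auroc(vote_for(s3, c2)[test], class_labels[test] == c1)
      }, 0)
      A[a, b] <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    }
  }
  (A + t(A)) / 2
}

#' Unsupervised clustering of integrated pseudo-cells
#'
#' PCA embedding on the supplied HVGs followed by SNN modularity clustering
#' at low resolution, plus the class-by-cluster row-normalized proportion
#' table.
#'
#' @param joint integrated pseudo-cell CountMatrix with lognorm layer.
#' @param hvgs genes for the embedding (default: computed from `joint`).
#' @param resolution modularity resolution (default 0.01).
#' @param n_pcs,k embedding and graph parameters.
#' @param seed seed.
#' @return list(labels, proportions) — proportions rows are classes and sum
#'   to 1.
#' @export
cluster_pseudocells <- function(joint, hvgs = NULL, resolution = 0.01,
                                n_pcs = 20L, k = 20L, seed = 7L) {
  if (is.null(hvgs)) hvgs <- select_hvgs(joint, min(2000L, nrow(joint)[1]))
  emb <- pca_embed(joint, hvgs, n_pcs = n_pcs)
  labels <- snn_cluster(emb, k = k, resolution = resolution, seed = seed)
  cls <- joint$cell_meta$class
  tab <- table(class = cls, cluster = labels)
  prop <- sweep(tab, 1, rowSums(tab), `/`)
  list(labels = labels, proportions = as.matrix(prop))
}

#' Filter orthogroups by species coverage and copy number
#'
#' Keeps orthogroups that contain at least one gene in every required species
#' and whose per-species copy count stays below `max_copies` (strictly, by
#' default) in each required species.
#'
#' @param t orthogroup table (orthogroup_id, species, gene).
#' @param species_required character vector of species that must be present.
#' @param max_copies copy-count bound (default 5).
#' @param strict_less require copies < max_copies (default) rather than <=.
#' @return the subset of input rows belonging to retained orthogroups.
#' @export
filter_orthogroups <- function(t, species_required, max_copies = 5L,
                               strict_less = TRUE) {
  stopifnot(nrow(t) > 0)
  cnt <- table(t$orthogroup_id, t$species)
  sp <- intersect(species_required, colnames(cnt))
  if (length(sp) < length(species_required)) {
    keep_ids <- character(0)
  } else {
    sub <- cnt[, sp, drop = FALSE]
    ok_presence <- rowSums(sub >= 1) == length(sp)
    ok_copies <- if (strict_less) rowSums(sub >= max_copies) == 0
    else rowSums(sub > max_copies) == 0
    keep_ids <- rownames(cnt)[ok_presence & ok_copies]
  }
  if (!length(keep_ids)) warning("no orthogroup passed the filter")
  out <- t[t$orthogroup_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Conserved differentially expressed genes per class
#'
#' The ortholog-DEG set of a class is the intersection, over the ingroup
#' species, of that class's per-species DEGs mapped to ortholog clusters
#' (`min_species` relaxes "every species" to a minimum count). A pseudo-cell
#' DEG is then retained if it is an ortholog-DEG of the same class or a
#' cross-study HVG.
#'
#' @param pseudo_degs DEG table from the integrated pseudo-cell matrix
#'   (gene ids are ortholog cluster ids).
#' @param per_species_degs named list (species -> DEG table in that species'
#'   own gene namespace).
#' @param map ortholog map data.frame.
#' @param hvgs character vector of HVG cluster ids (may be empty).
#' @param min_species number of species a mapped DEG must appear in
#'   (default: all).
#' @return list with `conserved` (class -> cluster ids), `ortholog_degs`
#'   (class -> cluster ids) and `table` (pseudo-DEG rows retained, ranked by
#'   adj_p within class).
#' @export
conserved_degs <- function(pseudo_degs, per_species_degs, map, hvgs = character(0),
                           min_species = Inf) {
  species <- names(per_species_degs)
  n_req <- min(min_species, length(species))
  classes <- sort(unique(pseudo_degs$class))
  lut <- lapply(species, function(s) {
    sub <- map[map$species == s, ]
    stats::setNames(sub$cluster_id, sub$gene)
  })
  names(lut) <- species
  ortho <- lapply(classes, function(cl) {
    per <- lapply(species, function(s) {
      d <- per_species_degs[[s]]
      g <- d$gene[d$class == cl]
      unique(stats::na.omit(unname(lut[[s]][g])))
    })
    if (any(vapply(per, length, 0L) == 0) && n_req >= length(species))
      warning("class '", cl, "' has no DEGs in some species; ",
              "ortholog-DEG set empty")
    cnt <- table(unlist(per))
    names(cnt)[cnt >= n_req]
  })
  names(ortho) <- classes
  cons <- lapply(classes, function(cl) {
    pd <- pseudo_degs$gene[pseudo_degs$class == cl]
    pd[pd %in% ortho[[cl]] | pd %in% hvgs]
  })
  names(cons) <- classes
  tab <- pseudo_degs[mapply(function(g, cl) g %in% cons[[cl]],
                            pseudo_degs$gene, pseudo_degs$class), , drop = FALSE]
  tab <- tab[order(tab$class, tab$adj_p, tab$gene), ]
  rownames(tab) <- NULL
  list(conserved = cons, ortholog_degs = ortho, table = tab)
}

#' Orthogroup-mediated DEG overlap with an outgroup
#'
#' A (class, celltype) pair accrues one unit per orthogroup that contains at
#' least one ingroup DEG of the class and at least one outgroup DEG of the
#' celltype; contributing gene pairs are listed (Sankey-ready long table).
#'
#' @param ingroup_degs named list (class -> ingroup gene ids, in the
#'   namespaces used by the orthogroup table's ingroup rows).
#' @param outgroup_degs named list (celltype -> outgroup gene ids).
#' @param groups filtered orthogroup table.
#' @param outgroup_species species tag of the outgroup rows.
#' @return data.frame(class, celltype, n_shared_orthogroups, gene_pairs).
#' @export
outgroup_deg_overlap <- function(ingroup_degs, outgroup_degs, groups,
                                 outgroup_species = "outgroup") {
  ing <- groups[groups$species != outgroup_species, , drop = FALSE]
  out <- groups[groups$species == outgroup_species, , drop = FALSE]
  res <- list()
  for (cl in names(ingroup_degs)) for (ty in names(outgroup_degs)) {
    gi <- ing[ing$gene %in% ingroup_degs[[cl]], , drop = FALSE]
    go <- out[out$gene %in% outgroup_degs[[ty]], , drop = FALSE]
    shared <- intersect(unique(gi$orthogroup_id), unique(go$orthogroup_id))
    pairs <- if (length(shared)) {
      vapply(shared, function(og) {
        a <- unique(gi$gene[gi$orthogroup_id == og])
        b <- unique(go$gene[go$orthogroup_id == og])
        paste(apply(expand.grid(a, b), 1, paste, collapse = "~"),
              collapse = ";")
      }, "")
    } else character(0)
    res[[length(res) + 1L]] <- data.frame(
      class = cl, celltype = ty, n_shared_orthogroups = length(shared),
      gene_pairs = paste(pairs, collapse = ";"))
  }
  do.call(rbind, res)
}
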