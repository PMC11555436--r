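#' Score regulon activity per cell (area under the recovery curve)
#'
#' For each cell, genes are ranked by expression in decreasing order; ties
#' are broken by a random gene permutation drawn once per run from `seed`, so
#' zero-inflated profiles do not bias target placement. With threshold
#' `N = floor(top_fraction * n_genes)` and recovery curve
#' `R(k) = #targets among the top k`, the activity is
#' `AUC = sum_{k=1..N} R(k) / (N * min(|targets|, N))`. The attainable
#' maximum is `1 - (m - 1) / (2N)` with `m = min(|targets|, N)` (targets
#' cannot all sit at rank 1 simultaneously), reached when the targets occupy
#' the first `m` ranks.
#'
#' @param m CountMatrix (lognorm layer used if present).
#' @param regulons RegulonSet; targets absent from the gene universe are
#'   dropped with a warning, and a regulon left with fewer than `min_targets`
#'   targets is skipped.
#' @param top_fraction fraction of the ranking examined (default 0.05).
#' @param seed tie-break permutation seed.
#' @param min_targets minimum surviving target count (default 8).
#' @return ActivityMatrix: regulon x cell matrix of AUC scores in [0, 1].
#' @export
aucell_score <- function(m, regulons, top_fraction = 0.05, seed = 7L,
                         min_targets = 8L) {
  tag <- if ("lognorm" %in% names(m$layers)) "lognorm" else m$layer_tag
  X <- as.matrix(cm_layer(m, tag))
  n_genes <- nrow(X)
  N <- floor(top_fraction * n_genes)
  if (N < 1) stop("top_fraction too small: no genes in the top set", call. = FALSE)
  tiebreak <- withr::with_seed(seed, sample.int(n_genes))
  entries <- list()
  tidx <- list()
  for (e in regulons$entries) {
    present <- intersect(e$targets, m$gene_ids)
    if (length(present) < length(e$targets))
      warning(sprintf("regulon '%s': %d target(s) absent from the matrix",
                      e$name, length(e$targets) - length(present)))
    if (length(present) < min_targets) {
      warning(sprintf("regulon '%s' reduced below %d targets; skipped",
                      e$name, min_targets))
      next
    }
    entries[[length(entries) + 1L]] <- e
    tidx[[length(tidx) + 1L]] <- match(present, m$gene_ids)
  }
  if (!length(entries)) stop("no regulon survived target filtering", call. = FALSE)
  act <- matrix(0, length(entries), ncol(X),
                dimnames = list(vapply(entries, `[[`, "", "name"), m$cell_ids))
  denom <- vapply(tidx, function(ti) N * min(length(ti), N), 0)
  for (j in seq_len(ncol(X))) {
    ord <- order(-X[, j], tiebreak)
    pos <- integer(n_genes)
    pos[ord] <- seq_len(n_genes)
    for (ri in seq_along(tidx)) {
      r <- pos[tidx[[ri]]]
      act[ri, j] <- sum(pmax(0, N - r + 1L)) / denom[ri]
    }
  }
  act
}

# Jensen-Shannon divergence in bits between probability vectors (0 log 0 = 0)
jsd_bits <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  min(1, max(0, (kl(p, m) + kl(q, m)) / 2))   # clamp fp noise at the ends
}

#' Regulon specificity scores
#'
#' For regulon R and class C, `RSS = 1 - sqrt(JSD(p, q))` where p is the
#' regulon's activity vector normalized to sum 1, q the class indicator
#' normalized to sum 1, and JSD the Jensen-Shannon divergence in bits. An
#' all-zero activity vector falls back to the uniform distribution (warned).
#'
#' @param act ActivityMatrix (regulon x cell).
#' @param labels class per cell.
#' @return RssTable: data.frame(regulon, class, rss, rank) with rank within
#'   class by decreasing rss.
#' @export
regulon_specificity <- function(act, labels) {
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least two classes", call. = FALSE)
  n <- ncol(act)
  qs <- lapply(classes, function(cl) {
    q <- as.numeric(labels == cl)
    q / sum(q)
  })
  res <- list()
  for (ri in seq_len(nrow(act))) {
    a <- act[ri, ]
    if (sum(a) == 0) {
      warning("regulon '", rownames(act)[ri],
              "' has all-zero activity; using uniform distribution")
      p <- rep(1 / n, n)
    } else p <- a / sum(a)
    for (ci in seq_along(classes))
      res[[length(res) + 1L]] <- data.frame(
        regulon = rownames(act)[ri], class = classes[ci],
        rss = 1 - sqrt(jsd_bits(p, qs[[ci]])))
  }
  out <- do.call(rbind, res)
  out$rank <- stats::ave(-out$rss, out$class, FUN = rank)
  out[order(out$class, out$rank), ]
}

#' Filter regulons by class specificity and regulator expression
#'
#' Per class, takes the `top_k` regulons by RSS, then keeps those whose
#' regulator gene is a positive one-vs-rest Wilcoxon marker of that class
#' (BH-adjusted p < `alpha`). A regulon may be assigned to several classes if
#' it passes in each.
#'
#' @param rss RssTable from [regulon_specificity()].
#' @param regulons RegulonSet scored.
#' @param m CountMatrix with lognorm layer (regulator expression).
#' @param labels class per cell.
#' @param top_k regulons examined per class (default 20).
#' @param alpha adjusted-p threshold on the regulator test (default 0.01).
#' @return list with `assignment` (data.frame regulon, class, rss) and
#'   `regulons` (RegulonSet of retained regulons).
#' @export
filter_regulons <- function(rss, regulons, m, labels, top_k = 20L,
                            alpha = 0.01) {
  regs <- stats::setNames(regulons$entries,
                          vapply(regulons$entries, `[[`, "", "name"))
  regulator_of <- vapply(regs, `[[`, "", "regulator")
  test_genes <- intersect(unique(regulator_of), m$gene_ids)
  deg <- if (length(test_genes))
    wilcoxon_degs(m, labels, alpha = alpha, positive_only = TRUE,
                  genes = test_genes)
  else data.frame(gene = character(0), class = character(0))
  keep <- list()
  for (cl in sort(unique(rss$class))) {
    sub <- rss[rss$class == cl, ]
    sub <- sub[order(-sub$rss, sub$regulon), ]
    sub <- utils::head(sub, top_k)
    ok <- vapply(sub$regulon, function(rn)
      regulator_of[[rn]] %in% deg$gene[deg$class == cl], TRUE)
    if (any(ok))
      keep[[cl]] <- data.frame(regulon = sub$regulon[ok], class = cl,
                               rss = sub$rss[ok])
  }
  assignment <- if (length(keep)) do.call(rbind, keep)
  else data.frame(regulon = character(0), class = character(0),
                  rss = numeric(0))
  rownames(assignment) <- NULL
  kept <- unique(assignment$regulon)
  list(assignment = assignment,
       regulons = regulon_set(unname(regs[kept])))
}

#' Transfer a regulon to another species through the ortholog map
#'
#' Regulator and targets are renamed to their one-to-one orthologs in
#' `target_species`; unmapped targets are dropped and counted. Transfer fails
#' if the regulator has no ortholog or fewer than `min_targets` targets
#' survive.
#'
#' @param r a [regulon()].
#' @param map ortholog map data.frame.
#' @param source_species,target_species species tags.
#' @param min_targets minimum surviving target count (default 8).
#' @export
transfer_regulon <- function(r, map, source_species, target_species,
                             min_targets = 8L) {
  src <- map[map$species == source_species, ]
  dst <- map[map$species == target_species, ]
  lut <- stats::setNames(dst$gene[match(src$cluster_id, dst$cluster_id)],
                         src$gene)
  reg <- lut[r$regulator]
  if (is.na(reg))
    stop("regulator '", r$regulator, "' has no ortholog in ", target_species,
         call. = FALSE)
  tg <- stats::na.omit(unname(lut[r$targets]))
  n_dropped <- length(r$targets) - length(tg)
  if (length(tg) < min_targets)
    stop(sprintf("regulon '%s': only %d of %d targets map to %s (minimum %d)",
                 r$name, length(tg), length(r$targets), target_species,
                 min_targets), call. = FALSE)
  out <- regulon(regulator = unname(reg), targets = tg, min_targets = min_targets)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Transfer a whole RegulonSet (untransferable regulons dropped, warned)
#' @inheritParams transfer_regulon
#' @param rs RegulonSet.
#' @export
transfer_regulon_set <- function(rs, map, source_species, target_species,
                                 min_targets = 8L) {
  out <- list()
  names_map <- character(0)
  for (e in rs$entries) {
    tr <- tryCatch(transfer_regulon(e, map, source_species, target_species,
                                    min_targets),
                   error = function(err) {
                     warning("regulon '", e$name, "' not transferable: ",
                             conditionMessage(err))
                     NULL
                   })
    if (!is.null(tr)) {
      if (tr$name %in% names(names_map))   # regulator shared across regulons
        tr$name <- sprintf("%s #%d", tr$name, length(out) + 1L)
      names_map[tr$name] <- e$name
      out[[length(out) + 1L]] <- tr
    }
  }
  if (!length(out)) stop("no regulon transferable to ", target_species,
                         call. = FALSE)
  rs2 <- regulon_set(out)
  attr(rs2, "source_names") <- names_map
  rs2
}

#' Cross-species regulon conservation
#'
#' Each class-assigned regulon is transferred to every foreign species and
#' scored there with [aucell_score()]; its activity is z-scaled across all
#' cells of that species, averaged within the homologous class (the "mean
#' scaled activity"), and tested one-sided (class > rest) by Wilcoxon
#' rank-sum with BH adjustment across regulons. A regulon is flagged
#' conserved when its mean scaled activity reaches `threshold` in every
#' foreign species.
#'
#' @param regulons RegulonSet in the source species' namespace.
#' @param assignment data.frame(regulon, class) mapping each regulon to its
#'   class (shared class vocabulary across species).
#' @param map ortholog map.
#' @param source_species source species tag.
#' @param foreign named list: species -> CountMatrix (lognorm layer; class
#'   labels in `cell_meta$class`).
#' @param threshold mean scaled activity threshold (default 1.6).
#' @param top_fraction,seed passed to [aucell_score()].
#' @return ConservationReport: data.frame(regulon, source_species,
#'   target_species, class, mean_scaled_activity, wilcoxon_adj_p, conserved).
#' @export
conservation_score <- function(regulons, assignment, map, source_species,
                               foreign, threshold = 1.6, top_fraction = 0.05,
                               seed = 7L) {
  rows <- list()
  for (sp in names(foreign)) {
    m <- foreign[[sp]]
    labels <- m$cell_meta$class
    tr <- transfer_regulon_set(regulons, map, source_species, sp)
    src_of <- attr(tr, "source_names")
    act <- aucell_score(m, tr, top_fraction = top_fraction, seed = seed)
    z <- t(scale(t(act)))               # z across all cells of this species
    z[is.nan(z)] <- 0
    for (k in seq_len(nrow(assignment))) {
      src_name <- assignment$regulon[k]
      tr_name <- names(src_of)[match(src_name, src_of)]
      cl <- assignment$class[k]
      if (is.na(tr_name) || !tr_name %in% rownames(act) ||
          !cl %in% labels) {
        rows[[length(rows) + 1L]] <- data.frame(
          regulon = src_name, source_species = source_species,
          target_species = sp, class = cl,
          mean_scaled_activity = NA_real_, wilcoxon_p = NA_real_)
        next
      }
      in_cls <- labels == cl
      msa <- mean(z[tr_name, in_cls])
      p <- stats::wilcox.test(act[tr_name, in_cls], act[tr_name, !in_cls],
                              alternative = "greater", exact = FALSE)$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        regulon = src_name, source_species = source_species,
        target_species = sp, class = cl,
        mean_scaled_activity = msa, wilcoxon_p = p)
    }
  }
  rep <- do.call(rbind, rows)
  rep$wilcoxon_adj_p <- NA_real_
  for (sp in names(foreign)) {
    i <- rep$target_species == sp
    rep$wilcoxon_adj_p[i] <- stats::p.adjust(rep$wilcoxon_p[i], method = "BH")
  }
  key <- paste(rep$regulon, rep$class, sep = "\r")
  flag <- tapply(rep$mean_scaled_activity, key, function(v)
    all(!is.na(v)) && all(v >= threshold))
  rep$conserved <- as.logical(flag[key])
  rownames(rep) <- NULL
  rep
}
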