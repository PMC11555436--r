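#' Specification of a synthetic multi-species expression panel
#'
#' Describes the generated study: several ingroup species sharing homologous
#' cell classes with conserved class-specific expression programs, planted
#' regulator/target co-expression modules (some conserved, some
#' species-specific), planted class-specific DEGs with partial one-to-one
#' ortholog coverage, and an outgroup species linked to the ingroup only
#' through orthogroups.
#'
#' @param n_species number of ingroup species.
#' @param n_classes shared homologous cell classes.
#' @param cells_per_class cells simulated per class per species.
#' @param n_genes genes per ingroup species.
#' @param ortholog_fraction fraction of genes covered by the one-to-one
#'   ortholog map (the remainder are species-private).
#' @param n_conserved_degs planted conserved DEGs per class (on orthologous
#'   genes, same class shift in every ingroup species).
#' @param n_specific_degs planted species-specific DEGs per class per species
#'   (on private genes).
#' @param n_regulons_per_class planted regulons per class; half are flagged
#'   conserved (active in every ingroup species), the rest are active in the
#'   reference species only.
#' @param regulon_size targets per planted regulon.
#' @param deg_fold mean fold-change of a planted DEG in its class.
#' @param regulon_boost median fold applied to target means by the shared
#'   per-cell latent activity in active cells.
#' @param regulon_sdlog lognormal sd of the latent activity.
#' @param base_shape,base_scale gamma parameters of background baseline means.
#' @param planted_shape,planted_scale gamma parameters of baseline means for
#'   planted (DEG/regulator/target) genes.
#' @param libsize_sdlog lognormal sd of per-cell library-size factors.
#' @param theta negative-binomial size (inverse overdispersion); counts have
#'   variance mu + mu^2/theta.
#' @param outgroup include the orthogroup-linked outgroup species.
#' @param n_outgroup_genes,n_outgroup_types,outgroup_cells_per_type,n_outgroup_degs
#'   outgroup panel dimensions.
#' @param seed integer seed; the full bundle is a deterministic function of it.
#' @export
panel_spec <- function(n_species = 3L, n_classes = 7L, cells_per_class = 300L,
                       n_genes = 1500L, ortholog_fraction = 0.7,
                       n_conserved_degs = 30L, n_specific_degs = 10L,
                       n_regulons_per_class = 2L, regulon_size = 15L,
                       deg_fold = 4, regulon_boost = 4, regulon_sdlog = 0.3,
                       base_shape = 0.4, base_scale = 1.25,
                       planted_shape = 2, planted_scale = 0.75,
                       libsize_sdlog = 0.3, theta = 5,
                       outgroup = TRUE, n_outgroup_genes = 800L,
                       n_outgroup_types = 5L, outgroup_cells_per_type = 150L,
                       n_outgroup_degs = 20L, seed = 7L) {
  sp <- as.list(environment())
  if (any(unlist(sp[c("n_species", "n_classes", "cells_per_class", "n_genes")]) <= 0))
    stop("panel dimensions must be positive", call. = FALSE)
  if (sp$ortholog_fraction <= 0 || sp$ortholog_fraction > 1)
    stop("ortholog_fraction must be in (0, 1]", call. = FALSE)
  n_ortho <- floor(sp$ortholog_fraction * sp$n_genes)
  need <- sp$n_classes * (sp$n_conserved_degs +
                          sp$n_regulons_per_class * (sp$regulon_size + 1L))
  if (need > n_ortho)
    stop(sprintf("infeasible spec: %d planted orthologous genes needed but only %d ortholog clusters",
                 need, n_ortho), call. = FALSE)
  if (sp$n_classes * sp$n_specific_degs > sp$n_genes - n_ortho)
    stop("infeasible spec: more species-specific DEGs than private genes",
         call. = FALSE)
  structure(sp, class = "PanelSpec")
}

ingroup_species <- function(spec) paste0("sp", seq_len(spec$n_species))
panel_classes <- function(spec) paste0("class", seq_len(spec$n_classes))

# deterministic layout of planted structure over ortholog cluster indices
panel_layout <- function(spec) {
  n_ortho <- floor(spec$ortholog_fraction * spec$n_genes)
  classes <- panel_classes(spec)
  idx <- 0L
  take <- function(n) { out <- idx + seq_len(n); idx <<- idx + n; out }
  deg_clusters <- stats::setNames(lapply(classes, function(cl)
    take(spec$n_conserved_degs)), classes)
  n_cons <- ceiling(spec$n_regulons_per_class / 2)
  n_spec <- spec$n_regulons_per_class - n_cons
  regs <- list()
  for (cl in classes) {
    for (r in seq_len(n_cons))
      regs[[length(regs) + 1L]] <- list(class = cl, conserved = TRUE,
                                        regulator = take(1L),
                                        targets = take(spec$regulon_size))
    for (r in seq_len(n_spec))
      regs[[length(regs) + 1L]] <- list(class = cl, conserved = FALSE,
                                        regulator = take(1L),
                                        targets = take(spec$regulon_size))
  }
  spec_deg_private <- stats::setNames(lapply(seq_along(classes), function(i)
    (i - 1L) * spec$n_specific_degs + seq_len(spec$n_specific_degs)), classes)
  list(n_ortho = n_ortho, deg_clusters = deg_clusters, regulons = regs,
       spec_deg_private = spec_deg_private, n_planted_clusters = idx)
}

#' Simulate the multi-species expression panel
#'
#' Generates per-species raw count matrices with planted class structure, the
#' one-to-one ortholog map over ingroup species, an orthogroup table that also
#' covers the outgroup, and a `TruthBundle` recording everything planted.
#'
#' Counts are negative binomial around `baseline * class fold * latent regulon
#' activity * library size`. Conserved DEGs and regulons live on orthologous
#' genes with the same class assignment in every ingroup species, so
#' homologous classes correlate across species; species-specific DEGs live on
#' private genes; species-specific regulons are active in the reference
#' species only. The outgroup has its own gene namespace and cell types, two
#' of which share planted-DEG orthogroups with the first two ingroup classes.
#'
#' @param spec a [panel_spec()].
#' @return list with `matrices` (named list of [count_matrix()], one per
#'   species including `"outgroup"`), `ortholog_map`, `orthogroups`
#'   (data.frames) and `truth` (TruthBundle list).
#' @export
simulate_panel <- function(spec = panel_spec()) {
  stopifnot(inherits(spec, "PanelSpec"))
  withr::with_seed(spec$seed, simulate_panel_impl(spec))
}

simulate_panel_impl <- function(spec) {
  lay <- panel_layout(spec)
  species <- ingroup_species(spec)
  classes <- panel_classes(spec)
  n_ortho <- lay$n_ortho
  n_priv <- spec$n_genes - n_ortho
  cluster_ids <- sprintf("OC%04d", seq_len(n_ortho))

  gene_ids <- stats::setNames(lapply(species, function(s)
    c(sprintf("%s_og%04d", s, seq_len(n_ortho)),
      sprintf("%s_pg%04d", s, seq_len(n_priv)))), species)

  ortholog_map <- do.call(rbind, lapply(species, function(s)
    data.frame(cluster_id = cluster_ids, species = s,
               gene = gene_ids[[s]][seq_len(n_ortho)])))

  # baseline means shared across species on ortholog clusters (conservation),
  # drawn independently for private genes
  planted_clusters <- seq_len(lay$n_planted_clusters)
  base_ortho <- stats::rgamma(n_ortho, shape = spec$base_shape,
                              scale = spec$base_scale)
  base_ortho[planted_clusters] <- stats::rgamma(length(planted_clusters),
                                                shape = spec$planted_shape,
                                                scale = spec$planted_scale)
  # per-class fold matrix on ortholog clusters (same in all ingroup species)
  fold_ortho <- matrix(1, n_ortho, spec$n_classes,
                       dimnames = list(NULL, classes))
  for (cl in classes)
    fold_ortho[lay$deg_clusters[[cl]], cl] <- spec$deg_fold
  for (rg in lay$regulons) {
    if (rg$conserved) fold_ortho[rg$regulator, rg$class] <- spec$deg_fold
    base_ortho[rg$targets] <- stats::rgamma(length(rg$targets),
                                            shape = spec$planted_shape,
                                            scale = spec$planted_scale)
  }

  truth_degs <- lapply(classes, function(cl) list(
    clusters = cluster_ids[lay$deg_clusters[[cl]]],
    genes = stats::setNames(lapply(species, function(s)
      gene_ids[[s]][lay$deg_clusters[[cl]]]), species)))
  names(truth_degs) <- classes

  matrices <- list()
  truth_spec_degs <- list()
  labels <- rep(classes, each = spec$cells_per_class)
  n_cells <- length(labels)
  for (si in seq_along(species)) {
    s <- species[si]
    base_priv <- stats::rgamma(n_priv, shape = spec$base_shape,
                               scale = spec$base_scale)
    fold_priv <- matrix(1, n_priv, spec$n_classes,
                        dimnames = list(NULL, classes))
    for (cl in classes) {
      pid <- lay$spec_deg_private[[cl]]
      base_priv[pid] <- stats::rgamma(length(pid), shape = spec$planted_shape,
                                      scale = spec$planted_scale)
      fold_priv[pid, cl] <- spec$deg_fold
    }
    truth_spec_degs[[s]] <- stats::setNames(lapply(classes, function(cl)
      gene_ids[[s]][n_ortho + lay$spec_deg_private[[cl]]]), classes)

    base <- c(base_ortho, base_priv)
    fold <- rbind(fold_ortho, fold_priv)
    # regulator of a species-specific regulon is boosted in its class in the
    # reference species only
    if (si == 1L)
      for (rg in lay$regulons)
        if (!rg$conserved) fold[rg$regulator, rg$class] <- spec$deg_fold

    mu <- base * fold[, labels]                       # genes x cells
    # shared latent regulon activity multiplying target means
    for (rg in lay$regulons) {
      if (!rg$conserved && si != 1L) next
      on <- labels == rg$class
      act <- stats::rlnorm(sum(on), meanlog = log(spec$regulon_boost),
                           sdlog = spec$regulon_sdlog)
      mu[rg$targets, on] <- mu[rg$targets, on, drop = FALSE] *
        rep(act, each = length(rg$targets))
    }
    lib <- stats::rlnorm(n_cells, meanlog = 0, sdlog = spec$libsize_sdlog)
    mu <- sweep(mu, 2, lib, `*`)
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = spec$theta),
                     nrow = spec$n_genes)
    cm <- count_matrix(counts, gene_ids = gene_ids[[s]],
                       cell_ids = sprintf("%s_c%05d", s, seq_len(n_cells)),
                       cell_meta = data.frame(species = s, stage = "s1",
                                              class = labels))
    matrices[[s]] <- cm
  }

  truth_regulons <- lapply(seq_along(lay$regulons), function(i) {
    rg <- lay$regulons[[i]]
    list(name = sprintf("%s (%d)", cluster_ids[rg$regulator], length(rg$targets)),
         class = rg$class, conserved = rg$conserved,
         regulator_cluster = cluster_ids[rg$regulator],
         target_clusters = cluster_ids[rg$targets])
  })

  og <- if (isTRUE(spec$outgroup)) simulate_outgroup(spec, lay, cluster_ids,
                                                     ortholog_map, gene_ids)
  else list(matrix = NULL,
            orthogroups = ingroup_orthogroups(cluster_ids, ortholog_map),
            linked = NULL, degs = NULL)

  if (!is.null(og$matrix)) matrices[["outgroup"]] <- og$matrix

  truth <- list(spec = spec,
                classes = stats::setNames(lapply(matrices, function(m)
                  m$cell_meta$class), names(matrices)),
                conserved_degs = truth_degs,
                specific_degs = truth_spec_degs,
                regulons = truth_regulons,
                outgroup_links = og$linked,
                outgroup_degs = og$degs)
  list(matrices = matrices, ortholog_map = ortholog_map,
       orthogroups = og$orthogroups, truth = truth)
}

ingroup_orthogroups <- function(cluster_ids, ortholog_map) {
  data.frame(orthogroup_id = sub("^OC", "OG", ortholog_map$cluster_id),
             species = ortholog_map$species, gene = ortholog_map$gene)
}

# outgroup species: own namespace and cell types; linked to the ingroup only
# through orthogroups, two types sharing planted-DEG orthogroups with the
# first two ingroup classes
simulate_outgroup <- function(spec, lay, cluster_ids, ortholog_map, gene_ids) {
  n_og_genes <- spec$n_outgroup_genes
  types <- paste0("outclass", seq_len(spec$n_outgroup_types))
  og_genes <- sprintf("out_g%04d", seq_len(n_og_genes))
  ogrp <- ingroup_orthogroups(cluster_ids, ortholog_map)
  classes <- panel_classes(spec)

  # planted outgroup DEGs: first n_outgroup_degs genes per type
  deg_idx <- stats::setNames(lapply(seq_along(types), function(i)
    (i - 1L) * spec$n_outgroup_degs + seq_len(spec$n_outgroup_degs)), types)
  linked <- data.frame(outgroup_type = types[1:2],
                       ingroup_class = classes[1:2])
  assigned <- rep(NA_character_, n_og_genes)          # orthogroup per og gene
  used <- integer(0)
  for (i in 1:2) {
    cl <- classes[i]
    k <- min(spec$n_outgroup_degs, spec$n_conserved_degs)
    cls <- lay$deg_clusters[[cl]][seq_len(k)]
    assigned[deg_idx[[types[i]]][seq_len(k)]] <- sub("^OC", "OG", cluster_ids[cls])
    used <- c(used, cls)
  }
  # remaining DEGs of non-linked types and half the background genes go to
  # background orthogroups (never planted-DEG clusters of linked classes)
  bg_clusters <- setdiff(seq_along(cluster_ids), unlist(lay$deg_clusters))
  pool <- which(is.na(assigned))
  pool <- pool[seq_len(floor(length(pool) * 0.5))]
  assigned[pool] <- sub("^OC", "OG",
                        cluster_ids[sample(bg_clusters, length(pool),
                                           replace = FALSE)])
  add <- !is.na(assigned)
  ogrp <- rbind(ogrp, data.frame(orthogroup_id = assigned[add],
                                 species = "outgroup", gene = og_genes[add]))

  # copy-number structure: extra within-species copies on some background
  # groups, a few groups pushed to >= max_copies, and groups missing species
  bg_og <- sub("^OC", "OG", cluster_ids[sample(bg_clusters, 80)])
  extra <- do.call(rbind, lapply(seq_len(60), function(i) {
    sp <- sample(ingroup_species(spec), 1)
    data.frame(orthogroup_id = bg_og[i], species = sp,
               gene = sprintf("%s_dup%03d", sp, i))
  }))
  heavy <- do.call(rbind, lapply(61:80, function(i) {
    sp <- sample(ingroup_species(spec), 1)
    data.frame(orthogroup_id = rep(bg_og[i], 5), species = sp,
               gene = sprintf("%s_amp%03d_%d", sp, i, 1:5))
  }))
  partial <- do.call(rbind, lapply(seq_len(30), function(i) {
    sp <- sample(ingroup_species(spec), 2)
    data.frame(orthogroup_id = sprintf("OGX%03d", i), species = sp,
               gene = sprintf("%s_px%03d", sp, i))
  }))
  ogrp <- rbind(ogrp, extra, heavy, partial)
  ogrp <- ogrp[order(ogrp$orthogroup_id, ogrp$species, ogrp$gene), ]
  rownames(ogrp) <- NULL

  base <- stats::rgamma(n_og_genes, shape = spec$base_shape,
                        scale = spec$base_scale)
  base[unlist(deg_idx)] <- stats::rgamma(length(unlist(deg_idx)),
                                         shape = spec$planted_shape,
                                         scale = spec$planted_scale)
  fold <- matrix(1, n_og_genes, length(types), dimnames = list(NULL, types))
  for (ty in types) fold[deg_idx[[ty]], ty] <- spec$deg_fold
  labels <- rep(types, each = spec$outgroup_cells_per_type)
  mu <- base * fold[, labels]
  lib <- stats::rlnorm(length(labels), 0, spec$libsize_sdlog)
  mu <- sweep(mu, 2, lib, `*`)
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = spec$theta), nrow = n_og_genes)
  cm <- count_matrix(counts, gene_ids = og_genes,
                     cell_ids = sprintf("out_c%05d", seq_along(labels)),
                     cell_meta = data.frame(species = "outgroup", stage = "s1",
                                            class = labels))
  list(matrix = cm, orthogroups = ogrp, linked = linked,
       degs = stats::setNames(lapply(types, function(ty) og_genes[deg_idx[[ty]]]),
                              types))
}

#' Build the planted RegulonSet in one species' gene namespace
#'
#' Convenience accessor over the TruthBundle: returns every planted regulon
#' (conserved regulons for any ingroup species; species-specific regulons only
#' for the reference species) with regulator/targets named in `species`.
#'
#' @param sim result of [simulate_panel()].
#' @param species ingroup species id.
#' @param conserved_only drop species-specific regulons.
#' @export
planted_regulon_set <- function(sim, species, conserved_only = FALSE) {
  map <- sim$ortholog_map[sim$ortholog_map$species == species, ]
  lut <- stats::setNames(map$gene, map$cluster_id)
  ref <- ingroup_species(sim$truth$spec)[1]
  entries <- list()
  for (rg in sim$truth$regulons) {
    if (conserved_only && !rg$conserved) next
    if (!rg$conserved && species != ref) next
    entries[[length(entries) + 1L]] <-
      regulon(regulator = unname(lut[rg$regulator_cluster]),
              targets = unname(lut[rg$target_clusters]))
  }
  regulon_set(entries)
}

#' Generate decoy regulons of random genes
#'
#' Decoys have no planted co-expression and serve as the null set for the
#' conservation analysis.
#'
#' @param sim result of [simulate_panel()].
#' @param species species namespace for the decoys.
#' @param n number of decoys.
#' @param size targets per decoy.
#' @param seed seed.
#' @export
decoy_regulons <- function(sim, species, n = 50L, size = 15L, seed = 1L) {
  genes <- sim$matrices[[species]]$gene_ids
  map <- sim$ortholog_map[sim$ortholog_map$species == species, ]
  pool <- intersect(genes, map$gene)      # orthologous so they can transfer
  withr::with_seed(seed, {
    regulators <- sample(pool, n)       # distinct regulators, as for real TFs
    entries <- lapply(seq_len(n), function(i) {
      regulon(regulator = regulators[i],
              targets = sample(setdiff(pool, regulators[i]), size),
              name = sprintf("decoy%03d (%d)", i, size))
    })
    regulon_set(entries)
  })
}
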