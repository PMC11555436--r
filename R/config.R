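#' Default pipeline configuration
#'
#' Collects every tunable numeric parameter of every stage, the random seed
#' and optional file paths. Round-trips losslessly through YAML via
#' [write_config()] / [read_config()].
#'
#' @param ... named overrides of the defaults.
#' @return a named list of class `PipelineConfig`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 7L,
    panel = list(),        # overrides of panel_spec() defaults
    kinetics = list(),     # overrides of kinetic_spec() defaults
    qc = list(min_genes_per_cell = 200L, max_mito_fraction = 0.10,
              mito_prefix = "mt-"),
    normalize = list(scale_factor = 1e4),
    hvg = list(n_hvgs = 3000L, n_bins = 20L),
    pca = list(n_pcs = 20L, clip = 10),
    cluster = list(k = 20L, resolution = 0.8, prune = 1 / 15),
    pseudocell = list(group_size = 10L),
    deg = list(alpha = 0.05, positive_only = TRUE, p_adjust = "bh"),
    metaneighbor = list(min_hvgs = 200L),
    pseudocell_cluster = list(resolution = 0.01),
    orthogroups = list(max_copies = 5L, strict_less = TRUE),
    conserved_degs = list(min_species = Inf, hvg_mode = "pseudocell"),
    aucell = list(top_fraction = 0.05),
    regulon_filter = list(top_k = 20L, alpha = 0.01),
    conservation = list(threshold = 1.6, scale_basis = "cells"),
    velocity = list(min_unspliced_frac = 0.07, min_shared = 10L,
                    n_hvgs = 2000L, n_pcs = 30L, k = 30L,
                    extreme_quantile = 0.05, softmax_scale = 4.0,
                    w_sim = 0.2),
    fate = list(top_quantile = 0.05, n_power_iters = 20000L, tol = 1e-8),
    dpt = list(n_comps = 10L),
    drivers = list(top_n = 100L),
    trend = list(df = 6L),
    paths = list()
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "PipelineConfig")
}

#' @rdname pipeline_config
#' @param cfg a PipelineConfig.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  base <- unclass(pipeline_config())
  for (nm in names(raw)) {
    if (is.list(raw[[nm]]) && is.list(base[[nm]]))
      base[[nm]][names(raw[[nm]])] <- raw[[nm]]
    else base[[nm]] <- raw[[nm]]
  }
  structure(base, class = "PipelineConfig")
}
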