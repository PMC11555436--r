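#' Specification of a synthetic spliced/unspliced kinetic panel
#'
#' Cells differentiate from a shared progenitor trunk into `n_lineages`
#' terminal classes along pseudotime t in [0,1]. Each gene follows the
#' two-state transcription model du/dt = alpha(t) - beta*u,
#' ds/dt = beta*u - gamma*s with piecewise-constant transcription rate
#' alpha(t); lineage genes switch on along exactly one lineage and driver
#' genes additionally ramp alpha monotonically. Counts are Poisson samples of
#' `count_scale * (u, s)`.
#'
#' @param n_lineages terminal lineages.
#' @param cells_per_lineage cells per lineage (pseudotime uniform on [0,1]).
#' @param n_hk housekeeping genes held at steady state.
#' @param n_lineage_genes genes switching on per lineage (drivers included).
#' @param n_drivers driver genes per lineage (monotone alpha ramp).
#' @param beta splicing rate (per unit pseudotime).
#' @param gamma degradation rate; gamma/beta is the steady-state u/s slope.
#' @param alpha_low,alpha_high off/on transcription rates of lineage genes.
#' @param alpha_driver plateau rate of driver ramps.
#' @param hk_alpha_shape,hk_alpha_scale gamma distribution of housekeeping
#'   transcription rates.
#' @param count_scale expected counts per unit molecular abundance.
#' @param trunk_t pseudotime below which cells are labelled progenitor.
#' @param onset_range uniform range of lineage-gene onset times.
#' @param n_stages pseudo-stage bins recorded in cell metadata.
#' @param seed integer seed.
#' @export
kinetic_spec <- function(n_lineages = 3L, cells_per_lineage = 250L,
                         n_hk = 300L, n_lineage_genes = 110L, n_drivers = 10L,
                         beta = 8, gamma = 4, alpha_low = 0.3, alpha_high = 3,
                         alpha_driver = 4, hk_alpha_shape = 2,
                         hk_alpha_scale = 0.5, count_scale = 30,
                         trunk_t = 0.35, onset_range = c(0.2, 0.7),
                         n_stages = 4L, seed = 7L) {
  sp <- as.list(environment())
  if (sp$beta <= 0 || sp$gamma <= 0 || sp$alpha_low <= 0 || sp$alpha_high <= 0)
    stop("kinetic rates must be positive", call. = FALSE)
  if (sp$n_drivers > sp$n_lineage_genes)
    stop("more drivers than lineage genes", call. = FALSE)
  structure(sp, class = "KineticSpec")
}

#' Closed-form two-state splicing kinetics
#'
#' Propagates (u, s) through du/dt = alpha - beta*u, ds/dt = beta*u - gamma*s
#' with piecewise-constant alpha, exactly (no numerical integration).
#'
#' @param breaks segment start times (first must be 0), increasing.
#' @param alphas transcription rate per segment (same length as `breaks`).
#' @param beta,gamma splicing and degradation rates (> 0).
#' @param t times at which to evaluate (>= 0).
#' @param u0,s0 state at t = 0.
#' @return data.frame with columns `t`, `u`, `s`.
#' @export
kinetics_solution <- function(breaks, alphas, beta, gamma, t, u0 = 0, s0 = 0) {
  stopifnot(length(breaks) == length(alphas), breaks[1] == 0,
            !is.unsorted(breaks), beta > 0, gamma > 0)
  step <- function(u, s, alpha, tau) {
    eb <- exp(-beta * tau); eg <- exp(-gamma * tau)
    u1 <- alpha / beta + (u - alpha / beta) * eb
    if (abs(beta - gamma) > 1e-12) {
      C1 <- beta * (u - alpha / beta) / (gamma - beta)
      C2 <- s - alpha / gamma - C1
      s1 <- alpha / gamma + C1 * eb + C2 * eg
    } else {
      s1 <- alpha / gamma + (s - alpha / gamma) * eg +
        beta * (u - alpha / beta) * tau * eg
    }
    c(u1, s1)
  }
  at <- function(tt) {
    u <- u0; s <- s0; t0 <- 0
    for (k in seq_along(breaks)) {
      t1 <- if (k < length(breaks)) min(breaks[k + 1], tt) else tt
      if (t1 > t0) {
        st <- step(u, s, alphas[k], t1 - t0)
        u <- st[1]; s <- st[2]; t0 <- t1
      }
      if (t0 >= tt) break
    }
    c(u, s)
  }
  out <- t(vapply(t, at, numeric(2)))
  data.frame(t = t, u = out[, 1], s = out[, 2])
}

#' Simulate spliced/unspliced kinetics along a lineage tree
#'
#' @param spec a [kinetic_spec()].
#' @param noise `"poisson"` (default) or `"none"` (exact deterministic means,
#'   useful for validating the closed form).
#' @return list with `spliced` and `unspliced` [count_matrix()] objects
#'   (shared cell axis; class/stage in `cell_meta`), `pseudotime` (true t per
#'   cell), and `truth` (lineage per cell, driver gene lists, rates).
#' @export
simulate_kinetics <- function(spec = kinetic_spec(), noise = c("poisson", "none")) {
  stopifnot(inherits(spec, "KineticSpec"))
  noise <- match.arg(noise)
  withr::with_seed(spec$seed, simulate_kinetics_impl(spec, noise))
}

simulate_kinetics_impl <- function(spec, noise) {
  lineages <- paste0("terminal", seq_len(spec$n_lineages))
  n_cells <- spec$n_lineages * spec$cells_per_lineage
  lineage <- rep(lineages, each = spec$cells_per_lineage)
  t <- stats::runif(n_cells)
  class <- ifelse(t < spec$trunk_t, "progenitor", lineage)
  stage <- paste0("stage", as.integer(cut(t, breaks = seq(0, 1,
                                          length.out = spec$n_stages + 1),
                                          include.lowest = TRUE)))

  hk_alpha <- stats::rgamma(spec$n_hk, shape = spec$hk_alpha_shape,
                            scale = spec$hk_alpha_scale)
  genes <- c(sprintf("hk_g%04d", seq_len(spec$n_hk)),
             unlist(lapply(lineages, function(L)
               sprintf("%s_g%03d", L, seq_len(spec$n_lineage_genes)))))
  n_genes <- length(genes)
  drivers <- stats::setNames(lapply(lineages, function(L)
    sprintf("%s_g%03d", L, seq_len(spec$n_drivers))), lineages)

  onset <- stats::runif(spec$n_lineages * spec$n_lineage_genes,
                        spec$onset_range[1], spec$onset_range[2])
  onset <- matrix(onset, nrow = spec$n_lineage_genes)

  U <- matrix(0, n_genes, n_cells)
  S <- matrix(0, n_genes, n_cells)
  b <- spec$beta; g <- spec$gamma

  # housekeeping genes: steady state at constant alpha for every cell
  U[seq_len(spec$n_hk), ] <- hk_alpha / b
  S[seq_len(spec$n_hk), ] <- hk_alpha / g

  ramp_breaks <- function(t0) t0 + (0:4) * 0.08
  for (li in seq_len(spec$n_lineages)) {
    on_cells <- which(lineage == lineages[li])
    off_cells <- which(lineage != lineages[li])
    for (gi in seq_len(spec$n_lineage_genes)) {
      row <- spec$n_hk + (li - 1L) * spec$n_lineage_genes + gi
      t0 <- onset[gi, li]
      is_driver <- gi <= spec$n_drivers
      if (is_driver) {
        brk <- c(0, ramp_breaks(t0))
        alp <- c(spec$alpha_low,
                 seq(spec$alpha_low, spec$alpha_driver, length.out = 6)[-1])
      } else {
        brk <- c(0, t0)
        alp <- c(spec$alpha_low, spec$alpha_high)
      }
      sol <- kinetics_solution(brk, alp, b, g, t[on_cells],
                               u0 = spec$alpha_low / b, s0 = spec$alpha_low / g)
      U[row, on_cells] <- sol$u
      S[row, on_cells] <- sol$s
      U[row, off_cells] <- spec$alpha_low / b
      S[row, off_cells] <- spec$alpha_low / g
    }
  }

  mu_u <- spec$count_scale * U
  mu_s <- spec$count_scale * S
  if (noise == "poisson") {
    cu <- matrix(stats::rpois(length(mu_u), as.vector(mu_u)), n_genes)
    cs <- matrix(stats::rpois(length(mu_s), as.vector(mu_s)), n_genes)
  } else {
    cu <- round(mu_u); cs <- round(mu_s)
  }
  cell_ids <- sprintf("kc%05d", seq_len(n_cells))
  meta <- data.frame(species = "sim", stage = stage, class = class,
                     lineage = lineage)
  spl <- count_matrix(cs, gene_ids = genes, cell_ids = cell_ids,
                      cell_meta = meta, layer_tag = "spliced")
  uns <- count_matrix(cu, gene_ids = genes, cell_ids = cell_ids,
                      cell_meta = meta, layer_tag = "unspliced")
  list(spliced = spl, unspliced = uns, pseudotime = t,
       truth = list(spec = spec, lineage = lineage, class = class,
                    stage = stage, drivers = drivers,
                    rates = list(beta = b, gamma = g),
                    mean_u = mu_u, mean_s = mu_s))
}
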