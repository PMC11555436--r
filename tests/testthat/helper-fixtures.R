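# lazily built, session-cached fixtures shared across test files
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# moderate panel for truth-recovery unit tests: 3 species, 7 classes
test_panel <- function() memo("test_panel", function()
  simulate_panel(panel_spec(n_species = 3L, n_classes = 7L,
                            cells_per_class = 60L, n_genes = 600L,
                            n_conserved_degs = 12L, n_specific_degs = 5L,
                            outgroup = TRUE, n_outgroup_genes = 400L,
                            n_outgroup_types = 4L,
                            outgroup_cells_per_type = 60L,
                            n_outgroup_degs = 10L, seed = 11L)))

# full default panel: the study conditions used by the acceptance checks
default_panel <- function() memo("default_panel", function()
  simulate_panel(panel_spec(seed = 7L)))

default_kinetics <- function() memo("default_kinetics", function()
  simulate_kinetics(kinetic_spec(seed = 7L)))

# dense matrix -> CountMatrix with lognorm layer
as_cm <- function(mat, genes = NULL, cells = NULL, classes = NULL,
                  species = NA_character_) {
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(mat)))
  if (is.null(cells)) cells <- sprintf("c%03d", seq_len(ncol(mat)))
  meta <- data.frame(species = species, stage = "s1",
                     class = if (is.null(classes)) NA_character_ else classes)
  normalize_log(count_matrix(mat, genes, cells, meta))
}

# run the velocity->fate pipeline on a kinetics bundle with the defaults
run_fate_pipeline <- function(kin) {
  flt <- filter_unspliced_cells(kin$spliced, kin$unspliced)
  genes <- gene_filter_shared_counts(flt$spliced, flt$unspliced)
  spl <- cm_subset(flt$spliced, genes = genes)
  uns <- cm_subset(flt$unspliced, genes = genes)
  mom <- knn_moments(spl, uns)
  model <- fit_steady_state_gamma(mom$Ms, mom$Mu)
  Tm <- combine_kernels(velocity_kernel(model, mom$nn),
                        connectivity_kernel(mom$graph))
  labels <- spl$cell_meta$class
  states <- terminal_initial_states(Tm, labels)
  fate <- absorption_probabilities(Tm, states$terminal)
  list(spl = spl, uns = uns, mom = mom, model = model, T = Tm,
       labels = labels, states = states, fate = fate,
       t = kin$pseudotime[match(spl$cell_ids, kin$spliced$cell_ids)])
}

default_fate <- function() memo("default_fate", function()
  run_fate_pipeline(default_kinetics()))
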