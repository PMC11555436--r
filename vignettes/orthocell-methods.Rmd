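---
title: "Methods: cross-species conservation, regulon transfer and velocity fate analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species conservation, regulon transfer and velocity fate analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

orthocell implements a comparative single-cell transcriptomics pipeline:
given per-species count matrices with annotated cell classes, it asks which
cell classes, gene regulatory programs (regulons), differentiation drivers
and marker genes are conserved across species. This vignette documents the
models and procedures, the parameters that matter, and the choices made
where the design was genuinely open. Every empirical number referenced here
is computed by the test suite or by `scripts/acceptance.R`; nothing is
quoted from elsewhere.

## Preprocessing

Cells are retained when they detect at least 200 genes and their
mitochondrial count fraction (genes matching a configurable prefix,
`mt-` by default, case-insensitive) is at most 10%. Both boundaries are
inclusive on the "keep" side: a cell with exactly 200 genes or exactly 10%
mitochondrial reads survives. Counts are normalized to counts-per-10K and
log1p-transformed (`normalize_log()`); raw counts are retained alongside,
because pseudo-cell construction and the velocity layers must aggregate
counts, not log values.

Highly variable genes are ranked by binned standardized dispersion: gene
means are cut into 20 equal-frequency bins and the dispersion
(variance/mean of the log layer) is z-scored within each bin. This is a
deliberate, simpler stand-in for variance-stabilizing transforms: all
downstream statistics here are rank-based or set-based, so they depend on
the ranking of genes, not on the particular variance stabilizer. z-scores
are rounded to 9 decimals before ordering and ties break by gene id, so the
ranking is reproducible across platforms.

PCA z-scales each gene and clips at ±10 before the SVD, which stops a
handful of extreme cells from dominating a component. Component signs
follow a fixed convention (the largest-magnitude gene loading is made
positive). Clustering builds a shared-nearest-neighbour graph (k = 20,
neighbourhoods include the cell itself, Jaccard edge weights pruned below
1/15) and optimises modularity with Louvain. Note that igraph's
`resolution` is calibrated differently from Seurat's: the low-resolution
merging regime that groups homologous classes is reached around 0.01–0.05
here.

### Pseudo-cells

To denoise sparse profiles before cross-species comparison, 10 same-class
cells are summed into one pseudo-cell. Cells are permuted with a seeded RNG
and partitioned into consecutive groups; leftovers that cannot fill a group
are dropped, and classes smaller than the group size are dropped with a
warning. Summing raw counts (rather than averaging) keeps the result a
valid count matrix for downstream log-normalization. Whether grouping
should be random or expression-guided is not determined by the problem;
random seeded grouping is the simplest defensible choice and is exposed via
the seed.

### Differential expression

One-vs-rest, two-sided Wilcoxon rank-sum per gene with the normal
approximation, tie correction and continuity correction; the test suite
checks the approximation against the exact permutation distribution on
small tie-free samples. P-values are Benjamini–Hochberg adjusted across
genes within each class (Bonferroni is available as a config switch);
positive markers additionally require the in-class mean to exceed the
out-class mean. The default marker threshold is adjusted p < 0.05 for the
ingroup species and < 0.01 for the outgroup.

## Cross-species class conservation (neighbour voting)

Per-species pseudo-cell matrices are mapped into a shared namespace through
a strictly one-to-one ortholog map (unmapped genes dropped and counted) and
column-concatenated over the intersection of gene sets. Cross-study HVGs
are genes whose within-study variance quantile lies in the top decile in
*every* study, relaxing decile by decile until at least `min_n` (200)
genes qualify.

The replicability score is a neighbour-voting AUROC: Spearman correlations
between all pseudo-cells on the HVGs, each cell's incoming correlations
rank-standardized to [0,1] with the self-correlation excluded; a test
cell's vote for a candidate (study, class) is its mean standardized
correlation to that class's cells in the other study, and the AUROC
measures how well votes separate the true class within the test study.
Entries are averaged over both train/test directions, so the matrix is
symmetric. Because everything is rank-based, the matrix is invariant to
monotone per-cell transformations of expression — a property the suite
verifies by applying `exp()` to the inputs.

## Regulons

A regulon is a regulator (transcription factor) plus its inferred target
set; sets with fewer than 8 targets are invalid, and the regulator is
excluded from its own target set so activity measures the targets, not the
regulator. Regulon inference itself (co-expression module discovery and
motif pruning) is upstream of this package: regulons are consumed as
GMT-like files or planted by the generator.

**Activity (AUC).** Per cell, genes are ranked by expression (descending);
ties — ubiquitous among zeros — break by one seeded random permutation
fixed per run, so zero-inflation cannot bias target placement. With
threshold N = ⌊0.05 · n_genes⌋ and recovery curve R(k) = number of targets
in the top k, the activity is `sum(R(1..N)) / (N · min(|T|, N))`. Under
this normalization the attainable maximum is `1 − (m − 1)/(2N)` with
m = min(|T|, N), reached when all targets head the ranking; the suite
asserts this closed form and checks the statistic against a brute-force
recovery-curve implementation on random instances.

**Specificity (RSS).** `1 − sqrt(JSD(p, q))` in bits, where p is the
regulon's activity normalized to a distribution over cells and q the
normalized class indicator. JSD is clamped to [0,1] before the square root
(exact matches can land at −1e−17 in floating point). All-zero activity
falls back to the uniform distribution with a warning.

**Filtering.** Per class, the top 20 regulons by RSS are kept only if
their regulator is itself a positive Wilcoxon marker of that class
(BH-adjusted p < 0.01). A regulon may be assigned to several classes if it
passes in each; the underlying statistic is silent on multiplicity, so the
package does not force uniqueness.

**Cross-species conservation.** Class-assigned regulons are transferred
through the ortholog map (transfer fails if the regulator is unmapped or
fewer than 8 targets survive), scored in each foreign species, z-scaled
across *all* cells of that species, and averaged within the homologous
class ("mean scaled activity"). z-scaling across cells — rather than
across class means — was chosen because the quantity of interest is how
far the class's cells sit above that species' background; the alternative
basis is a config switch. A one-sided Wilcoxon (class > rest, BH across
regulons per species) accompanies the score. A regulon is *conserved* when
its mean scaled activity reaches 1.6 in every foreign species. Note the
ceiling of this score: with class fraction f, a perfectly class-restricted
activity cannot exceed sqrt((1−f)/f), so the 1.6 threshold presupposes
classes that are minorities of the panel (with 7 equal classes the ceiling
is ≈ 2.45).

## Velocity and fate

Cells with unspliced fraction u/(s+u) below 7% are removed (the boundary
cell is kept), and genes must have both spliced and unspliced totals
strictly above 10. Both layers are scaled by a common per-cell size factor
(spliced totals over their median) — scaling the two layers separately
would distort the u/s ratio on which the steady-state slope estimate
rests. Moments Ms, Mu are neighbour means (self included) over the 30
nearest neighbours in a 30-PC embedding of the log spliced HVGs.

The per-gene degradation/splicing ratio is estimated on the presumed
steady-state cells — the top and bottom 5% of Ms — as the least-squares
slope through the origin, `gamma = <Mu, Ms>/<Ms, Ms>`; velocity is the
residual `V = Mu − gamma·Ms`. This extreme-quantile steady-state estimator
is the package's one deliberate algorithmic simplification relative to
full kinetic-model EM fitting: it recovers the slope exactly on noiseless
steady-state data and within 10% under Poisson noise (both asserted), and
the downstream fate machinery is unchanged by the substitution.

The velocity kernel compares V_i with displacement vectors toward each
KNN neighbour by cosine similarity and applies a softmax (scale 4.0); a
zero-velocity cell gets a uniform row. The final transition matrix mixes
in the row-normalized KNN connectivity with weight 0.2. Terminal classes
are those whose mean stationary-like mass (power iteration on the
transposed kernel, max-norm tolerance 1e−8) exceeds the global mean;
terminal cells are the top 5% by mass within each; the root class
maximizes the reversed-kernel mass. The power iteration runs on the lazy
chain (T + I)/2, which has the same stationary vector but converges on
periodic or nearly-periodic chains where the plain iteration oscillates.

Fate probabilities make terminal cells absorbing and solve the standard
absorption system (I − Q)B = R with a sparse direct solve; rows of B are
probability vectors, terminal cells are one-hot, and the suite checks the
solver against Monte-Carlo trajectory simulation. Diffusion pseudotime is
the Euclidean distance from the root cell in eigencomponents 2..10 of the
symmetrized diffusion operator, each scaled by λ/(1−λ), normalized to
[0,1]. Putative drivers are the 100 genes most Pearson-correlated with a
lineage's fate probability over non-terminal cells, computed on the
KNN-smoothed expression (the smoothed matrix, not raw counts, because the
fate probabilities live on the same smoothed manifold). Expression trends
are penalized weighted cubic splines (`mgcv::gam`, 6 basis functions) with
fate probabilities as weights, evaluated on a 100-point grid.

## Orthogroups and the outgroup

Orthogroup tables (group, species, gene; possibly multi-copy) are
consumed as input. The retention rule keeps groups with at least one gene
in every required species and strictly fewer than 5 copies in each.
Conserved DEGs per class are pseudo-cell DEGs that are either (a) in the
per-class intersection, over all ingroup species, of ortholog-mapped
per-species DEGs, or (b) cross-study HVGs of the integrated pseudo-cell
matrix intersected with the pseudo-cell DEGs. "All species" is the strict
reading of the intersection; a `min_species` parameter relaxes it. The
outgroup, linked only via orthogroups, contributes one overlap unit per
retained orthogroup containing at least one ingroup-class DEG and one
outgroup-celltype DEG.

## The synthetic study conditions

The generator produces the conditions every truth-recovery check runs
under: 3 ingroup species sharing 7 homologous classes (300 cells each,
1500 genes, 70% one-to-one ortholog coverage) plus an outgroup (800 genes,
5 cell types) connected only through orthogroups, two of its types sharing
planted-DEG orthogroups with two ingroup classes. Counts are negative
binomial (θ = 5, so variance = μ + μ²/5, matching single-cell
overdispersion) around baseline × class fold (4 for the 30 planted
conserved DEGs per class, on orthologous genes with the same class in every
species) × a shared lognormal latent activity (median fold 4) multiplying
each planted regulon's 15 targets in its active cells × a lognormal
library-size factor (sdlog 0.3). One regulon per class is conserved
(active in all species), one is specific to the reference species.
Species-specific DEGs live on private, non-orthologous genes.

The kinetic panel solves du/dt = α(t) − βu, ds/dt = βu − γs exactly for
piecewise-constant α (the closed form is verified against a numerical ODE
integrator to 1e−9), with β = 8, γ = 4 per unit pseudotime — so the true
steady-state slope γ/β is 0.5 — and Poisson sampling at count scale 30.
Three lineages of 250 cells share a progenitor trunk (t < 0.35); each
lineage has 110 genes switching on at uniform onset times, of which 10 are
drivers with monotone five-step α ramps. 300 housekeeping genes sit at
steady state. Pseudotime is binned into 4 stages so stage/pseudotime
consistency is testable.

What the generator does *not* emulate: batch effects, ambient RNA,
doublets, cell-cycle structure, non-1:1 ortholog ambiguity inside the
ingroup, and gradual class boundaries. Passing the truth-recovery suite
therefore shows the statistics behave correctly on data satisfying their
assumptions — it does not certify performance on real atlases, where
batch correction (explicitly out of scope here) would precede these steps.

Problem sizes throughout (panel of ~6,300 ingroup cells, 750 kinetic
cells) were chosen so the full suite and the acceptance script each run in
a few minutes on a single CPU while keeping every per-class statistic
well-powered.

## Numerical notes

- Power iteration: lazy chain, max-norm tolerance 1e−8, 20,000-step cap;
  non-convergence is an error carrying the residual.
- Transient cells unreachable from any terminal state get a uniform fate
  row with a warning; a singular absorption system is an error.
- `solve()` on the absorption system is exact to ~1e−15; tests compare at
  1e−12 or Monte-Carlo tolerance.
- All stochastic stages take explicit seeds and restore RNG state
  (`withr::with_seed`), so every stage re-runs byte-identically — the
  acceptance suite asserts this at the file level through the CLI.
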