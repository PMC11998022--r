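# statemap

Trajectory inference and cross-trajectory mapping for single-cell studies of
cell-state conversion.

When cells are reprogrammed between states (for example between extra-embryonic
endoderm-like XEN cells and pluripotent ES/iPS cells), time-course single-cell
RNA-seq captures a continuum of intermediate states.  Two questions follow: do
different conversions traverse the *same* intermediate states, and do the
in-vitro paths recapitulate the in-vivo developmental route — in particular,
do they pass through the bipotent ICM-like progenitor that bridges the
epiblast and primitive-endoderm lineages in the embryo?  `statemap` implements
the analysis machinery to answer both, together with a matching
chromatin-accessibility stack for metacell-level scATAC-seq, and seeded
simulators that generate every input with known ground truth so the whole
pipeline is testable end to end.

## The model

A conversion time course is embedded by a diffusion map.  From principal
components of median-scaled, log-transformed expression
(`ln(count / total · median_total + 0.1)`), a k-nearest-neighbour graph
(k = 50, Euclidean) is converted to affinities with an adaptive anisotropic
kernel

&nbsp;&nbsp;&nbsp;&nbsp;a<sub>ij</sub> = exp( −d<sub>ij</sub>² / (σ<sub>i</sub>σ<sub>j</sub>) ),&nbsp;&nbsp;σ<sub>i</sub> = distance from cell *i* to its *l*-th neighbour (l = k/3),

row-normalised into a Markov operator T = D⁻¹A.  Its leading eigenvectors
ψ<sub>i</sub>, re-weighted by λ<sub>i</sub>/(1−λ<sub>i</sub>), give the
multi-scale diffusion space in which all distances are measured; the number of
informative components is picked by the eigengap.  The same operator performs
graph-diffusion imputation (T³·X).

Differentiation is then modelled as an absorbing Markov chain: shortest-path
distances from a start cell give pseudotime; edges are re-oriented to run
forward in pseudotime (within a per-cell adaptive window); terminal states are
detected as boundary-absorbing extrema of the diffusion components; and each
cell's **branch probabilities** are the absorption probabilities
B = (I − Q)⁻¹R of the chain.  Their entropy −Σ p ln p is the cell's
**differentiation potential**.

To compare trajectories, cells are cut into 20 equal pseudotime bins and a
bins-by-bins matrix of mean multi-scale distances is computed in a *joint*
diffusion space built from an augmented affinity matrix: block-diagonal
within-dataset kernels plus adaptive-kernel affinities on mutual nearest
neighbours (k = 50) between datasets, with lineage-restricted extra edge sets
where a lineage is missing at intermediate stages.  Each in-vitro bin maps to
its closest in-vivo bin (row argmin); an in-vitro path that never maps to
ICM-labelled bins bypasses the progenitor state.

Around this core: gene-trend clustering (GAM smoothers on pseudotime,
correlation-radius 0.025 gene graph, Louvain, clusters < 2 genes dropped) and
a metacell scATAC stack — TF-IDF/SVD embedding, metacell aggregation,
median-scaled log-normalisation (pseudo-count 1), highly variable peaks
(binned-dispersion z > 3.0, mean > 0.0125), two-sample Kolmogorov–Smirnov
differential accessibility (p < 1e-4), peak-dynamics classes (late/gradual/
transient opening, late closing), chromVAR-style motif deviation z-scores with
GC- and accessibility-matched backgrounds, Fisher region-set enrichment
(p < 1e-3), and interval utilities (BED 0-based half-open throughout).

## Worked example

Simulate a 5-timepoint conversion with three terminal states, preprocess, and
fit the trajectory model:

```r
library(statemap)

cfg <- sim_config(n_cells_per_timepoint = 200, n_genes = 500, seed = 42)
sim <- simulate_branching_trajectory(cfg)

cells <- filter_cells(sim$cells)                  # drop >20% mito cells
norm  <- normalize_expression(cells)              # ln(count/total*median + 0.1)
hvg   <- select_hvg(norm, 250)
pcs   <- pca_retain(normalized_matrix(norm$values[, hvg],
                                      norm$scale_factor, norm$pseudo))

fit <- fit_trajectory(pcs, start_candidate = 1, k = 50)
fit
#> <trajectory_fit> 1000 cells, start 43, 3 terminal state(s)
glance(fit)
#> # A tibble: 1 × 4
#>   n_cells n_terminal n_components mean_diff_potential
#>     <int>      <int>        <int>               <dbl>
#> 1    1000          3            8               0.742
head(tidy(fit), 3)
#> # A tibble: 3 × 6
#>    cell pseudotime diff_potential terminal_855 terminal_910 terminal_931
#>   <int>      <dbl>          <dbl>        <dbl>        <dbl>        <dbl>
#> 1     1      0.269           1.09        0.303        0.389        0.308
#> 2     2      0.273           1.09        0.303        0.389        0.308
#> 3     3      0.117           1.09        0.303        0.389        0.308
```

The fit found the three planted terminal states automatically; early cells
have differentiation potential near ln 3 ≈ 1.10 (uncommitted, branch
probabilities close to 1/3 each), committed cells fall to 0.  Against the
generator's ground truth the pseudotime ordering agrees with Spearman
ρ = 0.943, and the three terminals sit on the three planted branches
(`T1`, `T2`, `T3`).  `autoplot(fit)` draws cells in the first two multi-scale
components coloured by pseudotime with terminals starred; `run_pipeline()`
chains all stages (both conversions, the embryo-like reference, the peak
experiment) into an output directory with a checksummed manifest.

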