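---
title: "Methods: trajectory inference, cross-trajectory mapping, and the accessibility stack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory inference, cross-trajectory mapping, and the accessibility stack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the tunable parameters with their defaults, what the
synthetic-data generators do and do not emulate, and the numerical and design
choices made where the method descriptions in the literature leave latitude.
It states no empirical result beyond what the test-suite and
`scripts/acceptance.R` themselves compute.

## 1. From counts to a diffusion space

Expression preprocessing follows the standard single-cell recipe for
trajectory work:

* **Cell QC** (`filter_cells`): cells with more than `mito_fraction_max`
  (default 0.20, a fraction) of their molecules on mitochondrial genes are
  treated as apoptotic and removed.
* **Normalisation** (`normalize_expression`): counts are divided by the
  cell total, multiplied by the *median* total across cells (so values stay
  on a counts-like scale), and log-transformed with pseudo-count 0.1.
  Natural log is used throughout; downstream z-scores are base-invariant.
* **Variable genes** (`select_hvg`, default n = 1500; 2500 is the
  conventional choice when pooling heterogeneous timepoints): genes are
  ranked by dispersion (variance/mean of the linear normalised values),
  z-scored within 20 equal-occupancy bins of gene mean.  The within-bin
  centring and scaling are robust (median/MAD): a handful of genuinely
  dispersed features in one bin would otherwise inflate the bin's scale and
  mask themselves.  Constant genes are never selected.  The same machinery,
  thresholded instead of ranked, selects highly variable peaks
  (`highly_variable_peaks`, dispersion z > 3.0 and mean > 0.0125; the
  relaxed set uses 2.0).  The mean-accessibility threshold is applied on the
  normalised-log matrix; its original scale is not documented, and this
  choice is flagged here.
* **PCA** (`pca_retain`): centred PCA keeping the smallest number of
  components whose cumulative explained variance reaches 85%.

The diffusion machinery then works on the retained components:

* `knn_graph`: exact Euclidean k-NN (k = 50), ties broken by ascending
  index for determinism.  Exact search is used deliberately — at the scales
  this package targets (10^3–10^4 cells) it is fast and removes a source of
  irreproducibility; an approximate backend could be slotted in later.
* `adaptive_affinity`: `a_ij = exp(-d_ij^2 / (sigma_i * sigma_j))`, with
  `sigma_i` the distance to the l-th neighbour (l = round(k/3) = 17 at
  k = 50).  The geometric-mean bandwidth is one reading of "scaled by the
  distance to the l-th neighbour" that makes symmetrisation natural;
  the single-bandwidth variant `exp(-d^2/sigma_i^2)` is available via
  `kernel = "local"`.  Symmetrisation is by averaging, `(A + t(A))/2`
  (averaging versus maximum is genuinely open; averaging is the default and
  the alternative would only strengthen weak one-directional edges).
  A zero bandwidth (duplicate points) is replaced by the smallest positive
  bandwidth in the graph.
* `diffusion_maps`: the row-stochastic operator `T = D^-1 A` is
  eigendecomposed through its degree-symmetrised form
  `D^{1/2} T D^{-1/2}` (numerically stable; identical spectrum) and the
  eigenvectors are mapped back.  20 eigenpairs are computed by default (the
  count is configurable; the method literature does not state one), a dense
  solver is used below 200 cells where iterative solvers are unreliable, and
  the number of informative components is the largest consecutive eigenvalue
  drop among the non-trivial eigenvalues, with a floor of 2 — a single
  component cannot support multi-scale distances.  `select = "fixed"`
  honours an externally chosen count (e.g. 14 for a joint two-trajectory
  operator).  Multi-scale coordinates re-weight component i by
  `lambda_i / (1 - lambda_i)`, with eigenvalues capped at `1 - 1e-10` so a
  disconnected or nearly disconnected graph cannot produce infinite weights.
* `impute`: graph diffusion `T^t X`, t = 3 steps by default.

## 2. Trajectory model

`fit_trajectory` chains the stages; each is exported separately.

* **Start anchoring** (`anchor_start_cell`): a user candidate (conventionally
  a random cell from the first timepoint) is moved to the extremum of the
  multi-scale component it loads most strongly on, choosing the extremum
  nearer the candidate.
* **Pseudotime** (`compute_pseudotime`): single-source shortest-path
  distances over the k-NN graph, min–max normalised to [0, 1].  Waypoint
  refinement (iteratively averaging waypoint-centred orderings weighted by
  proximity, convergence at max change < 1e-3) exists behind
  `n_waypoints > 0` but is off by default: plain shortest-path ordering is
  the documented base behaviour, and the refinement's waypoint count is not
  documented for the published method.
* **Chain direction** (`directed_markov_chain`): edge i→j survives iff
  `pt_j >= pt_i - w_i`, where `w_i` is the standard deviation of pseudotime
  among i's neighbours — a per-cell adaptive window that avoids one global
  tuning constant.  Rows are renormalised; rows left empty become
  self-absorbing.
* **Pseudotime and the chain are computed in the multi-scale diffusion
  space** (a second k-NN graph on the multi-scale coordinates), where noise
  directions are contracted and branches separate; the diffusion map itself
  comes from the PC-space kernel.  If the multi-scale k-NN graph fragments
  (possible at small n when branches separate strongly), k is doubled until
  the graph connects.
* **Terminal states** (`detect_terminal_states`): candidates are the
  extremum cells of every multi-scale component.  Each candidate is
  hill-climbed along the chain to its local pseudotime maximum — only that
  cell can be boundary-absorbing, the raw extremum rarely is.  A candidate is
  retained iff (i) its own forward transition mass (to higher-pseudotime
  cells) is below `eps = 1e-3` and (ii) its neighbourhood does not leak
  walkers to higher-pseudotime cells outside itself (per-neighbour leak
  below 0.05): a true branch end satisfies both, while a transient
  mid-branch pocket fails the leak test because the trajectory continues
  past it.  Surviving candidates are deduplicated by connectivity through
  high-pseudotime cells (margin 0.05): two candidates on the same branch end
  connect through cells near their own pseudotime, whereas distinct branches
  only connect through the much earlier branch point.  Known end points can
  be supplied via `user_terminals` and are returned verbatim.
* **Branch probabilities** (`branch_probabilities`): terminals are made
  absorbing and absorption probabilities are solved from the fundamental
  matrix `B = (I - Q)^{-1} R` — dense solve below 500 transient states,
  sparse LU above.  A singular system indicates a recurrent non-terminal
  class and is reported as such.  `fit_trajectory` additionally treats
  self-absorbing non-terminal cells (isolated dead ends created by the
  direction filter) as auxiliary absorbing states so the solve stays well
  posed; they are reported in `fit$dead_ends`, separate from the terminal
  states.
* **Differentiation potential**: Shannon entropy (natural log) of each
  cell's branch-probability row, `0·log 0 = 0`.

## 3. Cross-trajectory comparison

`pseudotime_bins` cuts [0, 1] into 20 equal-width intervals
`[i/n, (i+1)/n)`, the last closed; empty bins are dropped with a warning, and
stratification by a label (e.g. lineage) splits each interval so bins never
mix labels.  "Equal sized" bins admit two readings — equal width and equal
count; equal width matches interval-position figures and is the default,
equal-count quantile bins are available via `method = "count"` and the
question is left flagged rather than resolved.

`bin_distance_matrix` averages multi-scale distances over all cell pairs per
bin pair; above `max_pairs = 250000` pairs a seeded uniform subsample is
used (the estimator stays unbiased; whether published analyses
subsampled is unknown).  `map_bins` takes the row argmin with ties toward the
lower bin index, and reports the median pseudotime of the cells in the
nearest target bin as the representative coordinate.

`augment_affinity` composes a joint graph from per-group blocks
(`affinity_block`) plus mutual-nearest-neighbour cross edges
(`mutual_nn`, `cross_spec`), with cross-edge bandwidths taken from each
endpoint's within-group l-th-neighbour distance (method descriptions are silent on
cross-edge bandwidths; reusing the endpoints' own bandwidths keeps all
affinities on one scale).  Subset-restricted specs express stage- and
lineage-specific edge sets, e.g. joining only the parietal-endoderm cells of
two stages; every spec is recorded in the result's provenance.

`cluster_cells` offers modularity (Louvain) communities on a Jaccard
re-weighted k-NN graph (k = 30; resolution 1 by default, 3 reproduces the
finer clustering used for transition-state analysis) and seeded k-means
(conventionally 30 centres on diffusion components).  `differential_genes`
uses a two-sided Wilcoxon rank-sum test — a deliberate, documented stand-in
for the published hurdle-model test, whose internals are out of scope — with
Benjamini–Hochberg FDR and a log-fold-change computed as the difference of
group means on the normalised-log scale; defaults (FDR < 0.01, lfc > 2, top
50 by FDR then |lfc|) mirror terminal-state signature construction.
`signature_scores` averages per-gene z-scores over a set, so it is invariant
to gene order and to positive affine rescaling of any gene.

## 4. Gene trends

`fit_trends` fits, per gene, a penalized cubic regression spline
(`mgcv::gam`, basis dimension 8, GCV-selected smoothing) of expression on
pseudotime, evaluated on a 500-point grid; the original implementation's GAM
backend is a different package, and penalized splines are the equivalent
model family.  Branch-probability weights restrict a trend to one branch;
zero-weight cells are dropped before fitting so they have no leverage at
all, including on the smoothing selection.  `cluster_trends` z-scores the
trend grid values (variance guard 1e-12; flat trends are excluded with a
warning), connects genes with correlation distance `1 - r <= 0.025`,
symmetrises the radius graph (the original construction may be directed;
symmetrisation is assumed), sets affinity `1 - distance`, runs seeded
Louvain, and drops clusters below 2 genes to unassigned.

## 5. The scATAC metacell stack

`lsi_embed` performs one pass of TF-IDF
(`tf = count/total`, `idf = log(1 + n_cells/(1 + n_cells_with_peak))`) over
the 100,000 highest-count peaks and truncates the SVD at 30 dimensions.  The
reference toolkits iterate LSI with intermediate clustering; a single pass is a
documented simplification that suffices at metacell scale.
`assign_metacells` is a seeded k-means grouping in the embedding — a
simplified stand-in for archetype-based metacell optimisation, which is out
of scope; externally computed assignments are accepted anywhere a
`metacell_map` is.  Aggregation is an exact column sum (conserving totals),
normalisation mirrors the expression formula with pseudo-count 1, and
pseudobulk is the arithmetic mean per group.

`ks_differential_peaks` applies the two-sample Kolmogorov–Smirnov test per
peak, exact when the smaller group has fewer than 10 metacells and
asymptotic otherwise, at p < 1e-4.  `classify_peak_dynamics` encodes the
published dynamics categories as operational rules on min–max-scaled group
profiles; the thresholds (stable if raw range < 0.25; transient if an
interior maximum exceeds both endpoints by 0.5; late if ≥ 70% of the rise
falls in the final third of the order; gradual if monotone with Spearman
ρ ≥ 0.8; late-close mirrored) are artifact-defined, since the source
categories are visual, and all are exposed as arguments.  Profiles matching
no rule fall back to `stable`.

Interval utilities use 0-based half-open (BED) coordinates throughout,
ignore strand (accessibility is unstranded), and delegate the set operations
to `GenomicRanges`: `merge_intervals` (extend then reduce, merging adjacent
intervals — summits extended ±50 bp reproduce the 100-bp summit merge),
`overlap_intervals`, `window_signal_sum` (sum of feature signal with
inter-interval gap ≤ 1.5 kb by default) and `window_overlap_count` (the
50-kb TSS-proximity primitive).  A window of 0 degenerates to plain overlap.

## 6. Regulatory scoring

`motif_deviation_scores` implements bias-corrected deviations: observed
counts over a motif's peaks versus the expectation from the dataset-wide
fractional accessibility, z-scored against `n_background = 50` background
peak sets matched on GC content and mean accessibility through a fixed
10×10 quantile grid (sampling without replacement within a bin, with
replacement once a bin is exhausted).  Motifs with zero hit peaks are
flagged, not scored.  `regionset_enrichment` builds the 2×2
query/universe × in-set/out-set table by interval overlap and computes the
one-sided Fisher exact p — the hypergeometric upper tail — with odds ratio,
BH-adjusted q, and a p < 1e-3 significance flag.

## 7. What the simulators emulate — and what they do not

`simulate_branching_trajectory` places cells on a segment tree (linear; a
shared early segment splitting into three terminal branches; or the embryo
tree ICM → {EPI, PrE}, PrE → {VE, ParE}), samples five overlapping timepoint
windows (25% overlap, mimicking asynchronous sampling), interpolates each
gene's log-program with a cubic smoothstep, draws negative-binomial counts
(dispersion 2) and applies expression-independent Bernoulli dropout (rate
0.2).  All randomness in a call flows from one integer seed, and identical
seeds give byte-identical output.

Two generator design choices deserve emphasis because they make the planted
ground truth *identifiable*:

* **Per-gene activation windows.**  If every gene interpolated its program
  with one shared profile, each segment would be a straight line in
  expression space traversed at a speed that vanishes at the segment ends —
  cells near the ends would collapse onto single points and no method could
  order them.  Instead each gene receives its own activation window (width
  0.2–0.4 of the segment, midpoint up to 0.7), so programs switch
  sequentially and the expression path is a curve with non-vanishing speed,
  which is also what smoothed gene-trend clusters look like in real data.
* **Commitment-onset markers.**  One third of the genes switch immediately
  at segment entry, reflecting that lineage-defining programs engage at
  commitment (as the GATA factors do at primitive-endoderm commitment).
  Without them, cells on the first stretch of a branch would carry no
  fate information whatsoever and branch-assignment accuracy would be
  bounded away from what a correct method should achieve.

`simulate_reference_embryo` adds stage labels (E3.5–E8.75) and a designated
progenitor program expressed only on the ICM segment; configurations built
by `conversion_from_reference` reuse the reference's endpoint programs (e.g.
PrE-like start to EPI-like end) while the progenitor genes stay silenced —
the constructed ground truth for "the in-vitro path bypasses the
progenitor".  When scoring the bin mapping against this ground truth, note
that mid-transition in-vitro bins (mean interpolation weight between the
endpoint programs within [0.35, 0.65]) are designed blends with no unique
matching family: they count as correctly mapped to either non-progenitor
family, while early and late bins are scored strictly and mapping onto
ICM-labelled bins is always wrong.  `simulate_peak_experiment` plants the five accessibility
dynamics classes across ordered groups of metacells (501-bp peaks, beta-
distributed GC), with optional motifs confined to one class.
`simulate_methylation_tracks` lays out non-overlapping CpG-island-like
intervals (17,000 by default) with exponential signal.

Not emulated: read-level sequencing error, doublets, ambient RNA,
chemistry/batch effects, mappability structure, fragment-length effects, or
any genomic sequence context beyond a per-peak GC number.  Passing tests
therefore demonstrate correctness of the algorithms under a clean generative
model, not robustness to the full noise anatomy of real libraries; batch
correction in particular is accepted as a pre-corrected input rather than
performed (the upstream correction tools are deliberately out of scope).

## 8. Numerical choices and problem sizes

Tolerances: operator row sums to 1 within 1e-12; affinity symmetry 1e-12;
absorption rows renormalised and checked within 1e-6 (reported at 1e-9 after
the solve); eigen checks at 1e-8; entropy exact to machine precision.
Ties: k-NN and bin mapping break ties by ascending index; HVG ranking by
gene name.  Degenerate inputs: zero-total cells, unmapped cells, empty
groups, zero-hit motifs and malformed BED records raise named errors;
zero-variance trends and empty bins drop with warnings.

The test-suite and acceptance script exercise the trajectory criteria at the
design scale of n = 3000 cells (600 per timepoint, 1000 genes, 500 variable
genes retained) over 20 seeds for terminal detection and 5 seeds for
pseudotime correlation and fate accuracy; statistical calibration uses 10^5
null tests with two groups of 50; the combinatorial oracles enumerate all
2×2 tables with total ≤ 50 and 10^4 random intervals.  The bundled demo
configuration (`run_config()`) runs both conversions, the reference and the
peak experiment at 600 cells per dataset in well under a minute and is
checksum-deterministic at a fixed seed.

## 9. Known limitations

* Terminal-state detection assumes terminals are pseudotime-late boundary
  states; a terminal at intermediate pseudotime (e.g. a true dead-end that
  arrests early) can be missed — supplying `user_terminals` is the intended
  route when end points are known, matching how reference trajectories with
  known endpoints are handled.
* The rank-sum DE stand-in does not model dropout explicitly the way a
  hurdle model does; its calibration is verified, but power on
  zero-inflated contrasts may differ from the published analyses.
* Single-pass LSI and k-means metacells approximate their iterative /
  archetypal counterparts; both accept external results where fidelity to
  the original tools matters.
* The pair-subsampling cap in bin distances introduces Monte-Carlo error of
  order (max_pairs)^{-1/2} on very large bins; the cap and seed are
  explicit arguments.
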