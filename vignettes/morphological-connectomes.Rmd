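---
title: "Methods: individual GM morphological connectomes in morphnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual GM morphological connectomes in morphnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A subject's gray-matter (GM) morphological network treats each atlas region
as a node and quantifies, for every pair of regions, how similar the two
regional distributions of voxelwise GM values are. The chain is:

1. **Per-ROI sampling.** From a modulated GM volume map and a co-registered
   integer label atlas, collect the GM values of all voxels carrying each
   label (`extract_roi_samples()`). Voxels with values at or below `gm_floor`
   (default 0, strict inequality) are excluded: exact zeros are outside-brain
   padding and would put a spurious atom into the density estimate. ROIs with
   fewer than `min_voxels` (default 10) surviving voxels abort with an error
   naming the region — a silent tiny ROI would produce an unstable density
   and contaminate every one of its N−1 edges.
2. **Density estimation.** Each ROI's value distribution is estimated with a
   Gaussian-kernel KDE (`estimate_pdf()`). The bandwidth rule is Silverman's
   rule of thumb, *h* = 0.9·min(σ̂, IQR/1.34)·n^(−1/5); when the IQR
   degenerates to zero with positive variance the σ̂ term alone is used, and
   zero variance is an error (a distribution concentrated on one value has no
   meaningful density and, more importantly, no meaningful divergence).
3. **Divergence and similarity.** For an ROI pair the two densities are
   evaluated on one shared uniform grid of `grid_size` (default 128) points
   spanning the pooled sample range extended by 3 pooled bandwidths, where
   the pooled bandwidth is max(*h_i*, *h_j*) — the wider kernel dictates how
   far the tails matter. Densities are discretized to probability masses
   (normalized to sum 1; grid-spacing cancels, making the divergence
   invariant to the grid's units), floored by ε = 1e−12, renormalized, and
   compared with the symmetrized Kullback–Leibler divergence
   KL(P‖Q) + KL(Q‖P) in nats. The edge weight is exp(−KLD).

Two of these choices deserve justification because the source methodology
only constrains them loosely:

* **Symmetrization by summation.** A graph edge is directionless while KL is
  not; the sum KL(P‖Q)+KL(Q‖P) is the standard symmetric form in the
  individual-morphological-network literature and is what the worked
  two-point example (P = (0.5, 0.5), Q = (0.9, 0.1) → 0.5108 + 0.3681 =
  0.8789 nats) pins down in the tests.
* **exp(−d) as the similarity map.** Any strictly decreasing map of a
  non-negative divergence onto (0, 1] would satisfy the stated range;
  exp(−d) is the conventional choice, is 1 exactly when the distributions
  coincide, and never truncates information the way a hard cap would. The
  transform is recorded in the matrix metadata.

### Numerical implementation of the KDE

`estimate_pdf()` and the whole-matrix builder `build_network()` share one
code path (C++): sample mass is linearly binned onto the evaluation grid and
convolved with the Gaussian kernel evaluated at grid offsets, cut off at 5
bandwidths (truncated tail mass ~3e−7). Linear binning makes the
4,005-pair/subject build tractable (≈0.1 s per 90-ROI subject) with error
second-order in the bin width — orders of magnitude below every tolerance
asserted in the tests, where an exact-summation KDE serves as the
independent oracle. Because masses are normalized *before* the ε floor, the
divergence — and hence the network — is invariant to rescaling all of a
subject's values (verified to ~1e−3, limited only by discretization).

## Graph analysis

Similarity matrices are thresholded at each sparsity S in 0.10–0.34 (step
0.01, 25 thresholds): exactly round-half-up(S·N(N−1)/2) strongest edges are
retained, with ties at the cutoff broken by ascending (i, j) lexicographic
order so results are bit-reproducible. Both weighted (default) and binary
modes are first-class: the source methodology thresholds "similarity-weighed
matrices" but does not state whether metrics were computed on weights, so
the mode is recorded in every output and the two agree exactly on 0/1
matrices (tested). Published magnitude tables are consequently *not* used as
correctness anchors; correctness rests on brute-force oracle equivalence
(exhaustive triangle enumeration, Floyd–Warshall distances, path-counting
betweenness) on randomized small graphs.

Metric conventions:

* Weighted clustering uses the Onnela geometric-mean form with weights
  normalized by the graph maximum; nodes with degree < 2 contribute 0.
* Shortest paths run on lengths 1/weight. Global and nodal efficiency let
  unreachable pairs contribute 0 (their natural limit); the characteristic
  path length L_p averages over reachable pairs only and the output carries
  an explicit `disconnected` flag — averaging infinities would poison the
  AUC while silently dropping the flag would hide real fragmentation.
* Small-world indices γ, λ, σ = γ/λ normalize against 100 (default)
  Maslov–Sneppen double-edge-swap null networks (10 accepted swaps per
  edge), which preserve the binary degree sequence exactly; in weighted mode
  the weight multiset is reassigned randomly to the rewired topology. The
  indices require ≥95% of pairs reachable — below that L_p stops being
  comparable between graph and nulls, so the function refuses rather than
  extrapolates. Rewiring failure (pathologically dense graphs) raises an
  error reporting the acceptance ratio.
* Every curve is summarized by the trapezoidal AUC over the sparsity range
  (width 0.24), globally and per node.

## Inference

Group comparisons of AUC metrics use a one-way ANCOVA: y ~ group (dummy
coded, HC reference) + age + gender + education + TIV, with the group effect
tested by the extra-sum-of-squares F (full vs covariates-only model). The F
statistic uses the full-model residual mean square, as standard; note that
adding even a perfectly orthogonal covariate therefore rescales F by
(n−p)/(n−p−1) — the tests assert this exact identity rather than the naive
expectation that F is untouched. Results are invariant to the reference
level (tested). Pairwise contrasts come from the full-model coefficient
covariance with Bonferroni adjustment min(1, 3p), gated on overall
significance, following the stated analysis plan. Demographic-table
reproduction uses pooled-variance t-tests (the SPSS default implied by the
published table), summary-statistic ANOVA with Fisher-LSD post hocs, and
Pearson χ² without continuity correction — the recomputed p-values match
the published three-decimal values to ±0.002, the residual being rounding
of the published means/SDs to two decimals.

Clinical associations use partial Pearson correlations: x and y are
residualized on the covariates (with intercept) and the residuals
correlated, df = n − 2 − k. The source analysis says only "Pearson
correlation ... nuisance covariates"; residualization is the concrete
interpretation, and the correlation subset defaults to the pooled patient
groups (DM + DKD) with a config flag, since analyses described as run in
patients could equally mean the pooled patient groups or DKD alone.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` states a world with the published design: 70 HC, 65 DM,
50 DKD; 90 ROIs; 200–2000 voxels per ROI. Voxel values are log-normal
(positive support and right skew, as for modulated GM volumes), with per-ROI
location/scale shared across subjects plus small subject jitter
(SD 0.01 on the log-location). Six affected regions — standing in for the
right dorsolateral superior frontal, bilateral middle frontal, left lingual,
right middle occipital and right precuneus nodes — are shifted away from the
cohort's value-space center and widened in proportion to
effect_grade(group) × latent severity(subject, ~N(1, 0.15)); this makes mean
pairwise similarity involving those regions strictly decrease
HC → DM → DKD (tested) and degrades clustering and degree at those nodes
through the full KDE → KLD → graph chain, not by writing effects onto
metrics directly.

Two geometric refinements were needed to make the *global* clustering
response well-behaved, and both were diagnosed by mapping the dose-response
of mean C_p AUC against the effect grade on fixed cohorts. First, because
thresholding retains a fixed edge *count*, degrading one node's edges frees
slots for edges among the remaining nodes, which can initially *raise*
global C_p (near-central affected nodes), while far-peripheral affected
nodes are isolated almost immediately and the effect saturates; affected
baselines are therefore placed at moderate eccentricity (0.1–0.2 log-units
off center, random side), excluding both degenerate regimes. Second, the
six regions carry fixed staggered sensitivity multipliers (0.5–1.5×), so at
any grade some regions are still on the steep part of their dose-response —
the aggregate response stays monotone instead of saturating all at once. Clinical variables follow the
published per-group means/SDs; the healthy controls' kidney indicators are
not published (patient-only rows), so eGFR ~ (110, 12) and Scr ~ (58, 10)
are synthetic healthy-range choices, and TIV ~ (1450, 130) mL is a typical
adult value. eGFR (loading −0.6), Scr (+0.6) and NCT-A time (+0.4) are tied
to the same latent severity, so degree–kidney-function correlations of the
published sign are recoverable without asserting the published r values.

Default effect grades are DM 0.30 and DKD 0.60 log-scale units. The source
reports no effect size on the value distributions, and these defaults are
explicitly calibration knobs of the stated world: chosen once so that a
reduced cohort (n = 30/group) recovers the imposed ordering — which is what
the acceptance criterion then verifies over 50 replicates.

The generator does **not** emulate: spatial anatomy or smoothness (ROI
samples are i.i.d. draws, so KDE bandwidths are honest, whereas smoothed
real data have correlated voxels), preprocessing artifacts, CKD staging,
missing data, or site effects. A green recovery test therefore establishes
that the pipeline detects distributional group effects of the stated kind
and size — not that real DKD produces them.

## Degenerate inputs and edge policies

* Misaligned volume pairs (grid mismatch, or affines differing by > 1e−4
  per element) are rejected, never resampled — alignment belongs to
  preprocessing.
* Integer label volumes are read without value-altering scaling.
* Sparsity values retaining zero edges raise an empty-graph error carrying
  the offending threshold when inside `metric_curves()`.
* Per-node failures inside the nodal screen are recorded in the output
  table (NA statistics plus the message) without aborting the other nodes.
* All randomness (generator, null ensembles, pipeline stages) is seeded
  from configuration; identical configs reproduce outputs bit-identically,
  and the staged pipeline skips stages whose input hashes are unchanged.

## Known limitations

* The KDE grid is per-pair, so a subject's matrix is not a fixed linear
  functional of a single per-ROI density vector; memoizing per-ROI densities
  across pairs would change results slightly and is deliberately avoided.
* L_p on disconnected graphs is a reachable-pairs mean, flagged rather than
  penalized; comparisons between graphs with very different reachable
  fractions should use the efficiency metrics instead.
* The Maslov–Sneppen null preserves the degree sequence but not weighted
  strength; weighted γ/λ therefore compare against topology-randomized,
  weight-shuffled surrogates, the common practice in this literature.
* Across-node multiplicity in the nodal screen is reported per node
  (3-contrast Bonferroni) only, matching the stated analysis plan; no
  across-node FDR is applied by default.
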