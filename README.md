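# morphnet

Individual gray-matter morphological connectomes from regional value
distributions — construction, graph-theoretic characterization, and
covariate-adjusted group inference, with a synthetic-cohort generator so the
whole pipeline runs end-to-end without any imaging data.

## What problem this addresses

Single-subject structural MRI can be turned into a brain *network*: parcellate
the gray matter (GM) into atlas regions, treat each region as a node, and
connect two regions according to how similar the statistical distributions of
their voxelwise GM values are. Studies of this kind compare the resulting
network topology across clinical groups — here, the motivating design is a
three-group comparison of healthy controls (HC), diabetes patients without
kidney disease (DM), and diabetic-kidney-disease patients (DKD), asking
whether kidney impairment progressively degrades network segregation and
which regional hubs weaken.

`morphnet` is aimed at neuroimaging methodologists and applied researchers
who want that pipeline as reproducible, tested R code:

1. **Network construction.** For each region *i*, the distribution of GM
   values is estimated by a Gaussian kernel density estimate with Silverman
   bandwidth *h* = 0.9·min(σ, IQR/1.34)·n^(−1/5). For each pair (*i*, *j*)
   both densities are evaluated on one shared grid, discretized to
   probability masses, and compared by the symmetrized Kullback–Leibler
   divergence KL(P‖Q) + KL(Q‖P). The edge weight is exp(−KLD) ∈ (0, 1],
   giving an N×N similarity matrix per subject (N = 90 for AAL).
2. **Graph metrics.** The matrix is thresholded over the sparsity range
   S = 0.10–0.34 (step 0.01). At each threshold the package computes global
   efficiency E_glob, local efficiency E_loc, clustering coefficient C_p
   (Onnela form for weighted graphs), characteristic path length L_p, the
   small-world indices γ = C_p/⟨C_p^rand⟩, λ = L_p/⟨L_p^rand⟩, σ = γ/λ
   (degree-preserving Maslov–Sneppen null networks), and the nodal
   centralities degree, efficiency, and betweenness. Each curve is summarized
   by its trapezoidal area under the curve (AUC).
3. **Inference.** Group effects on AUC metrics are tested by one-way ANCOVA
   with age, gender, education, and total intracranial volume as nuisance
   covariates, with Bonferroni-corrected pairwise post hoc contrasts;
   summary-statistic t/ANOVA/χ² tests reproduce demographic-table
   comparisons; clinical associations use covariate-adjusted (partial)
   Pearson correlations.
4. **Synthetic cohorts.** `generate_cohort()` draws per-ROI log-normal voxel
   distributions whose parameters are perturbed in designated "affected"
   regions in proportion to a per-group effect grade times a latent subject
   severity, with clinical covariates (eGFR, creatinine, cognition scores)
   coupled to the same latent factor — so group differences and
   degree–kidney-function correlations are recoverable by the pipeline, by
   construction rather than by assertion.

## Worked example

```r
library(morphnet)

cfg <- cohort_config(group_sizes = c(HC = 12L, DM = 12L, DKD = 12L), seed = 1L)
sim <- generate_cohort(cfg)

net <- build_network(sim$samples[[1]])
net
#> <similarity_matrix> subject HC001, 90 nodes, weights in [0.001, 0.990]

curves <- metric_curves(net, global_metrics = c("cp", "e_glob", "e_loc", "lp"),
                        nodal_metrics = "degree")
curves
#> <metric_curves> subject HC001, 25 thresholds [0.10, 0.34], mode weighted
#> global AUC:
#>     cp e_glob  e_loc     lp
#> 0.1421 0.1125 0.1751 0.6302

cp_auc <- vapply(sim$samples, function(s)
  metric_curves(build_network(s), global_metrics = "cp",
                nodal_metrics = "degree")$auc_global[["cp"]], numeric(1))
ancova_group_test(cp_auc, sim$cohort)
#> <stat_result> ancova: stat = 17.03, df = 2, 29, p = 1.282e-05

tapply(cp_auc, sim$cohort$group, mean)
#>        HC        DM       DKD
#> 0.1437590 0.1409226 0.1374258
```

The AUC summaries are the threshold-free scalars: 0.1421 is the integral of
the clustering-coefficient curve over the 0.24-wide sparsity range (mean C_p
≈ 0.59 per threshold). The ANCOVA says the three groups differ in C_p AUC
after covariate adjustment, in the imposed order HC > DM > DKD; the
Bonferroni post hocs localize every pairwise contrast (HC–DM p ≈ 0.025,
HC–DKD p ≈ 7e−6, DM–DKD p ≈ 0.013). Recovery of this ordering at n = 30
per group over 50 replicate cohorts is acceptance criterion (f).

A full staged run (simulate → network → metrics → stats → report, with
content-hash skipping, a JSON run manifest, violin/scatter figures):

```r
res <- run_all(run_config(out_dir = "run1",
                          cohort = cohort_config(seed = 42L)))
```

or from the shell: `Rscript -e 'morphnet::morphnet_cli()' run-all --config cfg.json`.

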