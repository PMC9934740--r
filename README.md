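# glymclust

Cluster analysis of CSF tracer transport kinetics from dynamic
contrast-enhanced MRI (DCE-MRI).

## The problem

Tracers infused into the cisterna magna spread through the brain's
glymphatic system — along the subarachnoid space, into perivascular
channels, and (depending on molecular size) into the parenchyma. Dynamic
MRI follows this transport as a signal time course per brain region
(ROI). Two questions drive the analysis: *which regions share the same
transport kinetics*, and *how long does the tracer take to travel between
regions*?

`glymclust` answers both with correlation-matrix-based hierarchical
clustering (CMBHC):

1. **Preprocessing.** ROI mean time courses are extracted from the 4D
   series; consecutive frames may be combined (`n_average`); the baseline
   mean is subtracted with a polarity flag (water tracers darken
   T2-weighted images, so their signal change is flipped to make uptake
   positive); every curve is divided by the maximum signal change of a
   reference ROI at the infusion site (the "input function").
2. **Time-lagged cross-correlation.** For ROIs *i, j* and integer frame
   lags ℓ in a symmetric window, the Pearson correlation of the
   overlapping, re-centred segments is computed; the maximal
   cross-correlation coefficient is `mCC(i,j) = max_ℓ r_ℓ(i,j)` and the
   lag time is the maximizing shift in minutes (positive = *j* lags *i*).
3. **Clustering.** The dissimilarity `d = 1 − mCC` feeds complete-linkage
   agglomerative clustering; clusters are the maximal subtrees merging
   below a dissimilarity threshold (default 0.4, i.e. mutual mCC > 0.6).
4. **Cluster confidence.** A multiscale bootstrap resamples time frames at
   several sampling ratios *r* (with each pair held at its full-data
   optimal lag, so the lagged statistic stays well defined), counts how
   often each node's member set reappears (BP), and fits
   `Φ⁻¹(1 − BP_r) = v√r + c/√r` across scales by weighted least squares to
   obtain the approximately unbiased p-value `AU = 1 − Φ(v − c)`.

Because in-vivo data of this kind are rarely shareable, the package ships
a synthetic phantom generator (`phantom_truth()`, `simulate_roi_curves()`,
`simulate_dynamic_volume()`) whose curves follow infusion-boxcar ⊛ Erlang
cascade kinetics with known transport lags and planted cluster structure,
so every stage of the analysis can be validated against ground truth.

## Worked example

```r
library(glymclust)

truth  <- phantom_truth("four_cluster", seed = 7)        # 20 ROIs, 4 clusters
curves <- simulate_roi_curves(truth, noise_sd = 10, seed = 7)
curves <- normalize_by_input(subtract_baseline(curves), reference_roi = 1)
fit <- cmbhc(curves, threshold = 0.4,
             boot = bootstrap_config(n_boot = 200, scales = seq(0.6, 1.4, 0.2),
                                     seed = 7))
print(fit)
```

```
Correlation-matrix-based hierarchical clustering

Lagged cross-correlation: 20 ROIs, frame interval 2.5 min
  mCC range -0.112-0.944, |lag| up to 65 min
Cut at dissimilarity 0.4: 4 cluster(s), 0 singleton(s)
  C1 (n=6): cisterna_magna, ventral_1, ventral_2, ventral_3, ventral_4, ventral_5
  C2 (n=5): parenchyma_1, parenchyma_2, parenchyma_3, parenchyma_4, parenchyma_5
  C3 (n=5): deep_1, deep_2, deep_3, deep_4, deep_5
  C4 (n=4): periventricular_1, periventricular_2, periventricular_3, periventricular_4
  cluster AU p-values: C1=1.00, C2=1.00, C3=1.00, C4=0.99
```

The four planted kinetic families are recovered exactly; every cluster's
AU p-value is ≥ 0.99. The mCC / lag-time table (`mcc_lag_table(fit$lagcorr)`,
mCC in the lower triangle, lag minutes in the upper) shows the ventral
ROIs correlating at 0.88–0.94 with zero mutual lag:

```
               cisterna_magna ventral_1 ventral_2 ventral_3 ventral_4
cisterna_magna             NA      0.00      0.00      0.00         0
ventral_1                0.92        NA      0.00      0.00         0
ventral_2                0.94      0.92        NA      0.00         0
ventral_3                0.90      0.88      0.89        NA         0
ventral_4                0.91      0.89      0.91      0.89        NA
```

`plot(fit)` draws the dendrogram with the 0.4 cut and per-node AU/BP
annotations; `cluster_confidence(fit)` returns them as a table.

The same analysis runs end to end from a YAML config with
`run_pipeline()` (or the `inst/cli/glymclust` wrapper), writing curve
TSVs, the mCC/lag table, dendrogram JSON/Newick and the cluster
assignment to an output directory.

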