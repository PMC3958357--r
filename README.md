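# gimmeclust

Data-driven subgrouping of individuals from directed resting-state
functional connectivity.

Clinical and control samples alike are heterogeneous: individuals who
share a diagnostic label need not share brain physiology. `gimmeclust`
organizes a sample into subgroups using *only* each person's directed
connectivity map, with no prior labels:

1. **Individual connectivity maps.** Each person's ROI time series
   `y_t` is modeled as a lag-1 structural VAR (unified SEM),
   `y_t = A y_t + Φ y_{t−1} + ζ_t`, with contemporaneous directed paths
   `A`, lagged paths `Φ` (autoregressive effects on the diagonal), and
   diagonal innovation covariance. Maps are estimated by the two-stage
   GIMME search: paths supported by a 75% majority (Bonferroni-corrected
   score tests) form the group map, then individual-specific paths are
   added per person until the model fits excellently.
2. **Similarity network.** Each individual's vector of group-level
   contemporaneous weights is Pearson-correlated with every other
   individual's, and the N×N correlation matrix is binarized at a
   threshold `r` chosen entirely from the data: modularity maximization
   is run 100× per candidate threshold, and the selected `r*` is the most
   stable (smallest sd of Newman's Q across runs; ties to the highest
   `r`) among thresholds before the reachability elbow.
3. **Communities = subgroups.** The modal partition at `r*` assigns
   individuals to subgroups. Robustness is verified by degree-preserving
   edge rewiring at levels 0–1 and the variation-of-information distance
   to the original partition, against a size-matched random-graph
   baseline. Subgroup path weights are then compared (each subgroup vs
   the pooled others, ANOVA + contrasts, Storey FDR at α = .05).

A Monte Carlo generator (`simulation_design()` / `generate_panel()`)
reproduces the validation conditions: 100 individuals in 4 subgroups,
10 ROIs, 200 scans, AR 0.60, nine shared contemporaneous paths at 0.50
with per-subgroup ±0.20 deviations on three of them, and one
subgroup-unique path carried with probability 0.5. Utilities for
framewise displacement (`FD_i = |Δd_ix|+|Δd_iy|+|Δd_iz|+|Δα_i|+|Δβ_i|+|Δγ_i|`)
and >0.2 mm scrubbing with placeholder rows connect the pipeline to
motion-corrupted ROI series.

## Worked example

Simulate a small two-subgroup panel and run the full pipeline:

```r
library(gimmeclust)

cfg <- default_config(
  seed = 5,
  simulation = list(n_individuals = 12, n_rois = 6, n_timepoints = 200,
                    group_paths = cbind(from = 1:5, to = 2:6),
                    n_subgroups = 2, subgroup_sizes = c(6, 6)),
  subgroup = list(runs = 30),
  robustness = list(level_by = 0.25, reps = 20))
res <- run_pipeline(cfg)
print(res)
#> <pipeline_result>
#>   <connectivity_maps> 12 individuals; 5 group contemporaneous paths; individual-level additions: median 0.5 (range 0-1)
#>   r* = 0.06; <partition> 2 communities, Q = 0.4375; sizes: 6, 6
#>   subgroup accuracy vs ground truth: 100.00%; connection recovery: 100.00%
```

The group search recovered exactly the five shared chain paths
(`1->2, ..., 5->6` plus the AR diagonal), the two planted subgroups were
recovered perfectly, and the deviant paths surface in the comparison
table with the direction of their planted shifts:

```r
subset(res$comparison$contrasts, verdict != "similar")[1:4, ]
#>   path subgroup mean_subgroup mean_others         t df            p            q verdict
#> 1 1->2        1     0.6853913   0.3393907  9.690248 10 2.119303e-06 7.242359e-06  higher
#> 2 1->2        2     0.3393907   0.6853913 -9.690248 10 2.119303e-06 7.242359e-06   lower
#> 3 2->3        1     0.3033950   0.4956496 -6.445954 10 7.385842e-05 7.385842e-05   lower
#> 4 2->3        2     0.4956496   0.3033950  6.445954 10 7.385842e-05 7.385842e-05  higher
```

Subgroup 1 was generated with `1->2` at 0.7 and `2->3` at 0.3 (and vice
versa for subgroup 2): the verdicts match the planted pattern. The
robustness table shows the partition is exactly reproduced at
perturbation level 0 and departs only as rewiring destroys the blocks:

```r
res$robustness$table
#>   level   mean_vi     sd_vi   mean_fc      sd_fc
#> 1  0.00 0.0000000 0.0000000 0.0000000 0.00000000
#> 2  0.25 0.6522919 0.6884608 0.1333333 0.15625365
#> 3  0.50 1.7671197 0.4360933 0.3750000 0.10644440
#> 4  0.75 2.1676033 0.4329269 0.4875000 0.12174115
#> 5  1.00 2.2151006 0.2766137 0.4958333 0.09549425
```

`mean_vi` is the variation of information (bits) between the perturbed
and original community assignments; `mean_fc` is the fraction of
individuals whose (matched) community changed.

For observed data, point `load_panel()` at a directory of per-individual
delimited time series (rows = scans, columns = ROIs; `NA` rows for
scrubbed frames) and pass the panel to `run_pipeline()`, or use the
shell driver installed at `exec/gimmeclust`
(`simulate | fit | subgroup | robustness | compare | all`).

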