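# striaparc

Connectivity-based parcellation of brain regions from resting-state
fMRI, in R.

Subcortical structures like the striatum look uniform anatomically but
couple to distinct cortical networks. `striaparc` subdivides such a seed
region using only resting-state data, for researchers who want a
reproducible, testable implementation of the full chain:

1. **Temporal preprocessing** — framewise-displacement (FD) motion
   exclusion (max motion < 1.5 mm / 1.5°, mean FD < 0.30 mm),
   robust-MAD despiking, CompCor white-matter/CSF components, and
   *simultaneous* band-pass filtering (0.009–0.1 Hz) + regression of a
   23-column nuisance design.
2. **Connectivity profiles** — per subject, the Fisher-z Pearson
   correlation of every seed voxel with every rest-of-brain target
   voxel, averaged across subjects: `z_ij = atanh r(x_i, y_j)`.
3. **Parcellation** — K-means on the group profile matrix under
   correlation distance `d(u,v) = 1 − cor(u,v)`, best of many restarts
   by within-cluster inertia, with small-component cleanup.
4. **Cluster-number selection** — split-half stability: subjects are
   repeatedly split into halves (⌊n/2⌋ / ⌈n/2⌉), each half parcellated,
   and the halves compared with the variation of information
   `VI = H(C) + H(C′) − 2 I(C, C′)` (nats). The optimal K is the
   smallest K whose VI is statistically indistinguishable (paired t,
   by permutation) from the K−1 solution.
5. **Connectivity of the subdivisions** — per-subject simultaneous GLM
   on all cluster-mean series (seed-to-voxel maps with one-sample t and
   sign-flip permutation cluster-extent FWE correction), and ROI-to-ROI
   tables with Benjamini–Hochberg FDR at q < 0.05.

A synthetic multi-subject generator (`generate_dataset()`) plants known
cluster structure — seed voxels mixing band-limited network signals
through a cluster-specific weight matrix — plus realistic motion traces
and nuisance pools, so the whole pipeline is testable without scanner
data. NIfTI volumes, label atlases, motion TSVs and JSON/YAML region
specs are supported for real data.

## Worked example

Twenty synthetic subjects with three planted seed clusters, end to end:

```r
library(striaparc)

cfg <- pipeline_config(
  synthetic = list(n_subjects = 20, K_true = 3),
  k_range = 2:6, n_restarts = 20, n_perm = 25, n_perm_fwe = 200,
  seed = 1)
run <- run_pipeline(cfg, out_dir = "demo_run")

print(run$stability)
#> Split-half stability: 25 permutations, splits 10/10
#>   K = 2: mean VI = 0.0370
#>   K = 3: mean VI = 0.0000
#>   K = 4: mean VI = 0.3733
#>   K = 5: mean VI = 0.7218
#>   K = 6: mean VI = 0.8986
#> Transitions (VI at K vs K-1):
#>   K = 3: t = -1.000, p = 0.3273
#>   K = 4: t = 29.227, p = 0.0000
#>   K = 5: t = 14.467, p = 0.0000
#>   K = 6: t = 5.200, p = 0.0000
#> Optimal K: 3

adjusted_rand(run$parcellations$K3$labels, run$ground_truth$true_labels)
#> [1] 1

subset(run$roi_fc, cluster == "cluster1")
#>    cluster   region mean_z     t        p        q significant
#> 1 cluster1 region_1  0.048  1.48 1.55e-01 1.55e-01       FALSE
#> 2 cluster1 region_2  0.277  6.59 2.62e-06 3.37e-06        TRUE
#> 3 cluster1 region_3  1.549 44.44 1.15e-20 1.03e-19        TRUE
```

Reading the output: mean VI is near zero at K = 3 and rises sharply
beyond it — the halves keep reproducing the same 3-cluster solution but
disagree once forced to split further. The K = 3 transition is the first
that is not significant (p = 0.33), so the stability rule selects K = 3;
the adjusted Rand index of 1 confirms the parcellation equals the
planted labels exactly. In the ROI-to-ROI table, cluster 1 shows strong,
FDR-significant connectivity with its coupled network's region
(mean z = 1.55 — cluster numbering is arbitrary, so here cluster 1
matched latent network 3) and no significant coupling with the unrelated
region. The run directory holds every artifact (parcellation and VI
tables, cluster stats, exclusion report) plus an MD5 manifest;
re-running the same config reproduces it bit-exactly.

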