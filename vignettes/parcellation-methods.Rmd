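---
title: "Connectivity-based parcellation: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-based parcellation: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striaparc)
```

## The problem and the model

A seed brain region such as the striatum is not functionally homogeneous:
different parts of it couple to different large-scale cortical networks.
`striaparc` subdivides a seed region from resting-state fMRI alone by
clustering its voxels on their *connectivity profiles* — for seed voxel
$i$, the vector $z_{i\cdot}$ of Fisher-transformed Pearson correlations
$z_{ij} = \mathrm{atanh}\, r(x_i, y_j)$ between its time series $x_i$ and
every target (rest-of-brain) voxel series $y_j$. Subject-level profile
matrices are averaged elementwise across subjects; the group matrix is
what gets clustered.

Clustering is K-means under **correlation distance**
$d(u, v) = 1 - \mathrm{cor}(u, v)$: profile rows are centered and scaled
to unit norm once, Lloyd iterations assign rows to the most-correlated
centroid, and centroids are re-standardized means of their members. Each
$K$ is solved with many random restarts and the solution with the lowest
within-cluster point-to-centroid distance (inertia) is kept.

The number of clusters is chosen by **split-half stability**. Subjects
are randomly divided into halves of size $\lfloor n/2 \rfloor$ and
$\lceil n/2 \rceil$ (29 and 30 for a 59-subject study); each half is
averaged and parcellated, and the two solutions are compared with the
variation of information
$$\mathrm{VI}(C, C') = H(C) + H(C') - 2 I(C, C'),$$
with $H$ and $I$ computed from the cluster occupancy probabilities
$P(k) = n_k / n$ and joint probabilities $P(k, k')$. VI is a metric on
partitions: zero iff the parcellations agree up to relabeling, bounded
by $\log n$. Splitting is repeated (100 permutations by default), and
per transition $K-1 \to K$ a paired $t$ test (pairing by permutation)
compares the VI distributions. The selected $K$ is the smallest one
whose VI is statistically indistinguishable from the $K-1$ solution —
the most parsimonious solution that is as stable as its coarser
neighbor. $K = 2$ has no meaningful comparison because two one-cluster
solutions always have VI 0, so selection starts at $K = 3$.

Downstream, each subdivision's connectivity is mapped two ways:

* **Seed-to-voxel:** per subject, all cluster-mean series enter one
  ordinary-least-squares regression simultaneously, so each beta carries
  the variance that cluster explains uniquely; group inference is a
  random-effects one-sample $t$ per voxel (two-sided $p$, $df = N-1$),
  thresholded voxelwise and corrected by cluster extent (below).
* **ROI-to-ROI:** per subject, Pearson $r$ between cluster-mean and
  region-mean series, Fisher $z$, a one-sample $t$ across subjects per
  pair, and Benjamini–Hochberg FDR across all pairs of the table at
  $q < 0.05$.

## Temporal preprocessing

The package implements the temporal half of a standard resting-state
pipeline (spatial steps — realignment, normalization, smoothing — are
out of scope; inputs are assumed aligned):

1. The first 4 frames are discarded.
2. Subjects are excluded when max translation $\geq$ 1.5 mm, max
   rotation $\geq$ 1.5°, or mean framewise displacement $\geq$ 0.30 mm.
   FD is the Power-style sum of absolute parameter differences with
   rotations converted to arc length on a 50 mm sphere.
3. Despiking: samples beyond 3 robust-MAD units from the median are
   winsorized to the boundary. The threshold and the squashing rule are
   package choices (configurable); interpolation-based despiking would
   also be defensible.
4. Nuisance regressors: 6 motion parameters, their backward-difference
   derivatives (first row zero), 5 white-matter and 5 CSF CompCor
   components (top principal components of detrended, variance-normalized
   noise-pool voxels), and a linear trend — 23 columns.
5. Band-pass (0.009–0.1 Hz) and nuisance regression are applied
   *simultaneously*: both data and design are filtered with a zero-phase
   frequency-domain mask, then the data are residualized on the filtered
   design. Filtering both sides prevents the regression from
   reintroducing out-of-band nuisance variance. The filter is a hard
   Fourier mask; bin-aligned in-band sinusoids pass essentially
   unattenuated and out-of-band components are suppressed to numerical
   noise. The constant (DC) component lies outside the band, so a pure
   intercept column would be annihilated; such null columns are dropped
   before the regression.

## Cluster-extent correction by sign flipping

Random-field-theory cluster-size correction needs smoothness estimates
of real residual fields. The package instead uses a distribution-free
permutation scheme: under the null of zero mean, each subject's beta map
can be sign-flipped; the maximum suprathreshold cluster size across both
signs is recorded per permutation, and an observed cluster's corrected
$p$ is $(1 + \#\{\text{null max} \geq s\}) / (1 + n_\text{perm})$. The
voxel threshold is applied one-sided per sign (positive and negative
maps reported separately); taking the null maximum over both signs makes
the correction familywise over the pair of maps. Face (6-) connectivity
defines clusters, configurable to 18 or 26.

## The synthetic generator

No scan data ship with the package; `generate_dataset()` produces
multi-subject datasets in which every downstream claim can be checked
against a known ground truth. Seed voxel $v$ in cluster $c$ of subject
$s$ follows
$$x_v = \sum_m W_s[c, m]\, s_m + \sigma\, \varepsilon_v,$$
where the $M$ network signals $s_m$ are per-subject, zero-mean,
unit-variance Gaussian processes band-limited to 0.009–0.1 Hz (so the
band-pass stage is signal-preserving by construction), and target voxels
follow their network's signal plus noise. $W_s$ is the group weight
matrix plus i.i.d. Gaussian jitter (`subject_sd`), which makes group
averaging demonstrably variance-reducing. White-matter and CSF pools mix
two slow nuisance signals so CompCor has something real to find, and
motion traces are smoothed random walks rescaled to hit a requested mean
FD exactly (FD is linear in a common scaling of all parameters).

Defaults emulate the acquisition this pipeline targets: 59 subjects, 116
frames at TR = 3.5 s, mean FD 0.12 mm. The default weight matrix places
clusters and networks at unevenly spaced positions on a 1D gradient with
exponentially decaying coupling, giving the planted structure a
*hierarchical* similarity: coarser $K$ merge the closest clusters
consistently, the way near-hierarchical splits behave in real
parcellations. This matters for the selection rule: with exchangeable
(equidistant) clusters, the $K < K_\text{true}$ solutions merge an
arbitrary subset, their split-half VI is dominated by that arbitrary
choice, and the $K_\text{true}$ transition shows a significant VI
*decrease* — the rule, which asks for indistinguishability, would then
select nothing. The hierarchy makes coarse solutions reproducible, so
VI stays flat up to $K_\text{true}$ and rises beyond it.

The default noise level $\sigma = 1$ (with unit-variance signals and
between-subject jitter 0.1) was chosen once as the operating point at
which single-subject profiles are visibly noisy but 20-subject group
profiles separate the planted clusters cleanly; the recovery experiments
below use it unchanged. Per-subject network signals are stored in the
ground truth as a list (one $M \times T$ matrix per subject), since each
subject realizes their own spontaneous fluctuations.

What the generator does *not* emulate: spatial autocorrelation beyond
block cluster membership, scanner noise spectra, physiological
quasi-periodicity, motion-coupled signal artifacts, and registration
error. Passing tests therefore demonstrate the correctness and
calibration of the algorithms, not their robustness to every real-data
pathology.

## Problem sizes and numerical choices

The packaged experiments run at desk scale, chosen so the full suite
completes in minutes: recovery and stability experiments use
$K_\text{true} = 3$, 20 subjects, 30 seed voxels, 60 targets, 25
split-half permutations, 20 K-means restarts, over 10 master seeds;
calibration experiments use $10^5$ null voxel draws and 100 null
datasets with 100 sign flips each. The study-scale defaults (K = 2–10,
100 restarts, 100 permutations, 1000 sign flips) remain the function
defaults.

Other numerical decisions, all configuration-visible:

* Entropies and VI use natural logarithms (nats).
* mm coordinates come from the affine applied to 0-based voxel-center
  indices; bounding-box inequalities are strict exactly as specified
  (e.g. $-31 < x < 31$ for the midbrain box).
* Correlations are clamped to $|r| \leq 1 - 10^{-7}$ before the Fisher
  transform; zero-variance voxels yield zero profile rows (kept, with a
  warning) so voxel indexing never shifts between subjects.
* K-means ties go to the lowest cluster index; an emptied cluster is
  re-seeded at the row farthest from its centroid, never stealing a
  singleton's only member; every restart's seed derives deterministically
  from the master seed and the $(K, \text{restart})$ pair.
* The transition test is paired by permutation index by default (each
  permutation clusters both halves at every $K$); a two-sample variant
  is available. Degenerate cases are conventioned: identical VI vectors
  give $p = 1$, constant nonzero differences give $p = 0$.
* The FDR family is all (cluster, region) pairs of one table — the most
  conservative reading; per-cluster families can be formed by subsetting
  before `bh_fdr()`.
* Isolated-voxel cleanup drops connected components smaller than 3
  voxels (configurable) from a cluster's seed mask, flagging rather than
  relabeling them.

## Known limitations

* The optimal-K rule inherits the ambiguity of "statistically
  indistinguishable": with few permutations the test is underpowered and
  selects small $K$; with very many, trivial VI differences become
  significant. The permutation count is part of the analysis definition.
* Hard winner-take-all clustering imposes sharp borders on regions that
  are biologically gradiential; near-boundary voxel assignments should
  not be over-interpreted.
* The sign-flip correction assumes subject maps are exchangeable under
  sign reversal (symmetric null); heavily skewed between-subject
  distributions would break the nominal level.
* Nearest-neighbor mask resampling is adequate for label volumes but
  deliberately simple; no partial-volume handling is attempted.
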