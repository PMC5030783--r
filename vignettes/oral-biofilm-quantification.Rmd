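---
title: "Quantifying viability and compositional shifts in ex vivo oral biofilm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying viability and compositional shifts in ex vivo oral biofilm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oralbiofilm)
```

## The experimental setting

Native supragingival biofilm is grown on enamel-dentin slabs worn in the
mouth for 48 h, then transferred into a flow reactor and followed for a
further 48 h. Two questions are quantified:

1. **Viability.** Dual-stained confocal z-stacks (Syto 9 labels all cells
   green; propidium iodide labels membrane-compromised cells red) are
   recorded at four time points — T0 directly after removal from the mouth,
   T1 after 1 h, T2 after 24 h, T3 after 48 h of incubation — with at least
   five stacks at random positions per slab. Each stack pair yields a
   fraction of living bacteria; per subject and time point these are
   averaged over fields into a survival series.
2. **Composition.** 16S amplicon OTU count tables from paired T0/T3 samples
   per subject are compared: per-taxon quartile summaries, paired Wilcoxon
   signed-rank tests with Bonferroni correction, and zero-exclusion log2
   fold changes of mean absolute abundance.

Neither the raw image stacks nor the raw reads of such studies are
typically available, so the package ships a synthetic-data module that
generates both input kinds with known ground truth; every stage of both
pipelines is tested against that truth.

## Viability pipeline

### Segmentation model

Per channel, the multiset of **non-zero** voxel intensities is partitioned
into `k = 4` clusters; the lowest-mean cluster is taken to be background
plus noise and removed, and the remaining three clusters form the
foreground mask. The implicit model is that the non-zero intensity
histogram is dominated by stained biomass with a well-separated dim tail of
instrument noise; k = 4 leaves headroom for dim, medium and bright biomass
while sacrificing exactly one cluster to background.

`cluster_channel()` solves the k-means objective **exactly**: in one
dimension the optimal partition is contiguous in sorted order, so a dynamic
program over the run-length-encoded histogram finds the global
within-cluster sum-of-squares minimum deterministically. This removes the
seed sensitivity of conventional Lloyd iterations while solving the same
objective; a `method = "lloyd"` mode (fixed seed, `stats::kmeans`) is kept
for comparison. For 16-bit stacks the number of distinct values is a few
thousand at most, and the O(k d²) program runs in well under a second.

Degenerate inputs are handled conservatively:

* fewer distinct values than `k`: `k` is reduced;
* a single cluster (uniform staining): **all** non-zero voxels are kept —
  removing the only cluster would erase a genuinely stained uniform field;
* an all-zero channel: an explicit empty signal, which downstream turns
  into an empty mask rather than an error.

### Exclusion of yeast and mucosa

Occasional yeast and oral mucosa cells appear as large bright red regions
and must be removed from **both** channel masks. Two routes are supported:
a manually drawn ROI mask (`exclusion_mode = "roi"`), which mirrors the
original manual workflow, and an automated stand-in (`"auto"`, the default
in tests): connected components of the union mask (26-connectivity in 3-D)
with volume at least `min_volume` voxels are excluded.

The default `min_volume = 300` voxels sits between the largest plausible
bacterial aggregate in the simulated scenes (an eight-cell coccoid chain,
about 120 voxels at the default cell radius) and the smallest simulated
yeast blob (about 450 voxels at in-plane radius 6). On simulated scenes
this recovers yeast voxels essentially completely; its known cost is that
bacteria directly touching a yeast blob are excluded with it, which is the
dominant residual error of the whole pipeline (see below). The threshold
scales with voxel pitch and cell size and should be revisited for other
optics.

### Double labeling and fractions

A voxel foreground in both binarized channels is "double-labeled"
(orange). Mask intersection is the only definition of this class that a
binary-mask workflow supports, and such voxels are **always counted as
dead**: `reassign_double_labeled()` removes them from the live mask and
leaves the dead mask unchanged, so live and dead partition the foreground
union exactly. Coverage is the plain voxel count over the entire stack (no
per-slice weighting, no physical-area normalization; a voxel-pitch
conversion exists but is off by default), and the live fraction is
`100 · live / (live + dead)` percent, with 100% being the sum of both. An
empty foreground yields an *undefined* fraction (`NA`), never 0 or 100;
`build_survival_series()` excludes undefined fields with a warning. Panel
means use the arithmetic mean over fields and the sample (n−1) standard
deviation, which is only defined for two or more fields; missing time
points are reported as gaps.

## What the stack simulator emulates — and what it does not

`generate_stack_pair()` renders cocci as solid spheres (ellipsoids in voxel
space when the z pitch exceeds the in-plane pitch — anisotropy affects
placement geometry only, never intensities), chains as touching sphere
sequences along a direction with angular drift, and yeast as large blobs in
the red channel only. Double-labeled cells carry full intensity in both
channels, treating "orange" as a discrete class. Objects are placed by
rejection sampling without overlap and fully inside the grid; an overfull
grid raises a placement-failure error after a bounded number of attempts.

The background noise model is sparse shot noise: each voxel receives a
noise event with probability `1 − exp(−noise_rate)` (default rate 0.05) and
truncated-Gaussian amplitude (default mean 150, SD 150 counts). Most
background voxels are therefore exactly zero, as in photon-counting
confocal acquisition — this matters, because the segmentation clusters
*non-zero* voxels only, and its "lowest cluster = background" reading
presumes that non-zero background is a minority population well below the
signal. A dense, bright background (e.g. strong autofluorescence) would
break that assumption for the original method and for this implementation
alike. Bleed-through adds a fraction (default 3%) of each cell's intensity
to the opposite channel; at the default intensity ranges the bled values
land inside the background cluster and are removed with it.

Defaults (12 × 64 × 64 voxel grid; 80 live, 20 dead, 10 double-labeled
cocci; two chains of 4–8 cells; two yeast blobs; class intensities
3000–7000 counts) were chosen once as a plausible moderately dense field at
0.5 µm in-plane / 1 µm axial pitch. Not modeled: the optical point-spread
function, photobleaching, depth-dependent attenuation, intensity gradients
within cells, and saliva/flow effects. Passing the recovery tests therefore
shows that the algorithm chain is self-consistent on geometrically and
photometrically plausible scenes — not that it is robust to every artifact
of real microscopy.

Two recovery regimes are asserted in the tests:

* **Noise-free, bleed-free scenes with uniform class intensities** recover
  the true fraction *exactly*: each channel then holds one distinct
  non-zero value, the single-cluster rule keeps everything, and no voxel is
  misclassified. Uniform intensities are required for exactness — with zero
  noise but spread intensities there is no background cluster and the
  method necessarily sacrifices its dimmest signal cluster.
* **Moderate-noise scenes** (defaults, bleed-through ≤ 5%): the estimated
  fraction is within 5 percentage points of truth for well over 90% of
  stacks; the residual tail comes almost entirely from bacteria adjacent to
  yeast blobs being removed by the automatic exclusion.

Survival cohorts (`generate_survival_cohort()`) hit per-field target
fractions by splitting a fixed cell budget between the classes (chains are
assigned greedily, singles fill the exact remainder). With equal cell
radii, no clipping and no overlap, the voxel-level truth equals the cell
split, so zero-jitter cohorts whose targets are achievable with the budget
(e.g. integer percentages with a 100-cell budget) reproduce their
trajectory exactly; field jitter is Gaussian on the target, truncated to
[0, 100].

## Composition pipeline

The statistical conventions are fixed and recorded in every run's
metadata:

* **Common-OTU filter**: an OTU is retained only if its count is non-zero
  in *every* sample. Applied (by default) before the OTU-level stages
  (heat map, log2 fold change); rank-level testing uses the full table.
* **Taxonomy collapse**: counts are summed over OTUs sharing the label at
  the requested rank; OTUs unassigned at that rank — and malformed strings,
  with a warning — pool into `"Other"` ("unclassified at the collapsed
  rank"), so per-sample totals are conserved at every rank.
* **Quantiles**: linear interpolation with `p(k) = k/(n+1)`
  (`stats::quantile` type 6). This is the default of the commercial package
  family commonly used for such tables and gives quartiles 1.5/4.5 on
  `{1,…,5}`; since quantile conventions differ across software, the choice
  is stated in the output metadata rather than silently assumed.
* **Paired Wilcoxon signed-rank**, two-sided, on per-subject differences:
  zero differences are discarded before ranking (classic handling, not
  Pratt); ties get average ranks. With at most 12 non-zero differences and
  no ties the exact distribution is computed by convolution; otherwise a
  normal approximation with tie-corrected variance and *no* continuity
  correction is used (matching the z statistic of the same package
  family). The cut at 12 keeps enumeration cheap while making small-cohort
  p-values exact and reproducible.
* **Bonferroni**: `min(1, m·p)` with `m` = the number of taxa tested at the
  same rank in the same run; `m` is recorded per row.
* **Log2 fold change** uses arithmetic means of raw counts per time point
  ("absolute abundances"); OTUs with zero mean at either time point are
  excluded and listed, because their ratio is undefined — they are *not*
  imputed. A relative-abundance mode exists; raw counts are the default.
* **Heat map**: rows are genera above a mean relative abundance threshold
  (default 2%), columns subject-paired (each subject's T0 immediately left
  of its T3), values `log10(1 + percent)` — a logarithmic scaling that
  tolerates zeros.

The OTU simulator draws per-sample read depths uniformly from the observed
range (1841–3863 reads) and counts from a Dirichlet-multinomial around
time-point-specific base proportions (default concentration 200, a
moderate between-subject overdispersion; `Inf` gives pure multinomial
sampling). The default base composition uses the phylum-level medians of
the study community at T0 and T3, with the dominant Firmicutes split into
its leading genera (Streptococcus and Veillonella, together roughly two
thirds of the community) and the remainder pooled as `"Other"`. Each
taxon's proportion is spread over its OTUs by fixed Dirichlet weights
shared between time points, so OTUs keep their identity across the
pairing. The simulator does not model sequencing error profiles,
chimeras, or zero inflation beyond what the multinomial induces.

## Problem sizes used in the tests

The shipped suite and the acceptance script regenerate everything from
code: 50 noisy stack pairs for recovery, 100 random intensity multisets
(≤ 15 distinct values) against an exhaustive-search clustering oracle, 200
random difference vectors against full 2^n sign-assignment enumeration of
the signed-rank null, a 500-replicate paired null simulation (25 subjects)
for the empirical test size, and five simulated tables for the brute-force
filter comparisons. These sizes give Monte-Carlo error comfortably inside
the asserted tolerances while a full run stays in the minutes range.

## Known limitations

* The segmentation inherits the original method's assumptions: exactly one
  background cluster, and background separable from signal by intensity
  alone. Stacks whose non-zero voxels are mostly background violate this.
* The automatic exclusion trades a small bacterial loss near yeast for
  complete yeast removal; with `exclusion_mode = "roi"` a curated mask can
  avoid that cost.
* A single intensity threshold pair defines "double-labeled"; partial
  spectral overlap (true orange gradients) is outside the binary-mask
  model.
* The Wilcoxon normal approximation is used above n = 12 even though exact
  enumeration would still be feasible somewhat beyond that; the switch
  point is a reproducibility convention, not a statistical claim.
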