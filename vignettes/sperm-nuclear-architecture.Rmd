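---
title: "Quantifying sperm nuclear architecture from 3D-FISH stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sperm nuclear architecture from 3D-FISH stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Boar sperm nuclei are paddle shaped: a long antero-posterior (AP) axis of
about 12 µm and a flat head about 3 µm deep. Within this nucleus,
chromosomes occupy discrete territories (CTs), telomeres gather into small
clusters, and centromeres aggregate into chromocenters. A Robertsonian
translocation t(13;17) — the centromeric fusion of the acrocentric
chromosomes SSC13 and SSC17 — gives a heterozygous carrier whose balanced
gametes split half-and-half between a normal 19-chromosome complement
(38 telomeres) and an 18-chromosome complement carrying the fusion
(36 telomeres). `spermfish3d` implements the image-quantification pipeline
used to ask whether that fusion reorganises the sperm nucleus: segmentation
of multi-channel confocal stacks, per-nucleus spatial statistics, group
comparisons, and the Mendelian segregation model that predicts what a
carrier's sperm should look like if only the fused pair moves.

Because the original image data are not deposited, the package ships a
synthetic-data generator whose defaults encode the study conditions; every
stage of the pipeline is validated by recovering the generator's known
ground truth.

## Coordinate conventions

Stacks are arrays indexed `(z, y, x)` with physical coordinates
`(index - 1) × spacing` in µm; the acquisition spacing is
0.093 × 0.093 µm in-plane and 0.244 µm between planes at 8-bit depth.
All distances are µm throughout.

## Segmentation

All objects are voxels above a globally set per-channel threshold, labelled
into 26-connected 3D components (`connectivity` is configurable; 26 is the
default because spot clusters are isotropic in physical space while the
axial sampling is 2.6× coarser, so stricter connectivity would split
axially adjacent voxels of one cluster). The nucleus is the largest
component of the DNA counterstain, hole-filled slice-wise and then in 3D.
Signal objects are restricted to the nucleus mask and filtered at
`min_object_voxels = 5` to suppress single-voxel noise.

Two thresholding modes exist. The default for signal channels is a manual
global threshold (80, midway between the generator's background of 10 and
signal plateau of 150), which mirrors the interactive workflow the study
describes: a user sets a global threshold and adjusts it after visual
inspection. The automatic alternative (`auto_threshold()`) maximizes
between-class variance exhaustively over the 256 intensity levels; it is
the default for the counterstain, where the foreground fraction is large
and the criterion is reliable. For sparse point-like channels (< 1% of
voxels above background) a variance-based global threshold tends to settle
just above the background mode and inflate object extents — exactly the
situation the interactive workflow corrects by hand — hence the manual
default for signals.

## Spatial statistics

**Cluster counts.** Each connected component is one telomere cluster or
chromocenter. Counting can also be done on the z maximum projection
(`count_mode = "projected"`); for clusters separated in-plane the two modes
agree, and the package asserts that equivalence on synthetic data rather
than taking a position on which variant the original software used.

**Pair classification.** Territory pairs are *colocalized* when their voxel
sets share at least two voxels, *adjacent* when the edge-to-edge gap is
under one in-plane pixel, *distant* otherwise. "Pixel" is interpreted on
the acquisition grid: the gap is the minimum distance between voxel centres
minus one in-plane pixel, floored at zero, so an overlap of exactly one
voxel counts as touching (gap 0, adjacent) while the two-voxel rule is
reserved for colocalization. The threshold is configurable
(`adjacency_gap`).

**Associations.** Cross-channel chromocenter associations (AC6 ×
SSCRS2A) count pairs classified colocalized-or-adjacent, each object
consumed at most once, matched greedily by smallest gap with ties broken by
label order.

**Axis frame and positions.** The AP direction is the dominant principal
axis of the nucleus voxel cloud in physical coordinates; a mask whose two
leading axis lengths differ by less than 10% has no meaningful AP axis and
is rejected (a sphere is the degenerate case). The posterior origin is the
extreme voxel along the axis; AP% runs 0 (posterior) to 100 (anterior).
Anterior/posterior is disambiguated by a hint vector — the generator
manifest supplies it for synthetic data; without one the sign is fixed
deterministically and flagged low-confidence, because a symmetric ellipsoid
carries no intrinsic anterior cue (real paddle-shaped nuclei would need a
shape-based heuristic, and group means of AP% depend on that choice). ML%
is unsigned: 0 on the axis, 100 at the border, computed by dropping the
centroid perpendicularly onto the axis line and ray-marching (step = half
the smallest voxel size) from the centroid to the last in-mask position.
Morphology is *elongated* when the ratio of the two largest second-moment
axis lengths strictly exceeds 1.5 (at the threshold: round); the threshold
is an artifact decision, configurable. "Central part of the nucleus"
defaults to ML% < 50, also configurable — the study never defines the
cutoff.

## Group statistics

Per-nucleus measures are compared with a classical pooled-variance
two-sided Student test (Welch behind a flag); category distributions with
chi-squared tests (no continuity correction). Zero-variance measures with
equal means report p = 1 rather than NaN. No multiple-testing correction is
applied — matching the original analysis — but every report records the
number of tests run. The segregation model says a carrier population's
proximal (colocalized-or-adjacent) fraction is `f + (1 − f)·b` with
`f = 0.5` the fused-gamete fraction and `b` the control proximal fraction;
with the control condition rounded to one half this gives the 75% / 25%
expectation. `b = 0.48` (the observed 16% + 32%) is available as an
override.

## The synthetic-data generator

`generate_population()` draws per-nucleus ground truth; `simulate_nucleus()`
renders any manifest entry deterministically (a master seed feeds
per-nucleus sub-streams, so populations are reproducible and individual
nuclei re-render bit-identically).

**Nucleus.** A flattened ellipsoid with semi-axes (6.0, 3.5, 1.5) µm — the
12 µm AP axis and ~3 µm depth are reported; the lateral semi-axis is not,
and 3.5 µm is the package's choice. A true paddle outline is not modelled:
the positional metrics depend only on a convex mask with a dominant axis.
In-plane orientation is uniform random; the stack is sized around the
rotated nucleus with 1 µm clearance.

**Signals.** Telomere clusters draw sizes from {2, 3, 4} with weights
{0.35, 0.40, 0.25} (small clusters of 2–4 telomeres) until the karyotype's
telomere total (38, or 36 in fused gametes) is exhausted, any remainder
forming one smaller cluster. Chromocenter-count distributions match the
reported means: AC6 1.7 clusters per nucleus in controls (90% of nuclei
with 1–2, 10% with 3) and 1.48 in fused gametes, which also lose one
AC6-labelled centromere (5 instead of 6); SSCRS2A 11 centromeres in 3–9
clusters with mean 5.9. Cross-channel association counts follow the
reported mixtures (means 0.49 control, 0.34 carrier). Spots are
anisotropic Gaussians (σ_xy = 0.12 µm, σ_z = 0.35 µm, amplitude 150 over
background 10) jittered within 0.15 µm of their cluster centre so members
merge into one component; distinct clusters keep ≥ 1 µm in-plane
separation. Separation is enforced in-plane rather than in 3D: with
σ_z ≈ 3σ_xy a purely axial 1 µm separation could bridge at threshold, and
in a 3 µm-deep nucleus clusters separate laterally anyway. Noise is
Poisson on signal plus Gaussian read noise (σ = 3), clipped to 8 bits;
the resulting SNR is well above the 10 the recovery claims assume.

**Territories.** CT blobs have a steep-shouldered radial profile
`A · 2^(−q⁴)` in the normalized ellipsoidal coordinate, so the half-maximum
iso-surface *is* the design ellipsoid: any threshold near the midpoint
recovers the design volume and axis ratio, and level sets are scaled
ellipsoids, making the morphology ratio threshold-independent. Volumes
(SSC13 4 µm³, SSC17 3 µm³, X 4, Y 2) are the package's choice of painted
territory cores — genome-proportional volumes are geometrically unable to
sit peripherally in a 3 µm-deep nucleus, which would invert the observed
control ordering. Design centre-ML means put SSC13 peripheral (66, the
upper end of what containment allows for its size; containment rejection
compresses the realized mean to ≈ 49), SSC17 intermediate (43), and
gonosomes at the reported AP/ML means (X: 53/36.7, Y: 59/26.7), all with
σ = 15-point truncated normals — the spread is a free choice, the means are
reported values.

**The fused pair.** Each nucleus draws a true pair category: controls from
(0.16, 0.32, 0.52), fused gametes from (0.32, 0.68, 0) — chosen so a 50%
carrier population mixes to ≈ (0.24, 0.50, 0.26), the observed carrier
distribution. Proximal pairs share one long-axis orientation and sit back
to back along it: that is the configuration of a fused or contacting pair,
and the only one in which the designed surface gap is exact (tilted
ellipses have no closed-form contact distance). Colocalized pairs
interpenetrate by half the smaller long semi-axis; adjacent pairs leave a
one-pixel surface gap (a design-time geometric scan of the classifier's
validity window — the classifier rule itself is fixed); distant pairs are
certified separated by ≥ 0.6 µm using the ellipses' support functions.
The fused-pair ML anchor (32) displaces the pair to the central region —
the carrier phenotype — while control proximal pairs anchor at 58, between
the two single-territory means.

**What the generator does not emulate.** Optics beyond a Gaussian PSF (no
diffraction rings or chromatic shift), chromatin texture inside the
counterstain, partial decondensation, the true paddle outline, and
touching-but-distinct spot clusters below the separation floor. Passing
recovery tests therefore demonstrate that the measurement code is correct
under the stated imaging model, not that the pipeline is robust to every
artefact of real confocal data. Two printed observations are knowingly not
reproduced: the absolute "central fraction" percentages (51% vs < 20% at
any fixed cutoff depend on territory size, which compresses centre-ML
geometrically), and per-animal variation (the study images two animals;
the generator draws one population per condition).

## Numerical choices and degenerate inputs

Ties in the automatic threshold resolve to the lowest maximizing level;
labelling order is raster-deterministic; signal objects sort by descending
volume with raster ties. Empty images, constant channels, spherical masks,
centroids outside the mask, probes or probabilities out of range all raise
errors rather than returning silent defaults. Zero-variance test inputs are
the one deliberate soft spot (p = 1 on equal means) because self-comparison
reports must be NaN-safe.

## Problem sizes used in validation

The test suite validates recovery on a 200-nucleus population at the
default conditions (≈ 99%+ exact cluster-count agreement, AP/ML mean
absolute error ≈ 2 points against ground truth, ≥ 95% pair-category
agreement), estimates type-I error of both group tests over 1000 null
replicates of 80-nucleus groups resampled from a 3000-nucleus control pool
(exchangeable under the null; the pool keeps a thousand replicates cheap),
and estimates power over 100 replicates of 100 + 100 nuclei — the study's
per-condition sample size — detecting the SSC13 medio-lateral shift in
well over 80% of replicates. The analysis scripts use 40 nuclei per group
so a full end-to-end run stays interactive.

## Known limitations

Anterior/posterior disambiguation on real data is heuristic and
low-confidence; AP means flip sign with it. The adjacency rule inherits
the acquisition grid's anisotropy (one *in-plane* pixel). The watershed
splitting of touching clusters is deliberately out of scope, so cluster
counts undercount when true clusters sit closer than the separation the
generator enforces. Territory "volume" is threshold-dependent for any
profile shallower than a step; only ratios and classifications are
threshold-stable by design.
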