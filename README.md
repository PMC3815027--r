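# spermfish3d

Quantitative analysis of sperm nuclear architecture from multi-channel
3D-FISH confocal stacks, built around the boar model system: paddle-shaped
nuclei (~12 µm antero-posterior axis, ~3 µm depth) imaged at
0.093 × 0.093 × 0.244 µm voxels, with a DNA counterstain plus telomere,
centromere-satellite (AC6 / SSCRS2A) and chromosome-paint (SSC13, SSC17,
X/Y) channels. The scientific question the pipeline serves: does a
Robertsonian translocation t(13;17) — the centromeric fusion of two
acrocentric chromosomes — reorganise the sperm nucleus, globally or
locally?

## What the package computes

**Segmentation.** Objects are voxels above a globally set per-channel
threshold (manual, or the exhaustive between-class-variance maximizer),
labelled into 26-connected 3D components; the nucleus is the largest
hole-filled counterstain component.

**Per-nucleus statistics** (module `measure_nucleus()`):

* telomere-cluster and chromocenter counts (3D or z-projected);
* AC6 × SSCRS2A chromocenter associations (greedy one-to-one matching of
  colocalized-or-adjacent cross-channel pairs);
* the SSC13/SSC17 pair category — *colocalized* if the territories share
  ≥ 2 voxels, *adjacent* if their edge gap is < 1 in-plane pixel,
  *distant* otherwise;
* normalized positions in the nucleus frame: AP% along the dominant
  principal axis (0 posterior → 100 anterior) and unsigned ML% (0 on the
  axis → 100 at the border, by ray-marching the mask);
* territory morphology (*elongated* iff the top-two principal axis ratio
  exceeds 1.5) and centre-to-border distance.

**Group statistics** (`compare_populations()`): classical pooled-variance
Student tests on numeric measures, χ² tests on category distributions,
significance at 0.05, no multiplicity correction (the number of tests is
recorded).

**Segregation model.** A heterozygous carrier produces ~50% fused balanced
gametes, whose SSC13/SSC17 territories are always proximal
(colocalized-or-adjacent); the rest behave like controls with baseline
proximal fraction *b*:

```
P(proximal) = f + (1 − f) · b ,   f = 0.5, b = 0.5  →  75% / 25%
```

**Synthetic data.** `generate_population()` draws per-nucleus ground truth
under the study conditions (karyotype-conserved telomere totals of 38/36,
chromocenter-count distributions matching the reported means, category
mixtures, truncated-normal territory positions around the reported means)
and `simulate_nucleus()` renders each entry as a noisy 8-bit multi-channel
stack — flattened-ellipsoid nucleus, Gaussian-PSF spot clusters,
steep-shouldered territory blobs, Poisson + Gaussian noise. A master seed
makes populations and individual stacks bit-reproducible.

## Worked example

The analysis is organised as numbered drivers over the package:

```sh
Rscript analysis/01_simulate.R   # two 40-nucleus populations + ground truth
Rscript analysis/02_measure.R    # full imaging pipeline on both
Rscript analysis/03_compare.R    # control vs t(13;17) report + segregation fit
Rscript analysis/04_power.R      # type-I error and power at n = 100/group
```

`03_compare.R` prints (this run):

```
Control vs t(13;17) comparison (15 tests, alpha = 0.05)
measure              test      mean_ctl mean_car statistic         p   sig
n_telomere_clusters  student_t     12.9     13.1    -0.958     0.341
n_ac6_clusters       student_t     1.55     1.55         0         1
n_rs2a_clusters      student_t     5.85     5.83    0.0793     0.937
n_associations       student_t     0.65     0.35      2.41    0.0184     *
ssc13_ap_pct         student_t     49.1     51.7    -0.797     0.428
ssc13_ml_pct         student_t     52.3     40.5       3.2   0.00198     *
ssc13_morphology     chi2                           0.0559     0.813
ssc13_border_um      student_t    0.945     1.02     -2.35    0.0213     *
ssc17_ap_pct         student_t     51.7     46.7       1.3     0.198
ssc17_ml_pct         student_t     45.1     37.3      1.88    0.0634
ssc17_morphology     chi2                           0.0527     0.818
ssc17_border_um      student_t    0.993     1.02    -0.593     0.555
gonosome_ap_pct      student_t     54.1     53.8    0.0818     0.935
gonosome_ml_pct      student_t     29.2     30.5    -0.367     0.715
pair_category        chi2                             2.64     0.267

Carrier pair categories: 11 colocalized, 17 adjacent, 12 distant
Segregation model expects 75% proximal / 25% distant
Goodness of fit: chi2 = 0.533, df = 1, p = 0.465 (not different from expectation)
```

Reading the report: global measures (telomere clusters, chromocenter
counts, gonosome position) do not separate the groups, while SSC13 is
displaced toward the nuclear centre (ML% 52.3 → 40.5, p = 0.002) and moves
slightly off the border — the local-not-global reorganisation signature —
and the carrier pair-category mixture is compatible with the 75/25
segregation expectation. At 40 nuclei per group some tests are
underpowered (the pair-category χ² needs ~100 per group, see
`analysis/04_power.R`, which reports type-I ≈ 0.05 and power ≥ 0.98 for
both headline tests at that size).

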