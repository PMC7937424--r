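---
title: "Methods: CT texture analysis and unsupervised classification of adrenocortical tumours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT texture analysis and unsupervised classification of adrenocortical tumours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Adrenal masses found incidentally on CT must be triaged into benign
lesions (adenomas, stable incidentalomas) and adrenocortical carcinoma.
Conventional radiology uses the unenhanced attenuation (lipid-rich
adenomas sit below 10 HU) and contrast washout (absolute > 60 %, relative
> 40 % suggests adenoma). Lipid-poor adenomas defeat both rules: they
present above 10 HU with reduced washout, exactly like carcinoma. This
package implements the radiomic alternative — quantify the *texture* of
the lesion on each contrast phase and let the feature space separate the
classes — together with the synthetic data needed to validate every stage.

## Pipeline overview

```
volumes + masks ──► extract_voi ──► mean densitometry ──► washout_table
                         │
                         └─► quantize ──► GLCM ──┐
                                   │             ├─► 32-feature vector
                                   └─► RLM ──────┘
cohort of feature vectors ──► compare_features / select_features / roc_youden
                         └──► standardize ─► flag_outliers ─► kmeans_two
                                                │
                                                └─► fit_pca (visualization)
```

## Washout densitometry

For phase-wise VOI means `U` (unenhanced), `E` (enhanced, venous in this
package's cohorts) and `D` (delayed):

- absolute washout = `100 (E − D) / (E − U)`; invariant to adding a
  constant to all three values; undefined when `E = U`.
- relative washout = `100 (E − D) / E`; undefined when `E = 0`.
- benign pattern iff `U < 10` HU **or** (absolute > 60 **and** relative
  > 40); all comparisons strict. Lesion size (≥ 40 mm) is reported as an
  advisory flag only and never changes the class.

The enhanced and delayed measurements are caller-designated phases: the
formulas are protocol-agnostic, and nothing in the package assumes a
particular delayed acquisition time.

## The 32-feature radiomic signature

The signature is 5 first-order + 27 second-order features, the canonical
Haralick (GLCM) and Galloway (RLM) sets.

**Quantization.** Second-order features and the histogram entropy use
`Ng = 32` uniform bins spanning the VOI's `[min, max]` (the maximum maps
to level `Ng`; a constant VOI maps to level 1). Min–max binning makes all
quantized features invariant to constant HU offsets — only the first-order
mean moves when the whole VOI is shifted. `Ng` is configurable; 32 is a
common radiomics default that keeps co-occurrence matrices well populated
at the VOI sizes of adrenal lesions (hundreds to thousands of voxels).

**First order.** Mean and sample SD of the raw HU values; skewness
`m3/m2^1.5` and kurtosis `m4/m2²` as population central-moment ratios
(kurtosis is the raw ratio, ≈ 3 for a normal sample; no excess-3
correction); entropy `−Σ q log2 q` over the `Ng`-bin histogram. Skewness
and kurtosis fall back to 0 for a constant VOI.

**GLCM.** For each of the 13 unique nearest-neighbour 3D directions at
distance 1 (a 2D, 4-direction slice-wise mode is available because CT
slice thickness far exceeds in-plane spacing), ordered pairs of in-VOI
voxels separated by the offset are counted; pairs touching any voxel
outside the VOI are skipped. Counts are symmetrized, pooled over all
directions into a single matrix, and normalized. Offsets are in voxel
units; anisotropy of the voxel grid is deliberately ignored in the offset
geometry, matching common texture-tool behaviour. The 16 features are the
standard forms (autocorrelation, cluster prominence/shade, contrast,
correlation, difference entropy/variance, dissimilarity, energy, entropy,
inverse difference moment, maximum probability, sum average/entropy/
variance, variance). Logarithms are base 2 with `0·log 0 := 0`;
correlation is defined as 0 when a marginal variance vanishes. A VOI with
no co-occurring pairs (a single voxel) is an error, not a silent zero.

**RLM.** Per direction, every maximal collinear chain of in-VOI voxels is
decomposed into maximal equal-level runs (a voxel outside the VOI breaks
the chain); counts are pooled over directions. Each direction traverses
every VOI voxel exactly once, giving the accounting identity
`Σ j·r(i,j) = n_voxels` per direction, which the tests enforce. The 11
features are the Galloway set (SRE, LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE,
SRHGE, LRLGE, LRHGE), all normalized by the number of runs except run
percentage (runs per voxel traversed).

The exact membership of the 27 second-order features is a reconstruction
from the canonical Haralick/Galloway vocabularies — 16 + 11 is the only
partition consistent with the named features of the analysis this package
operationalizes — and the provenance columns (`n_grey`, `direction_mode`,
`distance`) record the conventions used for every extracted vector.
Numerical identity with any particular commercial texture tool is not
claimed.

Every GLCM/RLM feature is verified against an independent brute-force
oracle (explicit pair and run enumeration) to 1e-9 on dozens of random
small VOIs in the test suite.

## Statistics

- **Group comparisons** use the pooled-variance Student's t test by
  default (Welch behind a flag). Pooled is the variant that reproduces,
  from the printed `mean (s.d.)/n` summaries alone, the P values a
  clinical summary table of this design prints (0.001 for carcinoma vs
  adenoma densitometry; 0.003 and 0.027 for the diameter comparisons) —
  `t_from_summary()` exists precisely so such printed tables can be
  checked. χ² tests for 2×2 tables are plain Pearson without continuity
  correction (a correction flag exists).
- **Feature selection** tests each feature, per phase, as carcinoma versus
  the two benign groups *pooled* (a per-pair reading is possible but the
  pooled comparator is the default), and keeps `p < 0.05` strictly, with
  no multiplicity adjustment by default — matching how such pilot analyses
  are reported; Benjamini–Hochberg is available but off. Under the null
  the per-feature false-selection rate is calibrated (verified at 500
  simulated cohorts in the tests).
- **ROC/Youden.** The empirical ROC is evaluated at midpoints between
  adjacent distinct scores (plus ±∞), so the reported optimal cut-off is a
  half-way value such as 25.5 HU rather than an observed score. AUC is
  trapezoidal, which for the empirical curve equals the Mann–Whitney
  pairwise statistic with ties counted ½ (asserted against a brute-force
  pairwise count in the tests). Orientation is chosen so AUC ≥ 0.5 and
  recorded. When several thresholds attain the maximal Youden index the
  lowest is reported.

## Unsupervised arm

Features are z-scored per column (constant columns dropped with a
warning); k-means with `k = 2` runs on the **full** standardized feature
space — PCA is computed only to draw the 2D scatter, never as the
clustering input (a configurable alternative would be easy, but clustering
the raw standardized space is the more conservative default since it
injects no dimension-reduction choices into the result). Lloyd iterations
run to an assignment fixed point (cap 300) from 50 random restarts under a
fixed seed; restarts and seed are recorded in the result. Cluster-to-class
mapping maximizes total agreement, and detection rates are
`correct-in-class / class size`.

**Outlier flagging.** Real cohorts contain gross anomalies (e.g. massively
calcified carcinomas) that distort clustering; the package makes their
removal algorithmic rather than visual. Each subject's Euclidean distance
from a coordinate-wise median is thresholded at
`median(d) + k·MAD(d)` (normal-consistent MAD, default `k = 3`, single
pass). Two design points matter:

- *Distances are measured within class when labels are available.* With
  well-separated classes, a single global centre conflates class
  separation with outlyingness — the entire carcinoma cluster would be
  "far". An anomalous carcinoma is extreme relative to *other carcinomas*,
  and that is what the within-class distance captures. Without labels the
  rule falls back to one global pass.
- *The threshold is estimated from the pooled distances of all subjects*,
  not per group: median/MAD estimates from ten-subject groups are too
  unstable to threshold on.

Known limitation: with ~30 subjects and 32 features the within-class
distances are approximately χ-distributed and tightly concentrated, so
even a perfectly estimated median + 3·MAD threshold leaves roughly a 4 %
chance per cohort that some unremarkable subject exceeds it; threshold
estimation noise adds a little more. A rule of this form therefore
occasionally flags one extra subject alongside true gross anomalies — the
flagged list is always reported so such cases are visible, and `k_mad` is
configurable.

## Synthetic data

Two generators make the pipeline testable end to end with no patient data.
All randomness is driven by one integer seed per call; identical seeds
give byte-identical output.

**Lesion phantoms** (`generate_phantom()`). An ellipsoidal VOI inside a
configurable grid (default 28×28×10 voxels at 0.744×0.744×5 mm, the
unenhanced-CT geometry of adrenal protocols; the VOI holds ~2 500 voxels)
is filled with spatially correlated Gaussian texture: white noise smoothed
with a Gaussian kernel (σ = the correlation length, in voxels) and
rescaled so the realized VOI mean — and, without implants, the SD — equal
the configured targets exactly. Class presets follow the intensity
statistics of an adrenal series: carcinoma 33.4 (4.7) HU, adenoma
20.2 (9.2) HU, incidentaloma 2.8 (9.4) HU on unenhanced CT. Two choices
encode carcinoma heterogeneity:

- a shorter texture correlation length (1 voxel vs 2 for benign classes) —
  malignant tissue is spatially more disorganized;
- multifocal necrosis implants (default 15 % of the VOI): contiguous blobs
  of near-uniform necrotic fluid at 22 (2) HU. The narrow spread and the
  position of the necrotic mode *inside* the lesion's overall HU range
  matter: with min–max quantization, an implant that mostly *extends* the
  range coarsens the binning of the solid component and can paradoxically
  lower entropy, whereas fluid at ~22 HU below a ~33 HU solid component
  adds a genuine second histogram mode and boundary co-occurrences. Under
  these defaults carcinoma phantoms have higher GLCM entropy and lower
  inverse difference moment than adenoma phantoms, and necrotic lesions
  have strictly higher histogram entropy than their necrosis-free twins,
  verified by sign tests over 20 seeds in the suite.
- optional calcification specks (high HU, 300 (50)); the image-cohort
  generator gives a configurable number of carcinomas "massive"
  calcification (12 % of the VOI) to emulate gross outliers.

Contrast phases add a class-specific enhancement offset plus small
zero-mean correlated phase noise (so phases are not voxel-wise copies),
with the offsets solved from the class's washout pattern: carcinoma
30.0/16.5 %, adenoma 32.2/23.7 % (lipid-poor, washout-indeterminate —
deliberately so: the benign class that conventional rules cannot clear is
the interesting one), incidentaloma 63.3/46.5 % (benign pattern).

**Image cohorts** (`generate_phantom_cohort()`). One phantom per subject
at the study group sizes 10/9/11; each subject's mean densitometry is
drawn from its class distribution, truncated at the 10 HU lipid-rich/
lipid-poor boundary to mirror the inclusion criteria that define such
cohorts (operated lesions > 10 HU, surveillance incidentalomas < 10 HU).
Per-subject venous/delayed offsets are solved from a per-subject draw of
the class washout distribution, making the washout percentages exact by
construction for every subject (with fixed offsets, relative washout is
numerically unstable for lesions whose enhanced mean is near zero).

**Feature-table cohorts** (`generate_cohort()`). For statistical
calibration a faster generator draws 32 independent standard-normal
features per subject and phase, shifting the carcinoma centroid by
`separation` SDs per feature (default 5 — comfortably separable, the
regime in which cluster recovery should be perfect; 0 gives the exact
null). Optionally the first `n_outliers` carcinomas are displaced by ±15
SD per feature (random signs, constant across phases) as ground-truth
gross anomalies.

What the generators do **not** emulate: organ anatomy and neighbouring
structures, partial-volume effects at the lesion margin, beam hardening
and scanner noise spectra, enhancement heterogeneity (necrosis enhances
like viable tissue here), and inter-feature correlation structure in the
table generator. Passing tests therefore demonstrate the correctness and
calibration of the *computations*, not clinical performance on real CT.

## Problem sizes and numerical conventions

- Tests run phantoms at 28×28×10 (default) and 16×16×6 (pipeline
  round-trips), texture oracles at ≤ 6³ voxels with `Ng ≤ 8`, selection
  calibration at 500 null cohorts, power and recovery checks at 100–200
  cohorts; the full suite completes in well under a minute. The acceptance
  script simulates the complete 30-subject study at default geometry in a
  few seconds.
- Geometry tolerance for volume/mask pairing: 1e-3 mm. GLCM normalization
  and symmetry are exact up to floating point (asserted at 1e-9).
  Standardization and PCA identities are asserted at 1e-8–1e-9.
- Errors are typed conditions (`adrenomics_error_*`): geometry mismatches,
  empty VOIs, degenerate matrices, undefined washout, invalid specs and
  pipeline stage failures are distinct classes, never silent NAs — except
  `compare_features()`, which NA-flags zero-variance features with a
  warning so one degenerate column cannot abort a cohort analysis.
- Masks are required to be voxel-aligned with their volumes; there is no
  registration, resampling or world-coordinate handling. Each
  (phase, mask) pair is treated independently.

## Known limitations

- NIfTI only; DICOM series must be converted upstream.
- The 32-feature vocabulary is fixed; no filtered (wavelet/Laplacian),
  shape, or size-zone features.
- k is fixed at 2 by design; no model-based clustering or gap statistic.
- No AUC confidence intervals (DeLong) or multivariable models.
- The outlier rule's residual false-flag rate at small cohort sizes,
  discussed above.
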