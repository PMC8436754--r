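---
title: "Two-stage detection of covert brain lesions: models, phantoms and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage detection of covert brain lesions: models, phantoms and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In medically refractory focal epilepsy, surgery requires localising the
epileptogenic zone, yet in a substantial fraction of patients expert
visual reading of the MRI finds nothing ("MRI-negative" epilepsy). Subtle
structural and microstructural abnormalities often exist nonetheless, and
may be expressed across several MR contrasts at once — T1-weighted and
FLAIR intensities, diffusion-tensor metrics (AD, FA, RD), neurite density
(NODDI NDI), quantitative relaxometry, cortical thickness. `lesionstack`
implements a two-stage, lesion-type-agnostic detector over such
co-registered multimodal volumes, together with the synthetic phantoms,
cross-validation harness and stereo-EEG (SEEG) concordance protocol used
to validate it.

The package operates in a single common coordinate space: all volumes of
a subject must already be co-registered and resampled to one lattice
(registration, parcellation of real scans, and map fitting are upstream
preprocessing and out of scope). The phantom generator fabricates its
cohorts directly in that common space.

## The two-stage model

**Stage 1 — regional abnormality regressor (C1).** The brain is divided
into parcellated regions (157 in a whole-brain anatomical parcellation;
the desk-scale phantom default is 27). For each region we compute its
normalized volume (region volume / brain volume) and, for every modality,
the mean and standard deviation of intensities over three compartments:
the region *core* (the region deflated by 1 mm), the *inner shell* (the
1 mm layer inside the boundary) and the *outer shell* (the 1 mm layer of
brain tissue outside the boundary). Shells are computed with an exact
Euclidean distance transform in world millimetres, so anisotropic voxels
deflate by physical distance. Boundary compartments matter because many
epileptogenic lesions (blurred grey–white interfaces, dysplasias)
manifest at region boundaries. A gradient-boosted decision-tree ensemble
regresses these features onto the fraction of the region marked lesional
(0.1 for a region 10% inside the mask; 0 everywhere for controls).
Predictions, clipped to [0, 1], are rendered voxelwise as the regional
abnormality probability map (RAP).

*What C1 can and cannot learn.* The regressor has no explicit region
identifier; it recognises regions implicitly through their multimodal
appearance fingerprint, and learns what each looks like when normal. Two
consequences, both visible in the phantom experiments: positives in a
training cohort must cover each region with lesional examples several
times over, and regions whose baseline appearance resembles a shifted
version of another region bound the achievable specificity.

**Stage 2 — voxelwise classifier (C2).** For every brain voxel, the
feature vector concatenates, for each configured input volume (by
default: the RAP, T1, FLAIR, NDI, AD, FA, RD, and cortical thickness),
the intensity of the voxel and its six face neighbours in 3-D, plus the
voxel's parcellation label as spatial context — 7 × 8 + 1 = 57 features.
The label column is declared categorical so trees partition regions by
identity, never by label arithmetic. Neighbours outside the lattice or
the brain replicate the centre value; sentinel values would give the
trees spurious split points. A gradient-boosted classifier maps this to a
per-voxel probability of abnormality; thresholding (default 0.5) yields
the binary lesion mask. Quantitative relaxometry and susceptibility
contrasts can be confined to stage 1 via the per-stage modality lists:
regionally informative contrasts do not necessarily help voxelwise.

**Stacking by cross-fitting.** The RAP values that C2 sees during
training are *not* produced by the final C1: a first-stage model
evaluated on its own training subjects predicts the training targets
almost exactly, and a second stage trained on such maps learns to trust
them unconditionally — in piloting, the full stack then collapsed on
held-out subjects (LOOCV median Dice 0.00 on a region-lesion cohort
whose RAP-free counterpart scored 0.78). We therefore use grouped 5-fold
cross-fitting: training subjects are partitioned (stratified over
positives and controls) and each subject's RAP comes from a C1 fitted on
the other groups, so C2 sees first-stage output of honest, held-out
quality. The C1 shipped in the bundle, used for new subjects, is fitted
on all training subjects.

## Normalization and metrics

Raw structural contrasts (T1, FLAIR, SWI) carry arbitrary scanner units
and are z-scored over the brain mask (mean 0, SD 1, population divisor);
quantitative maps are already in physical units and pass through, and
the assignment is configurable. Overlap is scored with the Dice
coefficient, 2|A∩B|/(|A|+|B|), defined as 1 when both masks are empty so
control subjects are well-defined. Sensitivity and specificity are
counted within the brain mask only — air voxels would inflate
specificity meaninglessly.

## The phantom generator

The generator emulates the statistical structure the detectors assume,
not MR physics. A cohort is defined by a `phantom_config`: an
ellipsoidal "brain" inscribed in the lattice is partitioned into
contiguous regions (Voronoi cells of uniformly drawn seed points,
Euclidean in mm); each modality of each subject is its per-region mean
plus white Gaussian noise. Region means are drawn once per cohort and
shared across subjects, so region-specific normal appearance is a
learnable signal — the premise of stage 1. Cortical thickness is a
smooth positive field around 2.5 mm. Positives carry one planted lesion:
by default an axis-aligned ellipsoid with mean semi-axis drawn from 4–7
mm, centred at a random voxel of a random region (it may straddle
boundaries); alternatively a whole region (`lesion_style = "region"`)
for experiments probing the regional stage. The lesion shifts each
affected modality by `effect_size_sd` × that modality's noise SD.
Controls carry empty masks. Everything is deterministic given the seed.

Default study conditions (used by the acceptance experiments): a 48³
lattice at 1 mm, 27 regions, 20 positives and 20 controls, effect 3 SD
in FLAIR and NDI. With these defaults focal lesions occupy well under 5%
of the brain, matching the class imbalance a voxelwise detector faces;
whole-region lesions are a deliberately different regime (a region is
~4–12% of the brain depending on the parcellation) used only in the
stacking ablation. A `distractor` modality (zero regional structure,
unit noise, never lesion-affected) is available as a pure-noise channel
for ablation experiments.

What the phantoms do **not** emulate: partial-volume effects, spatially
correlated noise, registration error, bias fields, multi-subject
anatomical variability, or realistic lesion morphology. Passing the
phantom experiments shows the pipeline recovers the signal structure it
was designed for; it does not certify performance on real scans.

## Validation harness

Leave-one-out cross-validation iterates over the positive subjects;
controls are in every training fold and are never held out (control
evaluation is a separate specificity check — on held-out synthetic
controls we report the fraction of in-brain voxels above threshold).
Per-fold metrics are Dice, sensitivity, specificity and predicted vs
true lesion volume; cohort summaries are medians with type-7
(linear-interpolation) IQRs. Predicted and true lesion volumes are
compared with a two-tailed Mann-Whitney U test: exact by enumeration of
group assignments when n₁+n₂ ≤ 12 (ties through midranks), otherwise a
normal approximation with tie and continuity corrections.

The ablation harness re-runs the LOOCV with the RAP withheld from C2
(`no_c1`) or with one modality removed from both stages
(`minus_<modality>`), retraining from scratch per condition under
identical seeds and voxel samples — withholding an input, not zeroing a
feature.

Class imbalance is handled by seeded background subsampling: all
lesional voxels are kept, background is sampled at 10:1 per positive,
and each control contributes a fixed quota (default 1000). Both GBDT
stages run single-threaded with fixed seeds, so every harness run is
bit-for-bit reproducible.

## SEEG concordance

For patients whose MRI is read as normal, the reference standard is
SEEG. The package codifies the structured comparison as deterministic
rules (clinically these determinations are made by expert consensus; the
report is explicitly algorithmic): each electrode contact is a sphere of
10 mm diameter at its world-mm position; a contact overlaps the map when
an above-threshold voxel centre lies within the sphere radius
(inclusive); "areas" are face-connected components of the binary mask.
Five determinations are reported — seizure onset, early propagation and
interictal discharges within abnormal areas; abnormal areas sampled by
no contact; abnormal areas touched only by silent contacts — and the
subject is assigned Group A (an onset contact overlaps), B (onset
contacts exist, none overlaps) or C (no onset contact; SEEG
inconclusive). Overlap is geometric rather than a resampled sphere mask,
making it resolution-independent; enlarging the diameter can only turn
non-overlaps into overlaps.

## Numerical choices and degenerate inputs

- Shell convention: inclusive `≤ thickness` membership; a single-voxel
  region at 1 mm isotropic spacing has an empty core, itself as the
  inner shell, and its six face neighbours as the outer shell.
- Tiny regions whose 1 mm erosion empties a compartment fall back to
  whole-region statistics, flagged in a provenance column, keeping the
  feature table rectangular.
- C1 predictions are clipped to [0, 1]; the regressor itself is
  unconstrained.
- Default hyperparameters: C1 — 200 trees, depth 6, learning rate 0.05;
  C2 — 150 trees, depth 6, learning rate 0.08; both `hist`-method,
  single-threaded, seeded. These are configuration defaults, not tuned
  constants; the phantom experiments are insensitive to moderate changes.
- Degenerate inputs refuse loudly: constant in-mask images cannot be
  z-scored; an all-zero-target regional table cannot train C1; a
  single-class voxel matrix cannot train C2; empty truth masks make
  sensitivity `NaN` with a warning.
- Voronoi parcellations are redrawn (up to 50 times) until every region
  has ≥ 27 voxels; lesions are re-centred (up to 25 times) until the
  ellipsoid fits inside the brain.

## Problem sizes used by the shipped experiments

The test suite and the acceptance script run, as their main experiment,
LOOCV on the default 48³ / 27-region / 20+20 cohort at effect 3 SD, a
control-specificity check on 10 freshly synthesised controls, a
null-effect cohort (effect 0), and two ablation cohorts: focal
FLAIR-only lesions with a pure-noise distractor (40³, 18 regions,
10+8), and whole-region lesions (32³, 8 regions, 16+6, background ratio
4:1) affecting NDI at effect 1 SD with the NDI noise SD raised to twice
its between-region spread. That last choice puts the regional stage in
its intended regime: the lesion shift is large relative to
between-region baseline variation, so regional abnormality is learnable
with the two-to-three lesional examples per region that round-robin
coverage provides, while single-voxel contrast stays modest. These
sizes are the package's study conditions for desk-scale validation;
larger cohorts sharpen the same comparisons.

## Known limitations

- The appearance summary per compartment is mean + SD; richer summaries
  (percentiles, histograms) are pluggable but not implemented.
- The detector assumes one common space; nothing in the package
  registers images.
- Probabilities are the ensemble's native outputs, uncalibrated.
- The SEEG protocol is a codified surrogate for consensus visual
  reading; its geometric overlap rule is a stated convention, not a
  clinical standard.
- Phantom realism is deliberately limited (see above); cohort-level
  clinical figures from real patient data are out of the package's
  reach and are not reproduced.
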