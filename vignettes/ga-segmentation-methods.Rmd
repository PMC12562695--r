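---
title: "Methods: 3D-to-2D attention U-Net segmentation of geographic atrophy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D-to-2D attention U-Net segmentation of geographic atrophy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Geographic atrophy (GA) is the atrophic late stage of non-exudative
age-related macular degeneration: loss of the retinal pigment epithelium
(RPE), photoreceptors and choriocapillaris. On OCT, GA presents as complete
RPE and outer retinal atrophy (cRORA): the bright RPE band disappears and,
because the atrophic RPE no longer absorbs light, the choroid below brightens
markedly (hypertransmission). Clinically one wants the *en face* footprint of
the lesion and its area in mm², tracked over visits. Grading this manually
across dozens of B-scans per eye is impractical in routine care, which is why
automated segmentation of the en face GA map from the raw OCT volume is
useful.

`oct3d2d` implements such a segmenter end to end: a synthetic OCT generator
(so everything is testable without clinical data), preprocessing and quality
filtering, a 3D-encoder/2D-decoder attention U-Net, a combined
cross-entropy/Dice training recipe with early stopping, subject-grouped
k-fold cross-validation, and the agreement analysis used to validate this
class of models (Dice similarity coefficient, lesion-area r², Bland–Altman
limits of agreement, nAMD-stratified t-tests, longitudinal tracking).

# The network

The natural output space of GA segmentation is 2D (the en face plane spanned
by the lateral axis x and the B-scan index y) while the input is a 3D volume
with an axial depth axis z. The architecture therefore encodes in 3D and
decodes in 2D:

* **Encoder** — `levels` stages (default 4). Each stage applies a residual
  double 3×3×3 convolution block (two convolutions with ReLUs plus a 1×1×1
  projection shortcut) and then halves the resolution with 2× max pooling in
  x, y and z; once z is exhausted (z = 1) only x and y are pooled, which
  keeps toy geometries valid. Channel width starts at `baseChannels`
  (default 16) and doubles per level.
* **Axial collapse** — every encoder stage's output is reduced along z into
  the 2D skip connection. The reduction is a softmax attention over z: each
  channel has a learned logit scale `a` and offset `b`, the weights
  `softmax_z(a·f + b)` average the feature column, and a 1×1 channel-mixing
  convolution follows. At initialization `a = b = 0` and the mixing matrix is
  the identity, so the untrained collapse is exactly the mean over z; with
  z = 1 it is the single slice. The learned variant lets the network focus
  on the depth band where atrophy is actually imaged (the outer
  retina/choroid) — the design motivation for attention here. A
  plain mean-pooling ablation is available via zeroed collapse parameters.
* **Decoder** — 2D and mirror-symmetric: upsample 2× (nearest neighbour),
  gate the collapsed skip with an additive attention gate, concatenate, and
  apply a residual double 3×3 convolution block. The attention gate projects
  skip and gating signal to half the skip width, adds, applies ReLU, reduces
  to one channel and squashes to a per-pixel α ∈ [0, 1]; the output is
  skip ⊙ α.
* **nIR fusion** — Spectralis scans come with a near-infrared reflectance en
  face image. When `inChannels = 2`, the nIR image (resampled to mask
  resolution and z-scored) is concatenated to the finest decoder level and
  absorbed by one extra 3×3 convolution. Fusing in the 2D path was chosen
  because nIR is natively en face; broadcasting it over z into the 3D
  encoder would fabricate a depth axis it does not have.
* **Head** — a 1×1 convolution to one channel plus a logistic squashing
  gives the en face GA probability mask; thresholding at 0.5 (ties map to 1,
  making tests bit-exact) yields the binary mask.

With the stock device geometries the shapes are: Spectralis volumes
subsampled to 128×128×64 (z×x×y) produce 128×64 masks; Cirrus volumes
subsampled to 128×128×128 produce 128×128 masks.

Both attention mechanisms and the residual shortcuts carry ablation switches
(`useAttention`, `useResidual`); with both off the model degrades to a plain
3D-to-2D U-Net and still satisfies every shape/range contract.

## Initialization choices

Weights are He-initialized from the configuration seed; builds are
bit-reproducible. Two deliberate deviations from plain He init:

* the final 1×1 convolution starts at a tenth of the usual scale so initial
  probabilities sit near 0.5 and the cross-entropy is well conditioned;
* the attention-gate projections start *non-negative* with a +0.1 hidden
  bias. The gate's hidden width is half the skip width — for very narrow
  test networks a single unit — and its inputs are ReLU outputs, hence
  non-negative; a sign-symmetric init can then leave the unit dead at every
  pixel with exactly zero gradient forever. The non-negative start
  guarantees a live gate without constraining what training can learn.

# Training recipe

The loss is `w_ce · BCE + w_dice · (1 − (2Σpt + ε)/(Σp + Σt + ε))` with
ε = 1e−6 and default weights (1, 1): both terms matter, no canonical
weighting exists, and equal weighting is the neutral choice.
Optimization is AdamW (decoupled weight decay 1e−2, β = 0.9/0.999) at the
full-scale reference learning rate 5e−5, up to 450 epochs with batch
size 32. After every epoch the mean validation Dice score of the
binarized predictions is computed; training stops after `patience` (default
70) epochs without improvement and the best-epoch parameters are restored.
Early-stopping performance is judged on mean validation DSC — the headline
metric — and patience counts epochs, the conventional unit against a
450-epoch budget. The learning rate is warmed up linearly over the first
three epochs: GA masks are heavily class-imbalanced, and without warmup an
aggressive rate can push the output into the all-background local minimum
before the Dice term has a foothold, after which sigmoid saturation
starves it of gradient (observed on held-out synthetic folds). Validation splits are made at
subject granularity (⌈`valFraction`·n⌉ subjects), like the outer folds, so
no subject ever spans a train/validation boundary. Everything is
deterministic under the configuration seed, including shuffling. No data
augmentation is used.

Cross-validation deals subjects (shuffled by seed, then in decreasing
scan-count order, round-robin) onto folds, so repeat scans of one subject
can never appear on both sides of any split and scan counts stay balanced.

# The synthetic generator

No public GA OCT data with en face ground truth exists at the scale needed
for tests, so the package ships a device-parameterized generator. It
emulates exactly the features the segmentation task depends on:

* a layered retinal background — dark vitreous, two to three bright bands
  (inner retina, ellipsoid zone, RPE) whose depths drift smoothly across the
  en face plane, and a dim exponentially decaying choroid;
* multifocal lesions: unions of radially perturbed ellipses (equivalent
  radius 0.75–1.5 mm by default, 1–3 foci), rasterized on the anisotropic
  native en face grid;
* the cRORA phenotype inside the lesion footprint: 80% attenuation of the
  outer-retina/RPE band and 2.5× sub-RPE brightening, feathered over one
  pixel inside the boundary;
* longitudinal growth by anisotropic distance-transform dilation calibrated
  to an area increment (default 0.4 mm²/visit, the scale of typical GA
  progression over a few-month visit interval); per-eye area series
  are non-decreasing by construction, and growth that would exceed the field
  of view truncates with a flag;
* nAMD confounders on a configurable fraction of eyes (default 30%,
  typical of real-world GA cohorts, where roughly a third of eyes carry
  concurrent neovascular disease): dark intraretinal fluid
  pockets and bright fibrosis-like patches near the RPE whose slight sub-RPE
  brightening mimics hypertransmission outside the true lesion;
* multiplicative log-normal speckle (default σ = 0.2), mean-preserving;
* synthetic quality scores, drawn by default just above the device
  threshold so the inclusion filter acts only when configured to.

What it does **not** emulate: physical speckle statistics and the imaging
point-spread function, drusen and incomplete (iRORA) phenotypes, motion and
registration artifacts, vessel shadows, and real inter-grader ambiguity in
ground truth. Passing the synthetic acceptance suite therefore demonstrates
that the architecture, optimization and analysis machinery work end to end
on a task with the right geometry and contrast structure — it does not
certify clinical performance.

A well-posedness invariant keeps the task honest: on noise-free volumes,
simply thresholding the mean sub-RPE projection recovers the true mask with
DSC ≥ 0.7 (in practice ≈ 1.0), so the learning problem is solvable and a
model failure is a model failure.

# Device profiles and preprocessing

Stock profiles encode the two validated devices: Spectralis (49 B-scans of
512×496 px, quality index ≥ 25, nIR available) and Cirrus (200 B-scans of
200×1024 px, signal score ≥ 5, no nIR). Both use a 20° ≈ 6×6 mm macular
field of view; the printed "~6 mm²" descriptor is read as a 6 mm lateral
extent, the standard on-retina conversion. Quality thresholds are inclusive
("at least"). Volumes are trilinearly resampled to the network input dims
and z-scored per volume (no canonical normalization exists for this task;
per-volume standardization is robust to device gain differences). Ground-truth masks are resampled by exact area weighting
followed by a 0.5 threshold; this conserves the full-FOV area exactly and
any mask's area up to boundary-cell rounding. Lesion areas are measured at
output-mask resolution (pixel count × pixel area).

# Agreement analysis

Per scan: DSC between predicted and manual binary masks (two empty masks
score 1 — agreement on absence; the convention never arises in all-GA
cohorts but synthetic edge cases need it). Per cohort: squared Pearson
correlation between manual and automated areas; Bland–Altman bias and
limits of agreement on differences taken as manual − automated (matching
the usual plot orientation), with the sample (n−1) standard deviation;
pooled-variance Student t-tests comparing DSC between the GA-only and
GA-with-nAMD strata (the classical equal-variance test, not Welch); and a
Fisher-z test for the difference between the two strata's area
correlations, the standard test for comparing independent correlations.
α = 0.05 throughout, with no multiple-testing correction across the small
number of planned comparisons.
Connected-component counts (8-connectivity, the usual convention for en
face lesion counting) quantify the tendency of automated masks to coalesce
neighbouring small lesions.

# Desk-scale experiment sizes

The acceptance suite and `scripts/acceptance.R` replicate the study design
at sizes a single CPU handles in minutes, chosen once as the package's
reference experiment:

* geometry: Spectralis-like profile shrunk to native 96×64×32 with network
  input 32×32×16 (mask 32×16), same FOV and quality rules;
* cohort: 20 subjects × 1 eye × 3 visits, speckle 0.2, 30% nAMD eyes;
* reduced network: 3 levels, 8 base channels (≈ 9×10⁴ parameters);
* optimization: 20 epochs, patience 15, AdamW at 3e−3, batch 8 — the
  learning rate is scaled up from the full-scale default 5e−5 because the
  reduced network and small cohort need far fewer, larger steps;
* 5 folds, medians over three fixed seeds for stochastic checks.

Under these conditions the cross-validated mean test DSC and area r² land
well above the ≥ 0.8 / ≥ 0.9 acceptance bands, qualitatively mirroring the
agreement levels clinical validations of this model family report. The
capacity check (memorizing two scans to DSC > 0.95) uses the 64×64×32
reduced input. A deliberately corrupted nAMD stratum (multiplicative noise,
σ = 0.8, applied only to nAMD-scan volumes at evaluation time) reproduces
the directional stratified finding: the corrupted stratum's area
correlation falls below the clean stratum's.

# Known limitations

* Channel widths, level count and attention internals are declared design
  choices of this package; no attempt is made to reproduce any clinically
  deployed model's trained weights.
* The nIR fusion point (broadcast into the 3D encoder vs the 2D decoder)
  is an open design axis; this implementation fuses in the 2D decoder, as
  argued above.
* Training is single-device and double precision; there is no distributed
  path and no learning-rate schedule beyond a constant rate.
* Synthetic cohorts cannot stand in for clinical validation (see the
  generator's non-goals above); clinical performance of this class of
  models is established on private cohorts and is mirrored here only by
  qualitative, property-based checks.
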