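# oct3d2d — 3D-to-2D attention U-Net segmentation of geographic atrophy in OCT

Geographic atrophy (GA), the atrophic late stage of dry age-related macular
degeneration, appears on OCT as complete RPE and outer retinal atrophy
(cRORA): the bright RPE band vanishes and the choroid below brightens
(hypertransmission). Clinicians need the lesion's *en face* footprint and
its area in mm², tracked across visits — but manual grading over dozens of
B-scans per eye is impractical in routine care. `oct3d2d` is an R package
for ophthalmic image-analysis researchers that implements an automated
pipeline for this task, from raw volume to validated area measurements.

The core is a U-Net that **encodes in 3D and decodes in 2D**. Given a
volume `V ∈ R^(z×x×y)`, each encoder stage applies a residual double 3×3×3
convolution block and 2× pooling; every stage's skip connection is
collapsed along depth by learned softmax attention,

```
skip_2d(x,y,c) = Σ_z softmax_z(a_c f + b_c) · f(z,x,y,c),
```

followed by 1×1 channel mixing. The 2D decoder upsamples, gates each
collapsed skip with an additive attention gate `skip ⊙ α(skip, gating)`,
and a final 1×1 convolution with logistic squashing yields the en face GA
probability mask `P(x,y) ∈ [0,1]` (128×64 for Spectralis geometry,
128×128 for Cirrus; an optional near-infrared channel fuses into the
finest decoder level). Training minimizes

```
L = w_ce · BCE(P, T) + w_dice · (1 − (2Σ PT + ε)/(Σ P + Σ T + ε))
```

with AdamW and patience-based early stopping on validation Dice. Validation
follows the standard agreement battery: per-scan Dice similarity
(DSC = 2|A∩B|/(|A|+|B|)), lesion-area Pearson r², Bland–Altman bias and
limits of agreement (bias ± 1.96·sd of manual − automated), pooled Student
t-tests and a Fisher-z correlation comparison between GA-only and
GA-with-nAMD strata, and longitudinal area-versus-visit reporting — all
under subject-grouped k-fold cross-validation (no subject ever appears in
both train and test).

Because clinical GA cohorts are private, the package ships a
device-parameterized synthetic OCT generator (Spectralis-like and
Cirrus-like geometries) producing layered retinal backgrounds, multifocal
lesions with the cRORA contrast signature, programmed lesion growth,
nAMD-like confounders and speckle, with exact en face ground truth. The
network, backpropagation and AdamW are implemented in the package itself
(R orchestration over RcppArmadillo/BLAS convolution kernels), so the whole
pipeline runs on one CPU.

## Worked example

Generate a synthetic Spectralis-like cohort (desk-scale geometry: native
96×64×32 volumes, network input 32×32×16), run subject-grouped 5-fold
cross-validation with a reduced network, and inspect the agreement report:

```r
library(oct3d2d)

profile <- deviceProfile("spectralis", nativeDims = c(96L, 64L, 32L),
                         netInputDims = c(32L, 32L, 16L))
params <- syntheticParams(device = profile, nSubjects = 20L, visitsPerEye = 3L,
                          namdFraction = 0.3, seed = 42L)
cohort <- generateCohort(params, "ga-demo")

report <- crossValidate(cohort, profile,
                        netConfig(profile@netInputDims, levels = 3L,
                                  baseChannels = 8L, seed = 42L),
                        trainConfig(epochs = 20L, batchSize = 8L,
                                    patience = 15L, learningRate = 3e-3,
                                    seed = 42L),
                        nFolds = 5L, seed = 42L)
report
#> EvalReport: 60 scans, 5 folds
#>   mean DSC 0.914, area r^2 0.948
#>   Bland-Altman bias 0.114 mm^2, LOA [-1.372, 1.599]
#>   GA_only: n = 42, mean DSC 0.914, r^2 0.941
#>   GA_nAMD: n = 18, mean DSC 0.916, r^2 0.994
#>   p(DSC, pooled t) = 0.863; p(r^2, fisher-z) = 0.000158
```

Every scan is predicted exactly once by a model that never saw its subject.
Mean DSC is the average overlap between automated and ground-truth masks
(1 = perfect); area r² is the squared correlation between automated and
true lesion areas; the Bland–Altman row says automated areas are nearly
unbiased (manual − automated ≈ 0.1 mm²) with ≈±1.5 mm² limits of
agreement. The strata rows compare eyes with and without the synthetic
nAMD confounders: Dice scores are indistinguishable (pooled t, p ≈ 0.9)
while the area correlations happen to differ on this particular draw
(Fisher-z, p ≈ 2e-4) — with only 18 nAMD scans these stratified numbers
move noticeably between seeds. `plotAgreement(report)` draws the
scatter and Bland–Altman panels; `longitudinalReport()` applies a fixed
trained model to one eye's visit series; `writeEvalReport()` serializes the
report to JSON.

A thin command-line wrapper covers the same stages
(`inst/scripts/oct3d2d.R simulate|crossval|predict|evaluate|longitudinal`).

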