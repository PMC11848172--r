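---
title: "Staging Alzheimer's disease in Down syndrome from cortical structure: methods"
author: "cortexstage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging Alzheimer's disease in Down syndrome from cortical structure: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Adults with Down syndrome (DS) develop Alzheimer's disease (AD) pathology
with near-certainty from midlife, driven by triplication of the amyloid
precursor protein gene. Staging that pathology from structural MRI — telling
apart amyloid-negative cognitively stable (CS−), amyloid-positive cognitively
stable / preclinical (CS+), and amyloid-positive impaired (IMP+) adults — is
useful both clinically and for trial design. `cortexstage` implements a
data-driven *cortical signature* approach to that staging problem: derive a
set of surface vertices where cortical thickness separates two stages, use
each subject's mean thickness over that vertex set as a scalar biomarker, and
quantify staging performance by the area under the ROC curve (AUC). The same
ROC/effect-size machinery is applied to intracranial-volume-corrected
subcortical volumes, and effect-size maps can be compared across disease
variants (e.g. DS-associated versus autosomal-dominant AD) by Dice overlap
and spatial correlation.

The cohort this package's defaults emulate is restricted-access, so every
stage of the pipeline is exercised on synthetic cohorts whose demographic and
spatial-effect structure is configured to match the published summary
statistics. Nothing in the package requires a data download.

## The staging pipeline

1. **Stage labels.** Amyloid status comes from amyloid-PET burden on the
   centiloid scale with tracer-specific, inclusive positivity cut-offs
   (PiB: ≥ 16.4; florbetapir: ≥ 20.6). Stage labels combine amyloid and
   clinical status: CS− = (negative, stable), CS+ = (positive, stable),
   IMP+ = (positive, MCI or dementia). Everything else is excluded with an
   explicit reason (undetermined cognition, missing PET, impaired despite a
   negative scan); `assign_stage()` is total over its domain.
2. **Reference split.** A fraction (default 20%) of the CS− group is withheld
   from signature derivation and used only for ROC evaluation, so the
   reference group never evaluates signatures it helped derive. The
   derivation side takes `ceiling(0.8 * n)` members (85/21 at n = 106); the
   split is simple random (unstratified) with a balance report (Welch t for
   age/centiloid, two-proportion z for sex/APOE ε4).
3. **Smoothing.** Thickness maps are smoothed along the surface with a
   10 mm FWHM kernel before vertex-wise modelling (see *Numerical choices*).
4. **Vertex-wise model.** At every vertex, thickness is regressed on an
   intercept, a group indicator and covariates (age, sex; single shared
   slopes, no interactions). The group t map, two-sided p, adjusted
   mm-difference and Cohen's d (adjusted difference over pooled residual SD;
   a raw-SD variant is available behind `d_method`) are produced per
   hemisphere. Hemispheres are processed independently throughout.
5. **Candidate signatures.** The |t| map is thresholded at each element of a
   vertex-wise p grid (default 0.05, 0.01, 0.005, 0.001, 0.0005, 0.0001),
   suprathreshold vertices are clustered by mesh adjacency, and each
   cluster's surface area is referred to a permutation null of the *maximum*
   cluster area (Freedman–Lane residual permutation, 1000 permutations by
   default, cluster-wise p ≤ 0.001). Surviving clusters form one candidate
   signature per grid point; an empty result is recorded, not dropped, since
   signatures are evaluated on every stage contrast regardless of where they
   were derived.
6. **Scoring, evaluation, selection.** A subject's signature score is the
   area-weighted mean thickness over the signature vertices, both
   hemispheres pooled. Every candidate is evaluated on every comparison
   (AUC via the Mann–Whitney rank statistic with midrank ties; Welch t;
   Benjamini–Hochberg adjustment across the whole evaluation table), and the
   candidate with the best AUC per comparison is the *ideal* signature,
   exact ties going to the smaller mask. Orientation is fixed by convention:
   lower thickness (or volume) is read as more advanced, so an effect in the
   expected direction gives AUC ≥ 0.5.
7. **Subcortical volumes.** Regional volumes are head-size corrected by the
   residual method — per region and side, volume is regressed on ICV within
   the CS− reference group and adjusted along that slope — then staged with
   the same ROC machinery (smaller volume = more advanced). The residual
   method (rather than the ratio method) was chosen because it is exactly
   idempotent and leaves adjusted volumes uncorrelated with ICV in the
   reference group; fitting the slope in CS− only keeps disease effects out
   of the correction.
8. **Cross-variant comparison.** Effect-size maps of two variants are
   compared by thresholding each exported mm-difference map at ≥ 0.2 mm
   thinning (inclusive), computing the Dice coefficient 2|A∩B|/(|A|+|B|) on
   vertex counts (an area-weighted variant is reported alongside), category
   overlap maps, the A:B area ratio and containment, and the Spearman
   correlation of the raw maps ("rho" is read as Spearman by default;
   Pearson is a switch). Side B may be a bare map, since individual-level
   data for a comparison variant are often unavailable.

## Surface geometry

Real average-surface meshes are accepted through the I/O layer (FreeSurfer
binary surfaces, GIFTI), but all tests and defaults run on generated
icospheres: repeated 1-to-4 subdivision of an icosahedron projected to a
100 mm sphere. An order-k icosphere has 10·4^k + 2 vertices; order 7
(163,842) matches the vertex count of the standard average cortical surface
and order 4 (2,562) the resolution commonly used for downsampled map
comparison. Subdivision appends edge midpoints after the coarse vertices, so
vertex ordering is *nested* and downsampling between orders is subsetting.
Vertex areas follow the one-third-of-incident-triangle rule, making cluster
area exactly conservative. Within R, vertex indices are 1-based (the
language's convention); the on-disk formats keep their native 0-based
indices and the I/O layer converts.

## Smoothing: calibration, not exactness

Surface smoothing is iterated self-inclusive neighbour averaging (convex
relaxation steps `x ← (1−λ)x + λ·mean(neighbours)`), the same family of
kernels surface-analysis toolchains use, rather than an exact heat kernel.
The step count and λ are set from a random-walk variance argument: one step
contributes per-axis variance `c·λ·E[h²]/2` (h = edge length), with
`c = 0.70` an empirically calibrated step efficiency on icosphere meshes.
The package's contract is that the empirical kernel FWHM, measured on a unit
spike against geodesic distance, matches the request within 20%; the test
suite verifies this across mesh orders 3–5 and FWHM 10–40 mm. Requests below
the mean edge length cannot be honoured and return the input unchanged with
a warning. The operator is linear, fixes constants exactly, and never
expands the range of a map.

## The synthetic cohort generator

`cohort_config()` defaults encode the emulated study's structure: group
sizes 106/45/27; ages 36.20 (6.20), 48.91 (6.18), 51.93 (4.33) years;
centiloids 1.05 (7.42), 51.96 (23.82), 76.37 (35.32), truncated to the
correct side of the tracer threshold per group; male counts 54/28/19; APOE
ε4 carrier counts 22/6/8; a 15/12 MCI/dementia split inside IMP+; and a
PiB:florbetapir mix of 115:63. Sex and APOE hit their counts exactly
(shuffled assignment) so a default cohort reproduces the demographic table
rather than merely approximating it.

Thickness maps are built on shared left/right icospheres as

> baseline (2.5 mm) + smooth Gaussian noise + age slope · (age − mean age)
> − stage-dependent patch thinning,

with the noise field produced by smoothing white noise (20 mm FWHM) and
rescaling to an exact per-vertex SD of 0.25 mm. The emulated study reports
no within-group thickness variance; 0.25 mm spatial SD and a −0.005 mm/year
age slope are stated assumptions at the plausible end of adult cortical
morphometry, fixed once. Effects are geodesic-disc patches: a larger
"parietal-like" (30 mm radius) and smaller "temporal-like" (20 mm) patch per
hemisphere, thinning 0 / 0.10 / 0.40 mm across stages in the parietal patch
with right-hemisphere magnitudes 1.25× the left (the rightward asymmetry of
the emulated disease); magnitudes are generator defaults, not published
values. Subcortical volumes get region-specific stage shifts — hippocampus
declining monotonically, accumbens shifting almost entirely CS−→CS+, putamen
almost entirely CS+→IMP+, caudate nearly flat — plus proportional ICV
scaling and Gaussian noise. The default variant configuration
(`variant_config()`) stands in for a more focal, symmetric, milder disease
variant: one 18 mm parietal patch per hemisphere, equal on both sides,
0.45 mm deep at IMP+ — deep enough that its ≥ 0.2 mm thinning mask survives
10 mm smoothing, keeping the cross-variant overlap stage well-posed.

**What passing tests show, and what they do not.** The generator produces
smooth, patch-structured Gaussian fields. Recovery of its patches
demonstrates that the derivation/selection machinery is correct and
well-calibrated under known ground truth; it does not demonstrate
performance on real cortical data, where effects are not disc-shaped, noise
is not stationary, and registration error, scanner effects and
segmentation failures all intrude. The generator also makes no attempt at
longitudinal structure or PET image simulation. Because the evaluation
table's t tests (like the emulated analysis's) do not adjust for age, the
generator's age slope produces *true* score differences between
age-discrepant groups; null-calibration tests therefore set the slope to
zero so the global null genuinely holds.

## Numerical choices

- **Permutation p-values** are computed as `(1 + #{null ≥ observed}) /
  (n_perm + 1)`; 1000 permutations is exactly enough to resolve cluster-wise
  p ≤ 0.001, and a smaller `n_perm` triggers a resolution warning.
- **Ties**: AUC uses midranks; exact AUC ties in selection go to the smaller
  mask; the stored ROC curve's trapezoidal area reproduces the rank AUC to
  1e-9.
- **Degenerate inputs**: rank-deficient covariates (e.g. sex in a single-sex
  comparison) are dropped with a warning; empty signature masks make scoring
  error out but remain recorded candidates; two empty masks give Dice 1 by
  convention, flagged; constant maps make spatial correlation NA, flagged;
  an empty B mask makes the area ratio NA, flagged; thickness draws below
  0.5 mm are floored there with a warning.
- **Thresholds** are inclusive wherever the emulated analysis states "≥"
  (centiloid cut-offs, the 0.2 mm thinning threshold).
- **Welch t** is used for all scalar group tests (the variance assumption is
  never stated in the emulated analysis; unequal variances are the safer
  default), and Benjamini–Hochberg for FDR control.
- **AUC comparison** uses the DeLong test for paired markers and a bootstrap
  z test otherwise, with the method recorded in the output.

## Analysis sizes used by the test suite

The statistical acceptance tests run, per fresh session: family-wise error
of the permutation cluster correction over 200 null datasets (order-3
single-hemisphere mesh, n = 25 + 25, 199 permutations, vertex p 0.01,
cluster p 0.05); signature recovery over 25 default order-4 cohorts
(cluster p 0.01 with 250 permutations, satisfying the resolution
constraint); FDR behaviour over 30 null cohorts; and oracle equivalences
(brute-force AUC, per-vertex normal equations, flood-fill clustering,
step-up FDR) at small n. These sizes are the package's chosen compromise
between the tightness of binomial error bars and a test suite that runs in
minutes on one CPU.

## Known limitations

- Graph-shortest-path distances stand in for true geodesics on non-sphere
  meshes; on icospheres exact great-circle distances are used.
- Spherical registration, parcellation and any FreeSurfer execution are out
  of scope; the package consumes surfaces and maps, it does not make them.
- The withheld split applies only to the CS− group, mirroring the emulated
  design; comparisons not involving CS− reuse all subjects and can be
  optimistic — the same caveat the emulated analysis reports.
- Whether the original head-size correction pooled hemispheres, and which
  estimator its spatial "rho" used, is unstated there; this package corrects
  per side and defaults to Spearman, with switches.

## A minimal run

```{r example}
library(cortexstage)
cfg <- pipeline_config(
  cohort_config = cohort_config(mesh_order = 4L),
  variant = variant_config(mesh_order = 4L),
  seed = 1L)
report <- run_pipeline(cfg)
print(report)
report$evaluation          # candidate x comparison table with FDR-adjusted p
report$subcortical         # region x side x comparison staging table
report$summary             # JSON-serializable numbers only
```
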