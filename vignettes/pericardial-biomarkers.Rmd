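---
title: "Quantifying pericardial composition change after radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pericardial composition change after radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pericor)
```

## The problem

Radiation delivered to thoracic tumors inevitably reaches the heart, and
pericardial disease — effusion, fibrous thickening, constrictive
pericarditis, calcification — is a recognized late effect. On CT, these
tissue states occupy characteristic Hounsfield-unit (HU) ranges, so a
baseline planning CT and a deformably registered follow-up CT of the same
patient can be compared voxel by voxel to ask *what the pericardial
tissue turned into*, and whether that change tracks the local or mean
radiation dose and downstream clinical outcomes.

`pericor` implements that comparison as a reusable pipeline: region
construction from a heart mask, follow-up selection among candidate
scans, contrast-enhancement batch harmonization, three voxel-wise
composition-change biomarkers, and dose-correlation plus survival
statistics. A synthetic phantom-cohort generator stands in for patient
data so every stage is testable at desk scale.

## Regions: the pericardial shell and the reference ring

The pericardial sac is modeled as the outermost 4 mm layer *inside* the
heart mask. Human pericardium is often thinner than 4 mm, so this shell
knowingly includes some adjacent myocardium — which occupies the Fibrous
HU range and must be kept in mind when interpreting Fibrous-range
results. The shell depth is a parameter (`shell_thickness_mm`, default
4 mm).

Distances are Euclidean in millimeters with anisotropic voxel spacing,
computed by an exact separable distance transform in compiled code. The
mask boundary is modeled as the midpoints of the faces where mask and
complement meet. Among the simple digital-surface conventions this one
is the least biased: measuring to the nearest *outside voxel center*
overstates the distance by up to half a voxel (a 4 mm shell on a 20 mm
digital sphere at 1 mm spacing comes out about 5% small), while
measuring to whole faces or to the complement's voxel region lets cube
corners jut inward and understates it (about +10% on the same sphere).
With the face-midpoint convention the same shell lands within about 3%
of the analytic volume. A side effect worth knowing: a zero-thickness
shell is empty, because voxel centers sit at least half a voxel from any
face midpoint.

The *reference ring* — used only for follow-up selection — is the part
of a 5 cm annulus around the heart that received at most 1 Gy physical
dose. Out there, scanner and reconstruction-kernel differences shift the
HU distribution but radiotherapy cannot have, so the candidate follow-up
whose ring histogram is closest to the baseline's is the
best-acquisition-matched scan. Histograms use unit-width integer bins
spanning −1000 to 1000 HU (2001 bins; values are clamped to this range
at ingest), and the default distance is the L1 distance between
normalized histograms, with L2 and mean-HU alternatives available. Ties
break deterministically to the lowest candidate index.

## Dose: EQD2

Cohorts mix conventional fractionation with SBRT, so physical dose is
converted voxelwise to the equivalent dose in 2 Gy fractions before any
binning:

$$\mathrm{EQD2} = D \cdot \frac{d + \alpha/\beta}{2 + \alpha/\beta}$$

with total dose $D$ and per-fraction dose $d$. We default
$\alpha/\beta = 3$ Gy, the convention for late-responding cardiac
tissue; the value is configurable because no single choice is canonical.
Patients are grouped by mean pericardial EQD2 into the bins
[0, 0.2), [0.2, 2), [2, 5), [5, 12.5), [12.5, 20) and ≥20 Gy; the same
edges are applied per voxel where a voxel-level dose resolution is
needed.

## The three biomarkers

All three work on the shell voxels of a baseline/follow-up pair, with
$\Delta \mathrm{HU} = \mathrm{HU}_\text{baseline} -
\mathrm{HU}_\text{followup}$ computed on integerized HU (rounding half
away from zero). Tissue classes come from a fixed HU partition:
Calcification [130, 1000], Fibrous [65, 129], Heme [13, 64],
Fluid [−5, 12], Fat [−1000, −6]. These are composition *ranges*, not
diagnoses — each contains both normal and abnormal tissue.

**Per-HU-change volume curve.** For each integer $\Delta\mathrm{HU}$,
the percent of shell volume with exactly that change:

$$\Delta HUV_{P,\Delta\mathrm{HU}} = 100 \cdot
\frac{\sum_{\vartheta \in \Delta\mathrm{HU}} V_\vartheta}
     {\sum_\vartheta V_\vartheta}.$$

The division by the patient's total shell volume removes normal
inter-visit heart-size variation; the curve sums to 100 by construction,
which the tests assert at 1e−6. Cohort curves are unweighted means of
patient curves within each mean-dose bin.

**Per-tissue mass change.** Mass is proxied linearly as
$(\mathrm{HU} + 1000) \times V$ — no physical density calibration is
applied, so values are relative, which is all the within-patient
comparison needs. For tissue class $T$ and voxel-dose bin $D$:

$$VMC_{P,T,D} = 100 \cdot
\frac{\sum_{\vartheta \in D \cap T} \Delta\mathrm{HU}(\vartheta)\, V_\vartheta}
     {\sum_\vartheta (\mathrm{HU}_{\text{baseline},\vartheta} + 1000)\, V_\vartheta}.$$

The denominator is the patient's *total* baseline shell mass proxy, not
the per-cell mass, so cells are comparable within a patient. Positive
values mean mass decreased from baseline to follow-up. The tissue class
of a voxel is read at follow-up by default (what the voxel became);
baseline labeling is available via `label_timepoint`.

**Per-tissue volume change.** The percent of shell volume that left or
entered each class:

$$\Delta V_{P,T} = 100 \cdot
\frac{V_T(\text{baseline}) - V_T(\text{followup})}{\sum_\vartheta V_\vartheta}.$$

Because every voxel has exactly one label at each timepoint and the
shell is fixed, $\sum_T \Delta V_{P,T} = 0$ exactly — a conservation
property the tests check on random inputs.

Curves can be smoothed with a centered moving average (default window 11
bins, odd by construction) whose window shrinks symmetrically at the
edges so output length equals input length and constants are preserved.
Results are kept both raw and smoothed; the window is a display choice,
not part of the statistics.

## Contrast-enhancement harmonization

Iodinated contrast shifts soft-tissue and blood-pool HU, and cohorts mix
enhanced and non-enhanced acquisitions, so biomarker features carry a
batch effect. `pericor` implements location/scale (ComBat-style)
harmonization: features are standardized to pooled mean/variance,
per-batch additive and multiplicative effects are estimated, optionally
shrunk across features by parametric empirical Bayes (normal prior on
the location effect, inverse-gamma on the scale effect, hyperparameters
by method of moments, iterated conditional updates to 1e−6 or 500
iterations), then removed.

Batch schemes mirror the acquisition structure: analyses of baseline
images alone use two batches (enhanced / non-enhanced); longitudinal
biomarkers use four (both non-enhanced; both enhanced; baseline only;
follow-up only). What gets harmonized is configurable
(`harmonize_target`): per-image histogram bins, or — the pipeline
default — the pair-level biomarker feature vector (mean HU shift,
per-tissue volume and mass changes). The choice of pair-level features
for the four-batch scheme is a design decision of this package, made
because the feature set entering the longitudinal analyses is exactly
what the downstream statistics consume.

Implementation details that matter for reproducibility: per-batch scale
estimates use maximum-likelihood (n) denominators consistent with the
pooled variance, which makes the non-shrinkage mode an exact projection
— harmonizing twice changes nothing (the tests assert < 1e−6). Features
with pooled variance below 1e−12 (structurally empty histogram bins)
bypass harmonization bit-identically. The per-feature grand mean of the
output is re-anchored to the input's. No covariates are preserved
through harmonization; in particular dose is *not* regressed out. A
batch with a single sample is an error, named in the message.

## Clinical endpoints and statistics

Cardiovascular events are diagnosis-registry entries with ICD-10
category I20–I25 (ischaemic heart disease) or I50 (heart failure),
matched by 3-character category so subcodes count. Registry streams
repeat entries; events separated by at most 28 days are collapsed
greedily to the first entry of each cluster, anchored at the last kept
event. The survival clock starts at the end of radiotherapy; an event on
the RT end date itself counts as pre-RT (strict inequality — the
boundary convention is explicit because registries do record same-day
entries). Time to first post-RT cardiovascular diagnosis is censored at
death or last follow-up.

Dose correlations use Spearman rank correlation (average ranks for ties;
t approximation for n ≥ 10, exhaustive permutation below that) or
Pearson where linearity is the question. Survival contrasts dichotomize
each covariate at the cohort mean (values equal to the mean go to the
"low" group, deterministically), then apply Kaplan–Meier curves, the
two-sample log-rank test, and a univariable proportional-hazards fit
with Breslow tie handling for the hazard ratio with a Wald 95% CI. When
one group has no events the hazard ratio is reported as non-estimable
with a flag — never as an infinity. No multiplicity correction is
applied by default, matching per-panel reporting; a Benjamini–Hochberg
adjustment can be applied downstream if many covariates are screened.

## The synthetic cohort

The generator builds what the analysis *assumes*, not what anatomy looks
like: an ellipsoidal heart (semi-axes 28/24/22 mm) on a 48³ grid at 2 mm
spacing; an exponential dose falloff (length 25 mm) from a tumor seed
whose distance from the heart varies per patient, spreading mean
pericardial EQD2 across all six dose bins; fraction schedules drawn from
{33×2, 3×22.3, 5×10, 8×7, 30×1.5} Gy to exercise the EQD2 conversion;
shell voxels drawn from the five composition classes (Fat 0.35,
Fluid 0.20, Heme 0.25, Fibrous 0.18, Calcification 0.02), uniform HU
within each class range plus 3 HU Gaussian texture.

The planted dose effect moves a shell voxel one class up the density
ladder Fluid → Heme → Fibrous → Calcification at follow-up with
probability $\min(1, \beta \cdot \mathrm{EQD2}/100)$, $\beta = 0.5$ by
default. Single-step moves keep the planted effect identifiable; Fat
participates in noise but not the ladder, because fat change is
confounded by overall weight change in cancer patients. Contrast
enhancement adds +25 HU (optionally a multiplicative factor) to enhanced
images; each follow-up exists in three candidate reconstructions with
kernel noise σ = 5, 20 and 40 HU in shuffled order, exactly one being
the matched-kernel scan. Outcomes are exponential survival with
log-hazard raised by θ = log 2 for the high-biomarker group, plus a
Poisson cardiovascular-diagnosis stream with a higher rate in that
group, pre-RT history events, registry duplicates and non-CVD noise
codes to exercise the event rules.

What the phantom does *not* emulate: anatomy (no chambers, vessels or
lungs), scanner physics (no beam hardening, partial volume or noise
texture correlation), respiratory or cardiac motion, and registration
error — inputs are generated aligned, as the pipeline assumes
registration happened upstream. Passing tests therefore demonstrate
that the *computational machinery* is correct and recovers planted
effects under the stated statistical structure; they do not validate
the biology or the registration step on real data.

## Numerical choices and degenerate inputs

- HU are clamped to [−1000, 1000] at ingest and integerized
  half-away-from-zero before binning or labeling.
- A shell whose baseline is uniformly −1000 has zero mass proxy and is
  rejected as degenerate rather than dividing by zero.
- Dose bins are left-closed, right-open; the last bin is unbounded.
- Empty dose bins are absent from aggregates, not zero-filled.
- Pipeline randomness flows from one master seed recorded in the run
  manifest; reruns with identical inputs and config are bit-identical,
  which the tests verify by hashing every CSV.
- Patients failing validation are skipped with a logged reason; more
  than 50% failures aborts the run.

## Problem sizes used in the checks

The test-suite and acceptance checks run at sizes chosen to make each
property measurable in minutes on one core: conservation on 200 random
toy patients; brute-force oracle equivalence on 50 toy patients of up to
1000 voxels; dose-response recovery on 20 cohorts of 60 phantoms each at
β = 0.5 (and 20 at β = 0 as the negative control); harmonization on 50
samples per batch; follow-up selection on 100 noise replicates;
hazard-ratio recovery at 500 patients per arm with 200 null log-rank
replicates; and determinism on a 20-phantom pipeline rerun.

## Known limitations

- The 4 mm inner shell mixes pericardium with myocardium by design;
  per-tissue results in the Fibrous range partly reflect that mixture.
- The mass proxy is linear in HU with no density calibration, so mass
  changes are relative quantities.
- Voxel-level dose bins reuse the cohort mean-dose edges.
- Whether harmonization is best applied to histograms or to pair-level
  biomarker features is genuinely open; both are implemented and the
  default is declared, not claimed canonical.
- No connected-component or spatial-cluster analysis of changed voxels
  is attempted, and no competing-risk or multivariable survival
  modeling is included.
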