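# pericor

Voxel-wise pericardial composition-change biomarkers from paired
baseline/follow-up CT, for studying late cardiac effects of thoracic
radiotherapy.

Radiation reaching the heart can turn pericardial tissue into something
else — effusion, fibrous thickening, calcification — and on CT those
states occupy characteristic Hounsfield-unit (HU) ranges. Given a
planning CT, one or more deformably registered follow-up CTs, a heart
mask and a dose grid per patient, `pericor` quantifies what the
pericardial tissue became, whether the change tracks dose, and whether
it predicts survival or cardiovascular events. It is aimed at
radiotherapy outcomes researchers with registered image pairs in hand;
registration and heart contouring themselves are out of scope.

## What it computes

The pericardium is modeled as the outermost 4 mm layer of the heart
mask (the shell ϑ). With ΔHU = HU_baseline − HU_followup per shell
voxel, voxel volume V, and tissue classes T from a fixed HU partition
(Calcification ≥ 130, Fibrous 65–129, Heme 13–64, Fluid −5–12,
Fat ≤ −6), three biomarkers are computed per patient:

- **ΔHUV** — percent shell volume at each integer HU change:
  `ΔHUV(ΔHU) = 100 · Σ_{ϑ∈ΔHU} V_ϑ / Σ_ϑ V_ϑ` (sums to 100).
- **VMC** — percent mass change per tissue class and voxel-dose bin,
  mass proxied by (HU + 1000)·V:
  `VMC(T, D) = 100 · Σ_{ϑ∈T∩D} ΔHU(ϑ)·V_ϑ / Σ_ϑ (HU_base,ϑ+1000)·V_ϑ`;
  positive = mass loss.
- **ΔV** — percent shell volume leaving each class:
  `ΔV(T) = 100 · (V_T(base) − V_T(followup)) / Σ_ϑ V_ϑ` (sums to 0).

Around these sit: follow-up selection by HU-histogram distance in a
5 cm / ≤1 Gy out-of-field ring, voxelwise EQD2 conversion
(α/β = 3 Gy default), ComBat-style location/scale harmonization of
contrast-enhancement batches, Spearman/Pearson dose correlations, and
Kaplan–Meier / log-rank / Cox hazard-ratio survival contrasts with
mean-split grouping. A synthetic phantom-cohort generator with planted
dose effects and outcomes makes the whole pipeline testable without
patient data. The methods vignette
(`vignettes/pericardial-biomarkers.Rmd`) documents every model choice.

## Worked example

```r
library(pericor)

co  <- generate_cohort(cohort_config(n_patients = 30, seed = 42))
man <- run_pipeline(co, pipeline_config(), out_dir = "run")

read.csv("run/results_dose.csv")
#>               biomarker     rho        p  n
#> 1          upward_shift  0.7050 1.36e-05 30
#> 2 delta_v_Calcification -0.3030 1.04e-01 30
#> 3       delta_v_Fibrous  0.0734 7.00e-01 30
#> ...
```

`upward_shift` is the mean HU gain of a patient's shell (the negated
mean of the ΔHUV curve): tissue moving toward denser composition
classes. The phantom plants exactly that as a dose effect, and the
pipeline recovers it — Spearman rho 0.71 against mean pericardial EQD2,
p = 1.4e-05 across 30 phantoms — while per-tissue ΔV correlations stay
weak at this cohort size. Per-patient output:

```r
head(read.csv("run/patient_summary.csv"), 4)
#>   patient_id mean_pericardium_dose_gy upward_shift  batch
#> 1       P001                    0.101      25.3384 Batch4
#> 2       P002                    1.167     -24.0102 Batch3
#> 3       P003                    0.046      24.7573 Batch4
#> 4       P004                    0.101      -0.0272 Batch2
```

The raw `upward_shift` of patients P001–P003 is dominated by the ±25 HU
contrast-enhancement offset (Batch3 = baseline enhanced only, Batch4 =
follow-up enhanced only); the four-batch harmonization step removes
this before the statistics, which is the point of carrying the batch
column. Survival contrasts land in `run/results_survival.csv` (log-rank
p, hazard ratio and 95% CI per covariate and endpoint), per-patient
curves in `delta_huv.csv` / `vmc.csv` / `delta_v.csv`, cohort per-dose-
bin mean curves in `cohort_delta_huv.csv`, and a manifest with config
hash and patient accounting in `manifest.json`.

A shell front-end covers simulation and analysis without writing R:

```sh
exec/pericor simulate --out cohort --seed 7
exec/pericor run --cohort cohort --out run --subset "diagnosis == 'NSCLC'"
```

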