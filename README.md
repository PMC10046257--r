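# mammorisk

Hybrid fuzzy–statistical clinical decision support for breast-cancer
screening risk, working from the structured descriptors of a BI-RADS
mammography report (never from pixel data).

## Who this is for

Breast-cancer screening programs interpret mammograms through the
BI-RADS lexicon: a radiologist annotates masses (shape, margins,
density), calcifications (type, shape, distribution), asymmetries and
architectural distortion, breast tissue density, and assigns a 0–6
suspicion category. `mammorisk` is aimed at clinical-informatics teams
who want a transparent, auditable risk score built on those annotations
plus basic patient data (age, personal and family history), with every
intermediate quantity exposed so the medical team can see *why* a
patient was flagged.

## The model

Two inferential arms run concurrently and are then aggregated:

* **Symbolic Risks** `R1, R2, R3 ∈ [0, 100]` — three Mamdani fuzzy
  expert systems (singleton antecedents over the categorical
  descriptors; triangular consequents on [0, 100]; MIN implication,
  MAX aggregation, centroid defuzzification) score the three finding
  groups: masses, calcifications, asymmetries/distortion. A risk is
  *null* exactly when its finding group is absent from the mammogram.
  The rule bases ship as editable YAML files and can be replaced by a
  medical team's own rules.
* **Statistical Risk** `Rs ∈ [0, 100]` — a bagged decision-tree
  ensemble trained on all descriptors *except* the radiologist's
  BI-RADS category, with Min-Max normalized age
  `t' = (t − min t)/(max t − min t)` and SMOTE-NC augmentation to 200
  cases per class (k = 5 neighbours). `Rs` is the ensemble's
  cancer-class probability × 100.

The **Global Risk** aggregates them,

```
RG = (ω1·R1 + ω2·R2 + ω3·R3) · log10(Rs),   capped at 100,
```

where null risks carry weight 0 and their base weight (default equal
thirds) is redistributed equitably among the remaining ones. The
**Corrected Global Risk** `RG' = min(RG · Fp, 100)` rescales `RG` by a
BI-RADS-ordered weighting factor `Fp` (categories 1–2 attenuate, 3–4C
amplify with a cap, 5–6 saturate to 100), pulling the score toward
standard diagnostic practice. Finally `RG'` maps to a warning state:
healthy (< 40), dubious ([40, 60)), potential case (≥ 60), each with a
recommendation.

## Worked example

```r
library(mammorisk)

# a synthetic screening cohort with the study-design imbalance (21/109)
cohort <- generate_cohort(seed = 42)
model  <- train_classifier(encode_features(cohort), seed = 42)
model
#> <risk_classifier> bagged trees (100 trees), trained on 130 patients
#>   5-fold cross-validated AUC: 0.945

# the published case-study patient: irregular spiculated mass +
# grouped coarse-heterogeneous calcifications, BI-RADS 4B
profile <- risk_profile(case_study_patient(), model)
profile
#> <risk_profile> case-study (BI-RADS 4B)
#>   Symbolic Risks: R1 = 91.67, R2 = 75.00, R3 = null
#>   weights: (0.500, 0.500, 0.000)   Statistical Risk Rs = 9.00
#>   Global Risk = 79.52   Fp = 1.2575   Corrected Global Risk = 100.00
#>   state: potential -- Perform confirmatory tests.
```

The absent asymmetry/distortion group nulls `R3`, so the equal base
weights redistribute to (0.5, 0.5, 0). With the published component
risks (produced by the original study's own rule bases and model,
shipped here as `reference_risk_fixture()`) the aggregation reproduces
the printed worked example exactly:

```r
fx <- reference_risk_fixture()
risk_profile(case_study_patient(),
             override = c(unclass(fx$risks)[c("R1", "R2")], list(Rs = fx$Rs)))
#> <risk_profile> case-study (BI-RADS 4B)
#>   Symbolic Risks: R1 = 89.97, R2 = 99.98, R3 = null
#>   weights: (0.500, 0.500, 0.000)   Statistical Risk Rs = 25.61
#>   Global Risk = 100.00   Fp = 1.0000   Corrected Global Risk = 100.00
#>   state: potential -- Perform confirmatory tests.
```

A command-line wrapper covers the same flow
(`generate-cohort`, `train`, `assess`, `evaluate`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "mammorisk.R", package = "mammorisk"))')" \
    generate-cohort --out cohort.csv --seed 7
```

## Scope

The package consumes radiologist-annotated descriptors only — no DICOM
or image processing, and no health-record connectors. The bundled rule
bases are defensible defaults derived from documented suspicion
orderings of the BI-RADS lexicon, intended to be reviewed and replaced
by each medical team; see `vignette("mammorisk-methods")` for the full
methodological account.
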