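---
title: "Methods: hybrid symbolic-statistical breast-cancer risk assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid symbolic-statistical breast-cancer risk assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammorisk)
```

## The problem and the pipeline

Population mammography screening assigns each examined patient a
BI-RADS report: categorical descriptors of the findings (masses,
calcifications, asymmetries, architectural distortion), the breast
tissue density, and a 0–6 suspicion category. Interpreting these
reports consistently requires considerable expertise, and the final
BI-RADS category carries substantial inter-reader variability.
`mammorisk` implements a decision-support pipeline that separates the
*evidence* in the report from the *expert's categorical judgment*:

1. **Stage 1 — data collection.** A patient record holds age, personal
   and family history, the finding descriptors, and the BI-RADS
   category (`validate_record()`, `read_cohort()`).
2. **Stage 2 — concurrent inference.** Three Mamdani fuzzy expert
   systems produce per-finding-group *Symbolic Risks* (`assess_all()`);
   a bagged-trees classifier trained without the BI-RADS category
   produces the *Statistical Risk* (`predict_statistical_risk()`); the
   two arms aggregate into the *Global Risk* (`global_risk()`).
3. **Stage 3 — correction.** The Global Risk is rescaled by a
   BI-RADS-ordered weighting factor into the *Corrected Global Risk*
   (`correction_factor()`, `corrected_global_risk()`), pulling the
   score toward standard diagnostic practice without feeding the
   BI-RADS category into the inference itself.
4. **Stage 4 — warnings.** Thresholds map the corrected risk to
   healthy / dubious / potential states with recommendations
   (`classify_state()`).

## The fuzzy arm

All antecedents are categorical, so each input variable uses singleton
membership functions: a rule clause `shape = irregular` has membership
1 exactly when the observed shape is irregular. The rule connective is
AND, interpreted as MIN (with singletons, a rule therefore fires at
strength 1 or 0). Consequents are normal, convex triangular sets on the
risk universe [0, 100]; rule firing clips each consequent triangle at
the rule's strength (MIN implication), clipped sets combine by
pointwise MAX, and the crisp risk is the centroid of the aggregate.

Numerical choices:

* The centroid is integrated by the trapezoid rule on 2001 uniformly
  spaced points (`resolution` in the engine config, adjustable per rule
  base). At this resolution the engine agrees with a 200,001-point
  reference integration to better than $10^{-3}$ on the shipped
  consequent family — the suite checks this against an independently
  coded oracle.
* Five ordered consequent labels (very-low … very-high) peak at 0, 25,
  50, 75, 100 with half-width 25; the two shoulder triangles are
  clipped at the universe edges, so their centroids sit at ≈ 8.33 and
  ≈ 91.67 rather than at the peaks. A single interior label fired at
  full strength defuzzifies exactly to its peak.
* When several rules share a consequent label, the label's strength is
  the MAX of their firing strengths, consistent with MAX aggregation.

**Rule bases.** The three shipped rule bases (masses; calcifications;
asymmetry and distortion) are *generated defaults*, not clinically
validated rules. Each antecedent category carries a documented ordinal
suspicion score (`suspicion_ordinals()`): e.g. mass shape
none < oval = round < lobulated < irregular; margins circumscribed <
obscured < micro-lobulated < indistinct < spiculated; typically benign
calcification shapes score 1 while amorphous/coarse-heterogeneous score
3 and fine pleomorphic / fine linear (branching) score 4–5. Mass
density was treated as a minor modifier (scores 0–2): nothing in the
lexicon suggests density should dominate shape or margins, so it only
nudges the total. A rule is emitted for every point of the categorical
grid — 120, 270 and 48 rules respectively — mapping the normalized
score sum onto the five labels by equal-width bins. This construction
guarantees two properties the tests verify exhaustively: *totality*
(every input combination fires a rule) and *ordinal monotonicity*
(raising any one descriptor to a more suspicious category never lowers
the risk). The YAML files under `inst/extdata/rules/` are the canonical
interface for replacing these defaults with a team's own rules.

**Null risks.** A Symbolic Risk is null *iff* its finding group is
absent (for the third system, only when both asymmetry and distortion
are absent). Absence is decided by the present/absent flags, never by a
small computed risk: a present but benign-looking finding legitimately
scores low without being null.

## The statistical arm

Features are all record descriptors except the BI-RADS category
(excluded by design so the statistical arm remains independent of the
expert's categorical judgment) and except identifiers. Age, the only
numeric feature, is Min-Max normalized with bounds taken from the
training cohort; out-of-range ages at scoring time are clipped to
[0, 1] with a warning.

The 21/109 class imbalance is handled with SMOTE-NC: synthetic
minority rows interpolate the numeric features between a seed row and
one of its k = 5 nearest same-class neighbours, while each categorical
feature takes the majority value among those neighbours (ties prefer
the seed's value, then vocabulary order). Neighbour distances are
Euclidean on the numerics plus, per categorical mismatch, the squared
median of the numeric features' standard deviations. Both classes are
brought to exactly 200 rows; originals are never modified.

The classifier is a bootstrap-aggregated tree ensemble — a random
forest with `mtry` equal to the number of features, i.e. bagging
without random feature subsetting — with 100 trees by default (the
ensemble size is a free choice; 100 is comfortably past the
plateau for 16 features and 400 training rows). Performance is
estimated by stratified 5-fold cross-validation, and **augmentation
runs inside each training fold only**: synthetic rows are built from
training patients exclusively, so no information about held-out
patients leaks into the model that scores them. The alternative
ordering — augment first, split later — yields optimistic AUCs because
each held-out synthetic row has near-twins in training; published
figures obtained that way are not comparable to this package's CV AUC.

## Aggregation, correction and states

With base weights $\omega = (\tfrac13, \tfrac13, \tfrac13)$ (a medical
team can override them), null risks get weight 0 and their base weight
is redistributed equally among the remaining risks. Then

$$R_G = \min\bigl(100,\; (\omega_1 R_1 + \omega_2 R_2 + \omega_3 R_3)
\cdot \log_{10} R_s\bigr).$$

The logarithmic term multiplies the whole weighted sum — the worked
example in the tests (two non-null risks ≈ 90 and 100, $R_s = 25.61$,
raw product ≈ 133.7 → capped at 100) pins down this precedence.
$R_s$ is floored at 1 before the logarithm: the statistical term is
risk-*increasing* by design, and a negative log for $R_s < 1$ would
turn weak statistical evidence into negative risk.

The correction factor, with $f(R_G) = 10/(R_G + 10)$ and the numeric
BI-RADS levels $\{1, 2, 3, 4A, 4B, 4C, 5, 6\} \to \{1, \dots, 8\}$
(ordinal positions; configurable — the published worked example is
insensitive to the sub-category numbering):

| BI-RADS | branch | $F_p$ |
|---|---|---|
| 1, 2 | attenuate | $1/(k + f(R_G))$, $k = -\text{level} + 3.5$ |
| 3, 4A, 4B, 4C | amplify | $t + f(R_G)$, $t = \text{level} - 1.5$, capped at $F_c = 100/R_G$ when $F_c \le F_p$ |
| 5, 6 | saturate | $100/R_G$ |

so BI-RADS 5–6 always drive the corrected risk to 100, the amplify
branch can never push it past 100, and categories 1–2 always shrink it
($k \ge 1.5$, $f > 0 \Rightarrow F_p < 1$). Degenerate inputs:
BI-RADS 0 (incomplete study) has no defined correction and is an
error; $R_G = 0$ skips the correction with $F_p = 1$ and a warning.
A findings-free mammogram (all three groups absent) never enters the
aggregation at all — the profile reports $R_G = 0$, state healthy,
with an explicit "no findings" annotation, since weight redistribution
is undefined with nothing to redistribute to.

States use half-open thresholds on the corrected risk: healthy < 40 ≤
dubious < 60 ≤ potential (configurable). At the default evaluation
operating point (60, the potential-case boundary) dubious cases count
as negative.

## The synthetic cohort generator

No patient-level data ship with the package; `generate_cohort()`
emulates the *design* of the development study — 130 patients, 21
biopsy-confirmed cancers, mean age 55.2 (sd 10, truncated to 25–95) —
and plants a controllable monotone association between suspicious
descriptor values and the cancer label. Each patient draws a latent
liability $z \sim N(0,1)$; labels go to the top-`n_cancer` liabilities
(exact counts, optionally degraded by count-preserving noise swaps);
present/absent flags follow logistic links in $z$; categorical
descriptors are sampled with weights $\exp(\text{effect\_size} \cdot z
\cdot s/s_{\max})$ over their suspicion ordinals $s$; the BI-RADS
category mixes a liability-quantile assignment with a label-informed
one (`birads_informativeness`, default 0.8 — radiologist categories
track true status well but imperfectly).

The default `effect_size = 2` produces a realistic, learnable but
imperfect signal. Property tests that assert *recovery* of a planted
signal (full-pipeline AUC > 0.85 per seed) run in a strong-coupling
regime, `effect_size = 4`, where descriptors are close to deterministic
in the liability — the property being tested is that the pipeline
recovers a strong signal, not that every realistic cohort is this
separable. Null checks (`effect_size = 0`, or label permutation) assert
mean AUC within 0.5 ± 0.1 across seeds, since a single 21/109 null AUC
has standard deviation ≈ 0.07.

What passing these tests does **not** show: the generator plants
independent-given-liability descriptors with the marginal imbalance of
the study design; real reports have correlated findings, reader
effects, and missingness patterns the generator does not model.
Synthetic performance figures therefore validate the machinery, not
clinical performance; the published evaluation metrics of the original
cohort are not reproducible from synthetic data and are not claimed.

## Evaluation metrics

`evaluate_cohort()` scores a labeled cohort twice — by Global and by
Corrected Global Risk — reporting sensitivity, specificity, FNR, FPR,
the Matthews correlation coefficient (0 by convention, with a warning,
when a marginal is empty) and the rank-based (Mann–Whitney) AUC with
half-credit for ties. All metric implementations are cross-checked in
the suite against exhaustive counting oracles and, for AUC, against an
independent ROC package.

## Problem sizes and determinism

The test suite trains on 130-record cohorts (augmented to 400 inside
folds) with 100-tree ensembles — sizes chosen to mirror the study
design while keeping a full run of the suite in the low minutes on a
single core. Every stochastic step (generator, fold assignment,
SMOTE-NC, bootstrap) flows from an explicit integer seed, and seeded
runs are bit-reproducible end-to-end.

## Known limitations

* The shipped rule bases encode a generic reading of lexicon suspicion
  orderings; they are a starting point for clinical review, not a
  validated knowledge base.
* The correction-factor branch for BI-RADS 3 vs 4A–4C follows the
  min-with-cap reading of the published factor table; BI-RADS 0 is
  deliberately unsupported.
* The Statistical Risk model assumes the scoring record matches the
  training schema exactly; new vocabulary values require re-encoding
  and retraining.
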