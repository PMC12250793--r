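---
title: "Methods: cardiometabolic index screening for pediatric metabolic syndrome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiometabolic index screening for pediatric metabolic syndrome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedmets)
```

## The problem

Metabolic syndrome (MetS) — the clustering of abdominal obesity,
dyslipidemia, raised blood pressure and dysglycemia — drives much of the
early cardiovascular and diabetic morbidity in children with syndromic
obesity such as Prader–Willi syndrome (PWS). Diagnosing it requires a full
component work-up; screening for it should not. This package asks the
screening question quantitatively: of twelve anthropometric,
body-composition and biochemical indices, which one best predicts the
rule-based MetS diagnosis, at what cutoff, and does the answer depend on
age and sex?

Because clinical PWS cohorts are small, rare and not freely shareable, the
package also ships a synthetic cohort generator with a known generative
structure, so the entire analysis — index computation, rule-based
diagnosis, ROC evaluation, cutoff trends — runs end to end and can be
tested against ground truth without any patient data.

## The index panel

All indices are computed from standard clinic measurements (weight kg,
height cm, waist cm, DXA fat/fat-free mass kg, fasting lipids/glucose
mg/dL, insulin µU/mL, blood pressure mmHg):

| Index | Formula | Units in |
|---|---|---|
| BMI | weight / height² | kg, m |
| BMI-SDS | z-score vs. age/sex reference (LMS) | — |
| TMI | weight / height³ | kg, m |
| FMI, FFMI | DXA mass / height² | kg, m |
| BMFI | BMI × FM-fraction × waist | fraction, m |
| ABSI | waist / (BMI^{2/3} · height^{1/2}) | m |
| VAI | sex-specific waist/BMI/TG/HDL composite | mmol/L |
| WtHR | waist / height | cm/cm |
| CMI | WtHR × TG/HDL-C | — |
| TC/HDL-C, TG/HDL-C | lipid ratios | mg/dL |
| HOMA-IR | glucose × insulin / 405 | mg/dL, µU/mL |

Three unit conventions deserve comment, because the composite-index
literature prints formulas loosely:

* **VAI bracketing.** The waist term is WC / (c₁ + c₂·BMI) per the
  original definition; the frequently reprinted reading WC/c₁ + c₂·BMI
  changes the index scale by an order of magnitude. The mis-bracketed
  form is available via `literal = TRUE` for sensitivity analysis only.
* **BMFI units.** Fat mass enters as a *fraction* and waist in *meters*;
  percent × centimeters would put the index near 10⁵ instead of its
  conventional ~10 scale.
* **ABSI units.** Waist and height in meters, giving pediatric values
  near 0.08.

HOMA-IR uses the Matthews denominator 405 (mass units). Lipid conversions
are fixed at TG mg/dL ÷ 88.57 and cholesterol mg/dL ÷ 38.67 to mmol/L.

Missing optional inputs (DXA masses, HbA1c, Tanner stage) propagate as
`NA` — an index is undefined, never silently zero — and analyses drop such
subjects listwise with counts reported.

### BMI-SDS references

The growth reference is injected (`pedmets_reference` object), not
hard-coded: WHO-style LMS tables can be supplied as long-format CSV. The
z-score uses the Cole LMS transform ((x/M)^L − 1)/(L·S) when L ≠ 1 and the
plain (x − M)/S when L = 1 (S then read as an absolute SD). Thresholds and
LMS parameters are linearly interpolated in age between knots;
extrapolation beyond the tabulated range raises a coverage error rather
than clamping, since a clamped growth reference silently misclassifies.

## The MetS rule engine

Diagnosis dispatches on age to three criteria sets, with bands
left-closed/right-open at 10 and 16 years (a subject aged exactly 16.0
is assessed under the adult-style band):

* **Ages 7–<10 (IDEFICS-style):** four components, all at age/sex
  percentiles — waist > p90; systolic or diastolic BP > p90; TG > p90 *or*
  HDL-C < p10; HOMA-IR > p90 *or* glucose > p90. MetS at ≥ 3 components.
* **Ages 10–<16 (IDF):** mandatory gate waist > p90, plus ≥ 2 of: TG >
  150 mg/dL; HDL-C < 40 mg/dL; SBP > 130 or DBP > 85 mmHg; glucose > 100
  mg/dL or prior IGT/T2DM diagnosis.
* **Ages 16+ (IDF):** gate on absolute waist (> 94 cm male, > 80 cm
  female); HDL cut 40 (M) / 50 (F) mg/dL; lipid and antihypertensive
  treatment count as their factors.

Decisions made where the criteria are silent:

* Every comparison is strict, exactly as the criteria print them; a value
  sitting on a threshold is non-pathological. Likewise BMI-SDS exactly 2.0
  classifies as non-obese (obesity is defined by "> 2.0").
* A prior IGT/T2DM diagnosis satisfies the glucose component in **all**
  bands; treatment flags for lipids and BP count only at 16+, where the
  criteria place them.
* A 16+ subject on lipid treatment with normal measured lipids
  contributes **one** lipid factor by default ("specific treatment for
  this lipid abnormality" names one abnormality); `treated_lipid =
  "both"` exposes the alternative reading in which treatment marks both
  the TG and the HDL factor.
* `n_components` counts what the rule counts: the four pooled components
  for IDEFICS, the four non-gate factors for IDF.

## Diagnostic evaluation

The positivity convention is score ≥ threshold (high index = at risk)
throughout.

* **ROC/AUC.** Empirical operating points at every distinct score; AUC as
  the Mann–Whitney concordance probability computed from ranks (ties count
  half). The 95% CI uses the DeLong placement-value variance; paired index
  comparisons use the paired DeLong test (the study-level comparison
  method is not standardized in this literature; DeLong is the default
  choice and a permutation test backs it in the test suite).
* **Youden cutoff.** J = sens + spec − 1 maximized over observed
  thresholds; ties broken toward the *lower* threshold — the
  sensitivity-favoring choice for a screening test. The reported Youden
  index is always exactly sens + spec − 1 at the reported cutoff.
* **Confusion metrics.** Sensitivity, specificity, PPV, NPV with Wald
  intervals clipped to [0, 1] by default (this is the interval convention
  that reproduces published screening tables of the form p ± 1.96·SE);
  Clopper–Pearson is available via `ci_method = "cp"`. Likelihood ratios
  use the log-method interval. Metrics with empty denominators are
  reported as explicit `NA`, never dropped.
* **Cutoff trend.** Published age/sex cutoff trends rarely state their
  construction; the package uses a transparent sliding-window
  reconstruction: at each grid age the Youden cutoff is recomputed within
  ± 2 years (default `window = 4`) for one sex, and windows with fewer
  than `min_n = 10` subjects or a single class are emitted as undefined.
  The window default trades age resolution against the ~10 positives per
  window needed for a stable empirical cutoff at clinical cohort sizes.
* **Supporting tests.** Wilcoxon rank-sum (exact enumeration for combined
  n ≤ 12 without ties, tie-corrected normal approximation otherwise),
  Spearman correlation (mid-ranks, t-approximation), chi-square on 2×2
  tables with the continuity correction as a *required explicit argument*
  (published contingency tables mix conventions, so no silent default is
  safe), Lilliefors-corrected KS normality screen, and a Tukey-fence
  outlier screen whose findings are reported but never remove a subject.

## The synthetic cohort generator

`simulate_cohort()` draws from a single-latent-factor model:

1. Age ~ Uniform(7, 18); sex Bernoulli with 63:61 male:female odds.
2. Height follows a sex-specific linear growth curve with a pubertal
   plateau (females ~155 cm, males ~168 cm) and 3.5% log-normal noise —
   deliberately short statures, as in growth-affected syndromic cohorts.
3. BMI is log-normal around the reference median M(age) with log-mean
   0.349 and log-SD 0.30, placing a little over half the cohort above
   BMI-SDS 2 ("obese"); weight = BMI · height².
4. A latent cardiometabolic **risk state** is Bernoulli with log-odds
   increasing in BMI-SDS (slope 0.65/SDS unit); carriers receive joint
   multiplicative shifts of the MetS components: waist ×1.10, TG ×2.0,
   HDL ×0.72, glucose ×1.09, insulin ×1.8, SBP ×1.05, DBP ×1.10. Effect
   sizes were set from the MetS+/MetS− median ratios typical of pediatric
   PWS cohorts (TG ≈ 133 vs 72 mg/dL, HDL ≈ 39 vs 54 mg/dL, and so on).
5. Remaining variables are log-normal around clinically typical medians.
   Sexual dimorphism is injected only where such cohorts show it: height,
   fat-mass percentage (higher in girls), fat-free mass, glycemia.
6. Fat and fat-free mass partition weight exactly, so FMI + FFMI = BMI by
   construction.

The baseline latent-risk rate is tied to the target prevalence through a
single calibration constant, fixed once by simulating the default
parameters against the 19.4% prevalence target and then frozen; with the
defaults, the realized rule-based prevalence at n = 124 centres on ~19%
and converges to the target as n grows.

Correlation between components arises **only** through the shared latent
state. That single-factor structure is what makes ground truth
analyzable: `true_auc_oracle()` estimates each index's population AUC for
discriminating the *latent state* by Monte-Carlo, and with all effects at
1 (and the BMI tilt disabled) every oracle AUC is 0.5. The analysis
pipeline itself, by contrast, evaluates indices against the *rule-based
MetS labels* — the clinically observable endpoint — which is also how the
parameter-recovery tests are phrased: with lipid-dominant effects, the
TG/HDL-C ratio and CMI must outrank BMI, WtHR and ABSI by AUC in ≥ 90% of
simulation seeds.

What the generator does **not** emulate: genotype effects, growth-hormone
or sex-steroid therapy, longitudinal trajectories, multi-factor
correlation structure (e.g. lipids correlating with BP beyond the latent
state), assay noise, or real growth-reference percentiles (the shipped
reference tables are synthetic, smooth, ordered curves that stand in for
the external publications). Tests passing on this generator therefore
demonstrate the *statistical machinery* — not clinical validity on real
PWS data.

## Reference tables

`make_reference_tables()` produces deterministic half-year-knot curves
(p10/p50/p90) for waist, SBP/DBP, TG, HDL, glucose and HOMA-IR, plus an
LMS BMI reference (L = −1, S = 0.13, M rising linearly with age), over
ages 7–18 by sex. Percentiles are ordered at every knot and waist/BMI
medians are monotone in age. They are synthetic fixtures: shaped like
pediatric references (thresholds sit near general-population p90s so an
at-risk cohort exceeds them at realistic rates) but not reproductions of
any published table.

## Numerical choices and degenerate inputs

* Identities used as invariants: CMI = WtHR × TG/HDL-C to 1e−12;
  FMI + FFMI equals BMI computed from FM + FFM to 1e−9.
* ROC analyses require both classes; single-class strata are reported as
  explicitly undefined rather than erroring out of a whole-pipeline run.
* DeLong comparison of identical scores (zero variance, zero difference)
  returns p = 1 by convention.
* Rank tests on fully tied data return p = 1.
* All randomness flows from a single integer seed per cohort; identical
  (seed, parameters) give byte-identical cohorts and reports.

## Problem sizes

The package's own verification uses cohorts of 124 (the emulated study
size) and 500 (recovery sweeps), 200 simulation seeds for the
prevalence-calibration and index-ranking checks, and 10⁴–10⁵ draws for
Monte-Carlo oracles — sizes at which the checks are stable while the full
suite stays fast.

## Known limitations

* Wald intervals misbehave at extreme proportions (they clip to the
  boundary); they are kept as the default because they are the published
  screening-table convention, with Clopper–Pearson one flag away.
* The sliding-window cutoff trend is an explicit reconstruction of an
  under-specified published construction; its window and minimum-count
  defaults are documented choices, not estimates.
* The empirical Youden cutoff at n ≈ 124 with ~24 positives is noisy; the
  trend analysis inherits that noise per window.
* Percentile references are consumed at face value; the package does not
  model reference uncertainty.
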