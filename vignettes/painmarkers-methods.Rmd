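---
title: "Methods: convergent evidence scoring of blood biomarkers for pain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: convergent evidence scoring of blood biomarkers for pain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painmarkers)
```

## The design this package implements

Self-reported pain (a 0–10 visual analog scale, VAS) is noisy, and
cross-sectional case-control comparisons of blood gene expression are noisier
still. The design implemented here instead leans on three ideas:

1. **Within-subject contrasts.** Each discovery subject is sampled at both
   Low Pain (VAS ≤ 2) and High Pain (VAS ≥ 6) visits, so every comparison is
   its own genetic and (largely) medication control. Evidence is then summed
   *across* subjects as a concordance fraction.
2. **Convergence over steps.** No single step is trusted. A probeset
   accumulates points from discovery concordance, prior literature,
   validation against clinically severe patients, and out-of-sample
   prediction, and only the total (the convergent functional evidence score,
   CFE) ranks it.
3. **Personalization.** Prediction is evaluated in all subjects and within
   gender and gender-by-diagnosis strata, because marker effects in
   psychiatric cohorts are often gender- and diagnosis-specific.

This vignette documents the model assumptions, the tunable parameters, the
synthetic-cohort generator, and the numerical and design choices that were
genuinely open.

## Scoring model and assumptions

### Discovery (internal score, 0–6)

All within-subject (Low, High) visit pairs are enumerated in both temporal
orders; each pair is one comparison and all pairs are pooled across subjects
with equal weight. Two detection channels are scored per probeset:

* **DE** (graded change): concordant-increased when
  intensity(High)/intensity(Low) ≥ `fold_threshold`, concordant-decreased
  when the ratio ≤ 1/`fold_threshold`. The default 1.2 (linear scale) is a
  conventional minimal microarray change; it is exposed as an argument. A
  zero Low intensity with a nonzero High one is treated as increased
  (ratio → ∞); 0/0 counts for neither direction.
* **AP** (on/off change): concordant-increased on a strict Absent→Present
  call switch, decreased on Present→Absent. Marginal calls never count as a
  switch — the conservative reading of "turning on and off"; the 0/0.5/1
  numeric encoding of calls is used only downstream, where call data stand
  in for intensities.

The winning direction is the one with the larger concordant fraction; exact
ties carry no direction and score 0, since an un-directed marker cannot
enter a risk-oriented composite. Points: fraction ≥ 33% → 2, ≥ 50% → 4,
≥ 80% → 6, all thresholds inclusive. The "top set" flag uses fraction ≥ 90%,
also inclusive, applied to the *fraction* (not a normalized point score) —
this reading of the top-set cutoff was an open choice and is noted here. The
per-probeset internal score used downstream is the better of the AP and DE
rows.

### Prioritization (external score, 0–12; combined, 0–18)

Literature evidence lives in a table of (gene, category, citation) rows over
six categories: human/non-human × genetic / nervous tissue / peripheral
tissue-fluids. Each category with ≥ 1 citation contributes its weight
(default 2 points each; the cap is 12). Multiplicity within a category adds
nothing — the score reflects *breadth* of evidence, not volume. Weights are
configurable because published applications of this scheme include scores
(e.g. 7) that uniform 2-point weights cannot produce. Scores attach to gene
symbols and propagate to every probeset of the gene through a user-supplied
probeset→gene map; no array-manifest lookup is performed.

Combined = internal + external (max 18). The carry-forward cutoff of 6 is
one third of the maximum and deliberately admits novel genes: a probeset
with perfect internal concordance and zero literature still advances. The
separate long-list cutoff "external ≥ 8" is applied to the external score
alone — the other open reading (combined ≥ 8) would make the discovery and
prioritization components of the long list nearly redundant.

### Validation (0–6)

Three groups are assembled: discovery Low Pain visits, discovery High Pain
visits that are *not* clinically severe (SF-36 items 21 + 22 < 10), and an
independent cohort in which every visit is clinically severe (VAS ≥ 6 and
item sum ≥ 10). Values (linear intensities for DE candidates — log data are
first de-logged as `2^x` — or 0/0.5/1-encoded calls for AP candidates) are
z-scored within gender-by-diagnosis strata. Two exclusion rules protect the
z-scores: a stratum whose values have zero variance is excluded (the 0/0
z-score is undefined; excluded means `NA`, never 0, which would fabricate a
"mean" observation), as is any stratum of size 1.

"Stepwise" requires a *strict* ordering of the three group means in the
probeset's discovery direction; ties are not progression. One-way ANOVA
(`stats::aov`) over the three groups gives p; points are 6 for stepwise +
Bonferroni-significant, 4 for stepwise + p < 0.05, 2 for stepwise only. The
Bonferroni denominator is the number of probesets *entering validation*, not
the final long-list size — the long list is assembled only after validation,
so correcting by its size would be circular.

### Testing (0–8 per outcome)

Markers are z-scored (log2 intensities) by gender and diagnosis in the test
cohort, then oriented: risk score = Σ z(increased markers) − Σ z(decreased
markers). This single orientation rule is what makes every downstream hazard
and odds ratio read ">1 = increased risk" regardless of a marker's
direction, and it makes the analysis provably invariant to flipping a
marker's sign together with its direction label.

Three outcomes:

* **State**: is the visit High Pain (VAS ≥ 6)? Metrics: ROC AUC with a
  one-sided p, a one-tailed Welch t-test, and a one-tailed Pearson r against
  VAS. The AUC is computed as the Mann-Whitney U statistic scaled by
  n₁n₀ with ties counted one half; the one-sided p uses the normal
  approximation with tie correction and a continuity correction (the exact
  permutation distribution is out of reach at cohort sizes, and the
  tie-corrected approximation is the standard choice).
* **Trait, first year**: any ED pain visit within 365 days of the testing
  visit, among visits with at least 365 days of possible follow-up. AUC as
  above; Pearson r against ED-visit frequency (events per year of
  follow-up); Cox proportional hazards on time to first event, censored at
  365 days.
* **Trait, all years**: any future ED pain visit over the full, variable
  follow-up. The primary metric is a logistic odds ratio per z unit (unlike
  AUC it respects follow-up length); Cox censored at the last
  medical-record note is reported alongside. z units make odds ratios
  comparable across markers.

Prediction is **visit-level**: a subject contributes every eligible visit,
matching how case/total counts are reported in this design. Cross-sectional
rows use the visit's risk score. Longitudinal rows use the equal-weight
composite of four features of the subject's series *up to that visit* —
level at the most recent visit, maximum level, slope into the most recent
visit, and maximum slope (z per day) — each feature z-scored across the
cohort's longitudinal rows before averaging (the feature weighting was open;
equal weights after standardization is the neutral choice and is isolated in
one function). Longitudinal rows start at a subject's second visit, so the
longitudinal n is always below the cross-sectional n.

Strata: all subjects; each gender; each gender × diagnosis, plus a pooled
psychosis stratum (schizophrenia + schizoaffective). Strata with fewer than
2 cases or 2 controls are reported as skipped rows with the reason — small
enough to keep the strata the design cares about, large enough to block
degenerate fits. "Significant" is one-sided p < 0.05, uncorrected: the CFE
scheme marks Bonferroni survivors separately and nominal significance drives
the points; a Bonferroni-surviving prediction earns no extra points.

### CFE (0–48)

Per outcome, the best significant stratum level sets the points (all → 8,
gender → 6, gender×diagnosis → 4, none → 0; cross-sectional and longitudinal
both qualify). Total = discovery + CFG + validation + three testing
outcomes ≤ 48, split 36 own-data : 12 literature — the scheme weighs the
study's own data three times the literature. Ranking is by total, ties by
own-data subtotal, then identifier (stable).

## The synthetic-cohort generator

No patient-level data accompany this class of study, so the generator is a
first-class module: it emulates the statistical structure the analysis
assumes, with planted ground truth, so recovery can be *measured*.

* **Design**: subjects with 2–5 visits ~3–6 months apart; discovery subjects
  alternate Low and High Pain blocks (every subject gets ≥ 1 diametric
  change, which the design requires); validation subjects are uniformly
  clinically severe; test subjects span the full VAS range (~27% High Pain).
  Defaults mirror the fixed design shipped as `cohort_fixture()` — 28
  subjects, 79 visits, 19 M / 9 F, diagnosis mix BP 9, SZA 6, PTSD 5, MDD 3,
  SZ 3, PSYCH 2. The VAS distribution within Low/High blocks is uniform —
  it is a config choice, not an empirical claim.
* **Expression**: log2 intensities N(`baseline_log2` + shift, `noise_sd`),
  exponentiated to the linear scale (the log-normal microarray convention;
  the pipeline's de-log step is its inverse). Planted algogenes sit
  `effect_size·noise_sd` log2 units higher in High than Low Pain visits,
  suppressors lower, with the shift split symmetrically around baseline
  (−s/2 / +s/2). Clinically severe visits sit `severe_shift_mult` (default
  1.5) times the shift above Low — planting the Low < High < Severe gradient
  that validation tests for. Null probesets are exchangeable noise.
* **Detection calls**: Absent below `baseline_log2 − 1`, Present above
  `baseline_log2`, Marginal between. Call generation is a stand-in for the
  array vendor's algorithm, which this package deliberately does not
  reimplement; only call *consumption* is part of the method. A consequence
  worth knowing: at the default effect size 2 the planted signal is in the
  DE regime — call switching needs on/off-scale swings (≳ 4 standardized
  units) to cross both thresholds, so AP discoveries on default synthetic
  data are rare, exactly as AP is meant to capture a different class of
  gene.
* **Trait**: each subject has a latent liability t ~ N(0,1); the ED
  pain-visit process is homogeneous Poisson with rate
  `base_ed_rate·exp(trait_hazard_beta·t)` (default year-1 event probability
  ≈ 0.22 at t = 0), and planted markers carry an oriented expression
  component `trait_load·noise_sd·t` (default load 1). The load is a
  compromise: the planted-marker *panel* then tracks t with correlation
  ≈ 0.99 (per-marker attenuation a = load/√(load²+1) and panel correlation
  a/√(a² + (1−a²)/m)), while the subject-level variance stays small enough
  not to swamp cross-cohort group comparisons in validation. Follow-up spans
  0.8–1.2 × `followup_days` (default ~5.6 years).
* **Evidence**: `generate_evidence()` gives planted genes a higher chance of
  prior literature than nulls; `evidence_fixture()` reproduces the canonical
  six-category citation counts (212 / 3 / 57 / 26 / 48 / 9, total 355).

What the generator does **not** emulate: batch and array effects, probe-level
structure, medication covariates, diagnosis-specific expression baselines
(strata differ only in composition, not in distribution), informative
censoring, or correlated probesets. Passing recovery tests on this generator
therefore demonstrates that the *pipeline arithmetic and statistics* behave
as designed under the assumed data-generating process — not that real blood
expression data will yield biomarkers of any particular strength.

## Numerical choices

* Sample standard deviation (n − 1) throughout z-scoring.
* Direction ties in discovery → no direction, 0 points.
* 0/0 intensity ratios → neither direction; x/0 → increased.
* All-tied score vectors: AUC 0.5, p 1 (no evidence, not an error).
* One-sided p values throughout testing (the design pre-specifies the risk
  direction via orientation); Cox and logistic p from the Wald z.
* Degenerate outcomes (single-class, zero-variance correlates) are reported
  as untestable (`NA`) rather than silently dropped or zeroed; skipped
  strata keep a row with the reason.
* Determinism: every generator draw flows from a single integer seed;
  cohort roles use fixed seed offsets so the three cohorts of one config are
  independent but individually reproducible; re-running the pipeline on
  identical inputs is byte-identical.

## Problem sizes

The shipped analysis (`analysis/01` … `06`) uses a 1000-probeset array with
30 + 30 planted markers over the fixed 28-subject discovery design, a
23-subject severe cohort, and a 170-subject test cohort — sizes chosen so a
full run completes in well under a minute while every stage still has
realistic case counts in its strata. The test suite's recovery experiments
use 50–400 subjects and 120–400 probesets: at effect size 2 discovery
recovery is essentially saturated by 25 subjects, and at 400 subjects the
Cox and logistic recoveries have standard errors comfortably inside the
±0.2 / ±0.15 log-unit bands they are checked against (the logistic check
averages five 400-subject fits per seed, estimating the estimator's centre
rather than one draw of it).

## Known limitations

* The pipeline starts from normalized linear intensities and A/M/P calls;
  RMA/MAS5 normalization and call generation are upstream and out of scope.
* Probeset→gene mapping is an input table; no annotation service is
  consulted.
* Longitudinal composites assume visit days are strictly increasing and use
  expanding windows; irregular revisit patterns are represented only through
  the day spacing.
* The evidence table is taken at face value: curation quality, redundancy
  between categories, and publication bias are not modelled.
* Visit-level prediction rows within a subject are not independent; reported
  p values are marginal, as in the design being implemented, and should be
  read as descriptive rankings rather than family-wise error statements.
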