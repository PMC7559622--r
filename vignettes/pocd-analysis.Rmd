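---
title: "Reliable-change POCD classification and single-SNP association: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reliable-change POCD classification and single-SNP association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocdassoc)
```

## The problem

Postoperative cognitive dysfunction (POCD) in elderly surgical patients
is not observable from a single test score: repeated neuropsychological
testing improves performance by itself (the practice or learning
effect), and individual tests are noisy. The accepted solution is the
reliable change index (RCI): a healthy control group takes the same
battery at the same intervals as the patients, their change scores
estimate what "no cognitive insult" looks like, and a patient's change
is declared abnormal only when it falls far outside that reference
distribution. This package implements the RCI classifier for a six-test
battery, a case-control association layer linking POCD status to a
biallelic SNP (the motivating application is BDNF rs6265, an A/G
missense variant also known as Val66Met), group-comparison summary
tables, and a synthetic cohort generator with known ground truth.

## The reliable change classifier

For test $i$ and follow-up interval $t$ (day 7 or month 3 after
surgery), the deficit-oriented change score is

$$\Delta_{i} = o_i \,(x_{i,t} - x_{i,\text{baseline}}),$$

where the orientation $o_i \in \{+1, -1\}$ makes negative change mean
deterioration on every test (completion times and reaction times carry
$o_i = -1$). From $n$ controls the calibration stage computes the mean
$\bar\Delta_i^{c}$ and sample SD $s_i^{c}$ (always the $n-1$
denominator — with 25 controls the denominator choice is material) of
the same change score. A patient's RCI is

$$z_i = \frac{\Delta_i - \bar\Delta_i^{c}}{s_i^{c}},$$

a test is *positive* when $z_i \le -1.96$, and POCD is declared when at
least 2 of the 6 tests are positive. Subtracting $\bar\Delta_i^{c}$
removes the practice effect; dividing by $s_i^{c}$ calibrates against
retest variability.

Decisions worth stating explicitly:

* **Boundary.** "At least 1.96 SD below" is an inclusive comparison,
  $z \le -1.96$; a change landing exactly on the threshold counts.
* **Orientation** is per-test configuration in `battery_def()`, not an
  inference: published batteries rarely state which scales are
  inverted, so `default_battery()` documents the assumption (the four
  time-based tasks are higher-is-worse).
* **Missing data.** The default policy mirrors the usual cohort
  exclusion rule: a patient missing any test is unclassifiable and
  drops out of the incidence denominator. A permissive mode
  (`max_missing = 1`) exists but is never the default.
* **Rounding** is display-only. Incidence prints at one decimal
  (`29/99` → `29.3%`), but classification and comparisons always use
  unrounded values.

The classifier is scale- and shift-invariant per test (the $z$ is
unchanged if one test's scores are rescaled or shifted for everyone),
and monotone: worsening a patient's follow-up score can never clear a
POCD flag. The test suite checks all three properties, plus exact
agreement with a brute-force reimplementation on random cohorts.

## The genetic association layer

Let the genotype table be the 2 × 3 count matrix of POCD status by
AA/AG/GG. Four standard inheritance models are fitted:

* **Allelic** — each subject contributes two alleles; 2 × 2 table of
  G vs A alleles by status.
* **Dominant** — G-carriers (AG + GG) vs AA.
* **Recessive** — GG vs (AA + AG).
* **Additive** — per-allele logistic trend,
  $\mathrm{logit}\, P(\text{POCD}) = \beta_0 + \beta_1 g$ with
  $g \in \{0, 1, 2\}$ G alleles.

For the collapsed 2 × 2 models the odds ratio is $ad/bc$ and the 95%
confidence interval is Woolf's:
$\exp\{\log \mathrm{OR} \pm 1.96 \sqrt{1/a + 1/b + 1/c + 1/d}\}$.
Woolf was chosen because it exactly reproduces the published intervals
of the motivating study from its printed counts (dominant day 7
0.13–0.96, recessive day 7 0.078–1.06, dominant month 3 0.16–1.27,
recessive month 3 0.25–2.37). The additive model is a grouped-binomial
maximum-likelihood fit by Newton–Raphson (parameter tolerance
$10^{-10}$, at most 50 iterations) with a Wald SE from the observed
information — not a Cochran–Armitage test, which yields a p-value but
no odds ratio; $\exp(\hat\beta_1)$ on the printed day-7 counts
reproduces the published 0.41. Complete separation is detected
(diverging slope or singular information) and reported as an error
rather than a sham estimate.

Numerical and policy choices:

* **Zero cells** get the Haldane–Anscombe +0.5 added to all four cells,
  only when a cell is zero, and the result is flagged
  (`correction_applied`). A fully empty row or column leaves the OR
  undefined and errors.
* **Chi-square tests** are Pearson without continuity correction by
  default (a Yates flag exists); p-values for the 2 × 2 ORs come from
  this test on the uncorrected counts.
* **HWE** is tested on pooled genotype counts with the allele frequency
  estimated from the data, expected counts $n(p^2, 2pq, q^2)$, and 1
  degree of freedom (3 classes − 1 − 1 estimated frequency).
* **Display** follows association-table convention: two decimals, three
  below 0.1 (so 0.078 survives).

### Diagnostics for internally inconsistent published tables

Published summary tables are re-typed by humans and sometimes disagree
with themselves. `check_genotype_table()` flags genotype counts whose
totals contradict stated group sizes and allele counts that do not
equal the genotype-implied ones. In the motivating study's table, three
published figures cannot be derived from the published counts, and this
package deliberately recomputes rather than imitates them:

* the day-7 allelic OR is printed as 0.67, but the printed allele
  counts (G 22/79, A 36/61) give $\,(22 \cdot 61)/(79 \cdot 36) = 0.47$
  — coincidentally the printed CI's lower bound;
* the HWE statistic is printed as $\chi^2 = 4.402$, $p = .11$, but the
  pooled patient genotypes (21/55/23) give $\chi^2 = 1.23$, $p = .27$
  on 1 df (and $p = .11$ at 4.402 would imply 2 df, which is
  nonstandard when one allele frequency is estimated);
* the month-3 genotype counts sum to 25/74 subjects although the stated
  group sizes are 18/81 (the allele counts, 50/148, confirm 25/74), and
  the month-3 additive CI is printed as "0.32−0.302", an evident typo —
  only its point estimate (0.65, which the counts reproduce) is
  meaningful.

## The synthetic cohort generator

`generate_cohort(sim_config(...))` simulates the study design the
analysis assumes, with every parameter explicit:

* **Design**: 99 patients, 25 controls (the analysable sample of the
  motivating study); genotypes in HWE at G-allele frequency 0.51, the
  pooled patient allele frequency (101/198).
* **Risk model**: a latent binary surgical *insult* per patient with
  $\mathrm{logit}^{-1}(\beta_0 + \beta_1 g)$; defaults
  $\beta_1 = -0.9$ (the additive-model effect, $e^{-0.9} \approx
  0.41$) and $\beta_0 = \mathrm{logit}(0.48)$, i.e. an AA patient's
  insult risk of 48%, which averages to an overall early-POCD risk near
  30% over the genotype distribution. Controls are never insulted.
* **Scores**: each test on an arbitrary standardized scale (baseline
  mean 50, between-subject SD 10) — no raw battery score distributions
  are published, and the RCI arithmetic is scale-free, so realism of
  the scale is irrelevant; the scale is a labelled stand-in. Follow-up
  = baseline + practice effect (default +2 oriented points, treated as
  reached by day 7 and sustained) − insult × `decline_magnitude` ×
  `noise_sd` + residual noise. `decline_magnitude` is in control
  change-SD units (default 3, a decline the 1.96-SD rule detects on
  most tests); `noise_sd` (default 4) is the retest residual SD and
  hence the control change-score SD.
* **Inter-test correlation**: the tests' residual noise shares an
  exchangeable correlation `rho` (default 0.3). The false-positive rate
  of the 2-of-6 rule depends on this, which is why it is a visible
  parameter rather than a hidden constant.
* **Persistence**: an insulted patient's deficit persists to month 3
  with probability 0.6, giving late incidence roughly 60% of early
  incidence, in line with the roughly 29% → 18% pattern the design
  emulates.
* **Reproducibility**: one top-level seed drives every draw; identical
  seed and config reproduce the cohort bit for bit.

What the generator does *not* emulate: real battery score
distributions (skewness, floors/ceilings), genuine test-specific
effect profiles (the insult shifts all six tests equally),
covariate-driven risk (age, surgery type and the like are decorative),
and genotype-phenotype confounding. Passing tests on this generator
therefore demonstrate that the *statistical machinery* is correct
under its stated model, not that the model captures every feature of
real neuropsychological data.

## Group-comparison tables

`table1_report()` renders the familiar demographics table: mean ± SD
with an independent two-sample t-test for continuous variables, n (%)
with a Pearson chi-square for categorical ones, and a single joint
r × 2 chi-square per multi-level block. The t-test defaults to the
pooled-variance variant, which reproduces the motivating study's
recovery-time p = .03; Welch is available by flag
(`t_variant = "welch"`). For the education row the two variants give
.015 and .020 respectively against a printed .02 — the study does not
state which variant it used, so both are exposed and neither is forced.

## Problem sizes used in validation

The shipped test suite validates the classifier against a brute-force
oracle on 100 random small cohorts, the additive MLE against a
2001-point profile-likelihood grid search (agreement within $10^{-6}$)
on 50 random tables and against `stats::glm` on 20, the Woolf CI width
identity exactly, and parameter recovery on 500 simulated cohorts of
4000 patients (mean $\hat\beta_1$ within 0.05 of the true −0.9, Wald
CI coverage in the 93–97% band). Null calibration uses 200 seeds of the
study-sized design. These sizes keep the full suite in the
tens-of-seconds range while leaving Monte-Carlo error well below every
asserted tolerance.

## Limitations

* Single SNP, unadjusted models only: no covariate-adjusted logistic
  regression, haplotypes, or exact (mid-p / Fisher) OR intervals.
* The RCI here is the control-mean-adjusted difference form; no
  regression-based practice-effect models.
* The 1.96 threshold, 2-of-6 rule and Woolf intervals are faithful to
  the analysis convention this package reproduces, not the only
  defensible choices; all are parameters where a choice exists.
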