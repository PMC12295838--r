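---
title: "AIDA methods: classification and evaluation of transverse fetal head position"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AIDA methods: classification and evaluation of transverse fetal head position}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aida)
```

## The clinical problem

Persistent occiput transverse position during a prolonged second stage of
labor carries a high risk of intrapartum cesarean delivery (ICD). Digital
examination is unreliable in exactly these labors (molding, caput), so
assessment increasingly relies on intrapartum ultrasound, from which four
geometric parameters are measured: the angle of progression (AoP, head
descent), the head–symphysis distance (HSD, printed in the field's tables
under the column alias "SPD"), the midline angle (MLA, the rotation of the
fetal head midline relative to the maternal anteroposterior axis) and the
asynclitism degree (AD, lateral tilt of the head). AIDA — the Artificial
Intelligence Dystocia Algorithm — turns these four measurements into a
five-level ordinal risk class and, with machine-learning backends, into a
per-case delivery-outcome prediction.

This package implements the full pipeline: position geometry, color coding
and class assignment, a packaged 66-case reference cohort of transverse and
near/transitional positions, descriptive outcome analysis, seeded
train/test prediction, the statistical toolkit used to evaluate it, and a
synthetic-cohort generator so every stage is testable without access to any
clinical data.

## Position geometry

Occiput position is described on the ISUOG clock face (12:00 = occiput
anterior, midline) or as a rotation angle; the dial maps linearly at 30°
per hour with 12:00 anchored at 0° and angles increasing toward the
maternal left. This anchor is forced by the published sector pairings:
LOT (left occiput transverse) occupies 75°–105°, paired with the clock
segment around 3:00, and ROT occupies 255°–285° around 9:00, while
9:30–2:30 is occiput anterior and 3:30–8:30 occiput posterior.

The canonical midline angle folds the circle onto `[0, 180]`:
`value = min(theta, 360 - theta)`, with the side recorded as LEFT, RIGHT or
MIDLINE. Right-sided (ROT) positions are thereby treated as the mirror
equivalents of their LOT counterparts, which is how "corresponding values
for ROT" are given meaning throughout.

Strata on the canonical value `c`:

* **classic transverse**: `75 <= c <= 105`;
* **near-transverse**: `70 <= c < 75`;
* **transitional**: `60 <= c < 70`;
* **other**: everything else.

Boundary handling was genuinely open at 75°: the published definition
states "`>= 75`" for the classic stratum, which forces 75 into CLASSIC; the
lower bands are half-open so the strata partition the circle without
overlap. All reference-cohort angles are integers, so only the 75° boundary
is load-bearing. Canonical values above 105° (posterior-side positions) are
deliberately labeled OTHER rather than given a posterior stratum, because
no stratum beyond 105° is defined for this spectrum. The ISUOG transverse
bands are closed on both ends; whether an angle of exactly 75° or 105°
was treated as OT or as the neighboring sector in the source data is not
recorded, and the closed choice is the one consistent with `>= 75`.

## Color coding and the AIDA class

Each parameter is coded GREEN (favorable for vaginal delivery), YELLOW
(intermediate) or RED (high risk for cesarean) against per-parameter
threshold bands. The class is then

> **AIDA class = number of parameters not coded GREEN** (YELLOW and RED
> each count one),

an integer 0–4: class 0 means all four parameters favorable, class 4 all
four in the yellow or red zones. The published prose pins only the
endpoints; the counting rule is the unique rule consistent with every one
of the 66 reference-cohort rows (e.g. one RED plus one YELLOW gives
class 2), and the test suite verifies agreement on all 66. It makes the
class permutation-invariant in the parameters and monotone under
single-parameter degradation — both tested as properties.

Two numerical choices:

* **Boundary tie-break**: a value exactly on a breakpoint takes the
  *riskier* color. In a screening context the conservative direction is the
  defensible default; the source is silent.
* **Default thresholds are placeholders.** The published numeric cut-offs
  live in a prior publication and are configuration here, not constants:
  `threshold_config()` / `read_thresholds()` always accept external values,
  and every analysis of recorded data consumes transcribed colors directly.
  The defaults exist so the raw-measurement path and the generator run end
  to end. The MLA breakpoints (61° and 64° canonical) are the one
  data-constrained entry: they are the only integer choices consistent with
  every reference-cohort row (60° GREEN, 61° YELLOW, 64°+ RED). AD units
  are configurable (mm by default); the source never states them.

## The packaged reference cohort

`aida_fixture()` loads a verbatim transcription of the 66 published
per-case records (checksummed at load): patient id, MLA in degrees, the
four colors, the class, the binary outcome (`ICD`/`NOICD`) and the recorded
predictions of the three algorithms. The detailed delivery categories
(spontaneous, operative vaginal, cesarean after failed operative attempt,
cesarean) are published only as aggregates by class and stratum; they are
packaged as a separate summary (`outcome_summary()`) rather than invented
per case. The binary tables' `ICD` label includes cesarean-after-failure
(the 27 classic-stratum `ICD` rows equal that stratum's 27 cesareans).

One known discrepancy: the source prose counts seven vaginal deliveries,
but the per-case tables (and the aggregate table) contain six `NO ICD`
rows. The package follows the tables; `vaginal_profile()` reports what the
data contain.

## Descriptive results

`stratified_cd_rates()`, `class_cd_rates()`, `class_stratum_table()`,
`color_distribution()` and `vaginal_profile()` reproduce the headline
descriptive results exactly from the fixture: stratum sizes 29/9/28
(43.9 %/13.6 %/42.4 %), the cesarean gradient 100 % (near) / 93.1 %
(classic) / 85.7 % (transitional), class-3 risk 29/32 (90.6 %), class 4
21/21, and the per-parameter color distributions. Conventions: rates are
reported as exact fractions alongside percentages rounded to one decimal
(the printing convention of the field); the asynclitism summary uses the
RED-or-YELLOW union while AoP/SPD summaries use RED alone (both are always
computed and labeled); empty strata yield `NA`, never 0 %, so gradients on
small cohorts stay honest. `reproduce_fixture()` recomputes all of these
next to their printed reference values with PASS/FAIL flags.

## Machine-learning stage

`split_cohort()` draws a seeded 70/30 partition; the train size is
`floor(0.7 n + 0.5)` (round half up), matching the published 95/40 split of
the 135-case parent cohort. `train_predict()` fits one of three backends —
SVM (`e1071`, RBF kernel, probability model), random forest
(`randomForest`) and a single-hidden-layer MLP (`nnet`, standardized
inputs) — with the run seed injected at every stochastic step, and returns
a probability score and a 0.5-threshold label per test case.
`multi_seed_evaluate()` repeats this over the seed list (default 1, 0, 250,
500, 750) and reports per-seed confusion metrics plus their unweighted mean
(how the published five samples were pooled is not stated; per-seed detail
is always retained so any other pooling can be computed).

What the published classifiers consumed as features is not recorded. The
package makes the encoding explicit: `raw` (the four measurements), `color`
(ordinal GREEN=0/YELLOW=1/RED=2 per parameter plus the canonical MLA in
degrees — the only mode available for the fixture, which carries no raw
AoP/HSD/AD), and `class` (the AIDA class alone). Backend hyperparameters
are the ecosystems' standard defaults, recorded in the run manifest.
Splits are plain random (the source says only "random samples"); no
outcome stratification is applied.

Because per-split scores were never published, the overall performance
table of the source (e.g. random-forest accuracy 0.955) is **not**
reproduced numerically; the recorded per-case prediction columns imply
62/66 for the random forest, so that table cannot be the fixture's
confusion matrix. The path that *is* exactly reproducible — scoring the
recorded prediction columns against outcomes, `recorded_accuracy()` —
reproduces every published subset accuracy without retraining.

## Statistical toolkit

`confusion_metrics()` implements the printed metric family (accuracy,
sensitivity, specificity, PPV, NPV, F1); metrics with zero denominators are
reported `NA` ("undefined"), never coerced to 0 — specificity on an
all-cesarean stratum is honestly undefined. `wilson_interval()` uses the
exact normal quantile (not 1.96) and is tested against
`prop.test(correct = FALSE)`, which inverts the same score test.
`mcnemar_paired()` defaults to the continuity-corrected statistic with an
explicit flag, since which variant produced the published chi-squared
values is not stated and those values are not derivable from the printed
tables; printed McNemar and Wilson numbers are therefore validated by
closed-form and oracle properties, not by numeric reproduction. AUC is the
rank-based Mann–Whitney statistic with ties counted half, tested against a
brute-force pairwise oracle and an independent ROC implementation. Pearson
correlation wraps `stats::cor.test`.

## Synthetic cohorts

`generate_cohort()` emulates the statistical structure the analysis
assumes: stratum weights (default 29/9/28, weight 0 outside the transverse
spectrum), per-stratum color-pattern frequencies fitted from the fixture,
class = count of non-green by construction, and a class-conditional
cesarean probability. The default gradient is the fixture's empirical class
rates with the single-case class-0/1 cells smoothed to (0.10, 0.50, 0.80,
29/32, 1.00) — the smoothed cells are calibration, not published data;
class 4 remains certainty.

Raw measurements are drawn from a latent multivariate normal (optional
correlation matrix, identity by default) and mapped through the normal CDF
into the numeric band of the assigned color, with MLA mapped into the
intersection of its color band and the stratum band (sides drawn equally,
right-sided cases emitted as ROT angles). This construction guarantees that
colors and raw values can never contradict each other under the active
thresholds — `profile_to_class()` reproduces the assigned pattern on every
synthetic case — and gives correlation analyses a testable ground truth.
An empty band intersection is an infeasibility error, not silent
adjustment.

What the generator does *not* emulate: biomechanics, longitudinal parameter
evolution within labor, measurement error structure, or any real-data
marginal distribution of AoP/HSD/AD beyond band membership. Passing tests
on synthetic cohorts therefore demonstrate pipeline correctness and
statistical calibration, not clinical validity on real ultrasound data.

## Problem sizes and verification

The test suite verifies: exact reproduction of every headline fixture
quantity; round-trip and partition sweeps of the geometry (720 clock
positions, 0.5° circle sweep); class-rule agreement on all 66 rows plus
monotonicity/permutation properties over random patterns; closed-form and
brute-force oracles for Wilson, McNemar and AUC; generator calibration at
n = 10 000 (class-conditional rates within three binomial standard errors);
a null-association cohort at n = 400 whose mean accuracy tracks the base
rate; and byte-identical determinism of all three backends under fixed
seeds. These sizes keep the full suite in a few seconds while leaving the
Monte-Carlo checks comfortably powered.

## Known limitations

* The default thresholds are placeholders (above); analyses of recorded
  colors never touch them.
* Detailed outcome labels are aggregate-only; per-case detailed outcomes
  cannot be reconstructed.
* Published pooled statistics (overall metrics table, McNemar chi-squared,
  Wilson bounds, Pearson r of the source) rest on unpublished per-split or
  parent-cohort data and are out of numeric-reproduction scope by design.
* The 66-case cohort is small; class 0 and 1 contain one and two cases, so
  their empirical rates are not estimates in any useful sense — the
  generator smooths them and says so.
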