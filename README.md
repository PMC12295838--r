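# aida

Classification and evaluation pipeline for labor-dystocia risk in
**transverse fetal head position**, from intrapartum-ultrasound geometric
parameters to delivery-outcome analysis.

Persistent occiput transverse position in a prolonged second stage of labor
carries high rates of intrapartum cesarean delivery (ICD). AIDA — the
Artificial Intelligence Dystocia Algorithm — standardizes the assessment:
four geometric parameters measured on translabial ultrasound, the angle of
progression (AoP), the head–symphysis distance (HSD, table alias "SPD"),
the midline angle (MLA) and the asynclitism degree (AD), are each coded
GREEN / YELLOW / RED against threshold bands, and the case is assigned the
ordinal class

```
AIDA class = #{ parameters not coded GREEN }  ∈ {0, …, 4}
```

so class 0 has all parameters favorable and class 4 none. Position geometry
follows the ISUOG clock face (12:00 = occiput anterior ≙ 0°, 30° per hour):
LOT occupies 75°–105°, ROT 255°–285°, and the canonical midline angle
`min(θ, 360 − θ)` defines three strata — classic transverse (MLA ≥ 75°),
near-transverse (70°–74°) and transitional (60°–69°). The package is for
researchers in intrapartum ultrasound and clinical decision support who
want the whole pipeline — geometry, color coding, class assignment,
descriptive outcome analysis, seeded SVM/RF/MLP outcome prediction,
confusion-matrix metrics with Wilson score intervals, McNemar paired
comparisons, AUC — as tested, reusable functions, together with a packaged
66-case transverse-position reference cohort and a synthetic-cohort
generator.

## Worked example

```r
library(aida)

cohort <- aida_fixture()          # packaged 66-case reference cohort
table(mla_stratum(cohort$mla_deg))
#>      CLASSIC         NEAR TRANSITIONAL        OTHER
#>           29            9           28            0

stratified_cd_rates(cohort)
#>        stratum  n cesarean      rate   pct
#> 1         NEAR  9        9 1.0000000 100.0
#> 2      CLASSIC 29       27 0.9310345  93.1
#> 3 TRANSITIONAL 28       24 0.8571429  85.7
#> 4        OTHER  0        0        NA    NA
```

The cesarean-rate gradient runs 100 % (near-transverse), 93.1 % (classic),
85.7 % (transitional): every transverse stratum is high-risk, and even the
"mildest" transitional band delivers vaginally in only 4 of 28 cases.
Class-level risk is steeper still:

```r
class_cd_rates(cohort)
#>   aida_class  n cesarean    rate   pct
#> 1          0  1        0 0.00000   0.0
#> 2          1  2        1 0.50000  50.0
#> 3          2 10        9 0.90000  90.0
#> 4          3 32       29 0.90625  90.6
#> 5          4 21       21 1.00000 100.0
```

Every class-4 case (no favorable parameter) required a cesarean; class 3
sits at 29/32 (90.6 %). Scoring the cohort's recorded per-case algorithm
predictions against outcomes — no retraining involved — gives the
per-stratum accuracies:

```r
recorded_accuracy(cohort, by = "stratum")
#>          group algorithm  n correct  accuracy   pct
#> 1      CLASSIC       svm 29      27 0.9310345  93.1
#> 2      CLASSIC        rf 29      27 0.9310345  93.1
#> 3      CLASSIC       mlp 29      26 0.8965517  89.7
#> 4         NEAR       svm  9       9 1.0000000 100.0
#> ...
```

Retraining from scratch, and synthetic cohorts for testing:

```r
res <- multi_seed_evaluate(cohort, seeds = c(1, 0, 250, 500, 750))
res$summary                       # per-backend mean metrics over 5 seeded 70/30 splits

cfg <- fit_synthetic_config(cohort)   # empirical strata, color patterns, class risks
sim <- generate_cohort(cfg, seed = 42)
```

A thin command-line front end (`classify`, `reproduce`, `simulate`,
`train`, `export-fixture`) lives at `inst/cli/aida.R`.

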