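# osteomir

Panel-biomarker modelling of postmenopausal osteoporosis in R:
integrate circulating **miR-194-5p** with routine medical-examination
items (EIs) into a stacked neural-network score and evaluate it the way
clinical biomarker studies do.

## The problem and who this is for

In postmenopausal women, circulating miR-194-5p expression (2^−ΔΔCT
units) falls as lumbar-spine bone mineral density (BMD, L1–L4, g/cm²)
declines, but the marker alone is a weak screen for osteoporosis
(T-score ≤ −2.5): Spearman ρ(marker, BMD) ≈ −0.365 corresponds to an
AUC near 0.69 and a sensitivity of only ~0.27 at specificity 0.9. The
package is for biostatisticians and biomarker researchers who want to
reproduce, stress-test, or extend the *derivative artificial neural
network* (DANN) strategy: strengthen a weak circulating marker with
examination items that are already collected at hospital discharge.

The core pipeline:

1. **Screening** — Spearman tests of 42 EIs against spine BMD; an item
   is BMD-correlated when |ρ| > 0.1 and p < 0.01; collinearity is
   flagged at pairwise |ρ| > 0.3 and the weaker member of a collinear
   pair is dropped.
2. **ANN I** — an RBF network regressing min-max-normalized BMD on the
   marker plus the top five EIs, with a 2:1:1
   training/verification/testing holdout; centres by seeded k-means,
   widths from centre spacing, output weights by ridge least squares,
   centre count selected on the verification set.
3. **DANN (ANN I + ANN II)** — for each participant the others are
   sorted by Euclidean distance in the normalized 6-D input space and
   cut into *m* near-equal divisions; four *derivative features* (own
   ANN I output, division mean output, division mean distance, division
   osteoporosis proportion) feed a second RBF network; (m, division
   index) are searched over m = 2…10 by verification-set Spearman ρ.
4. **PPSN** — a participant–participant similarity network (edges at
   distance < 0.198) with Rodriguez–Laio density-peak clustering.
5. **Evaluation** — ROC with explicit score orientation, Youden-optimal
   cut-off (ties toward higher specificity), sensitivity at fixed
   specificity 0.9, DeLong paired AUC comparison, D'Agostino–Pearson
   normality, leakage-safe 10-fold cross-validation of the whole
   pipeline, and external-cohort validation at the fixed risk
   threshold 0.38.

A Gaussian-copula simulator (`simulate_cohort()`) reproduces the study
cohorts' statistical structure — class proportions 40/34.3/25.7%
(exactly 92/79/59 at n = 230), planted marker ρ = −0.365, a collinear
LVDS–LVEDD echocardiography pair at ρ = 0.63, right-skewed ALT-like and
zero-inflated count-like margins — so the full pipeline is testable
without patient data. See `vignettes/osteomir-methods.Rmd` for the
model, assumptions, and design choices.

## Worked example

```r
library(osteomir)

cohort <- simulate_cohort(230, seed = 42)
table(cohort$status)
#>       normal   osteopenia osteoporosis
#>           92           79           59

scr <- screen_items(cohort)
dplyr::filter(tidy(scr), bmd_correlated)
#> # A tibble: 5 × 7
#>   item       rho             p     n band           bmd_correlated valid
#> 1 mir194  -0.379 0.00000000278   230 weak           TRUE           TRUE
#> 2 age     -0.239 0.000250        230 weak           TRUE           TRUE
#> 3 weight   0.303 0.00000297      230 weak           TRUE           TRUE
#> 4 CKMB_CK  0.194 0.00310         230 extremely-weak TRUE           TRUE
#> 5 U_ECH   -0.177 0.00717         230 extremely-weak TRUE           TRUE

cand  <- scr$item[scr$bmd_correlated & scr$item != "mir194"]
feats <- select_model_inputs(scr, collinearity_matrix(cohort, c("mir194", cand)))

dann <- fit_dann(cohort, feats, seed = 42)
dann
#> DANN: ANN I -> division (m = 8, index = 5) -> ANN II
#>   training-cohort Spearman rho(score, BMD) = 0.618
#>   ANN II holdout R_Tr = 0.689, R_Te = 0.453
#>   risk threshold = 0.38 (score below => osteoporosis)

roc_curve(dann$scores, cohort$status, direction = "low")
#> ROC (59 positive / 171 negative, low score = positive)
#>   AUC = 0.828
#>   Youden-optimal cut-off 0.504: SE = 0.76, SP = 0.76
#>   SE at SP >= 0.9: 0.47

delong_test(cohort$mir194, dann$scores, cohort$status, "high", "low")
#> DeLong paired AUC test: 0.716 vs 0.828 (delta -0.112)
#>   z = -3.409, two-sided p = 0.0006528
```

Reading this: the marker and four EIs pass the screening rule on this
simulated cohort; the stacked DANN score correlates with BMD at
ρ = 0.62 (the raw marker manages |ρ| = 0.38) and identifies
osteoporosis with AUC 0.83 versus 0.72 for the marker alone — a
significant improvement by the DeLong test. Scores are BMD-like:
*lower* scores mean higher risk, and `predict(dann, newdata,
type = "class")` calls osteoporosis below the 0.38 threshold.
`kfold_cv(cohort, feats, k = 10, seed = 1)` cross-validates the whole
pipeline with no leakage into normalization, fitting, hyperparameter
selection, or the derivative-feature reference. `autoplot()` methods
cover ROC curves, screening profiles, the division-search grid, and
density-peak decision plots; `tidy()`/`glance()` return tibbles
throughout.

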