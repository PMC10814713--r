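# neolungseg

Rule-based lung-field segmentation and recovery statistics for neonatal
chest radiographs.

## The problem

Respiratory distress syndrome (RDS) in preterm newborns — surfactant
deficiency causing alveolar collapse — is diagnosed and monitored with
anteroposterior chest radiographs and capillary blood-gas analysis.
Radiographic severity is graded I–V, from diffuse fine granular
opacities to complete opacification ("white lungs") in which the
cardiac border disappears. Clinicians tracking recovery after
surfactant and inhaled-corticosteroid therapy need two things that this
package provides:

1. an automatic delineation of the aerated lung fields on each film,
   with objective quality metrics against expert masks, and
2. paired before/after statistics on the accompanying blood-gas
   parameters (FiO2, pH, pCO2, pO2, HCO3, BE).

Because neonatal radiographs are rarely shareable, the package also
ships a parametric **phantom generator** that renders synthetic graded
radiographs with exact ground-truth lung masks, so the entire pipeline
is testable and demonstrable without patient data.

## The segmentation pipeline

For an M×N image `X` with intensities in [0, 255], the pipeline is the
classical rule-based chain:

1. **Binarize** — `Y(i,j) = 1` iff `X(i,j) > T` (or `X(i,j) ≤ T` with
   the default inverted polarity, since aerated lung is radiolucent).
   `T` comes from Otsu's method on the 256-bin histogram by default.
2. **Dilate** — `Z = Y ⊕ B`, with `B` a disk of radius 3, bridging
   small interruptions.
3. **Remove small objects** — components with area `≤ U` are dropped
   (`U` defaults to 0.1 % of the image area).
4. **ROI mask** — `X_mask = W · Q`, where `Q` is the union of the two
   largest components (one per lung) or an external mask file.
5. **Close** — `X_closed = (X_mask ⊕ B_c) ⊖ B_c` with `B_c` a disk of
   radius 7, then re-intersected with `Q`.
6. **Visualize** — the product image `X · X_closed` and a colored
   overlay blending the segmentation onto the film at weight 0.5.

All morphology uses zero padding (lungs never touch the film border).

## Evaluation metrics

From the confusion counts TP/TN/FP/FN of a predicted mask against an
expert mask, `metric_report()` computes sensitivity TP/(TP+FN),
specificity TN/(TN+FP), accuracy (TP+TN)/(TP+TN+FP+FN), precision
TP/(TP+FP), F-measure, Dice 2TP/(2TP+FP+FN), Jaccard TP/(TP+FP+FN),
MCC, and the operating-point AUC (Se+Sp)/2; `auc_sweep()` offers a
full 256-threshold ROC AUC when the grayscale source is available.
Metrics with zero denominators are reported as `NA`, never silently
substituted. Note that two indicator formulas occasionally appear in
the literature with typographical slips (an extra TP in the accuracy
denominator; TP·TN in the Jaccard numerator); this package implements
the standard forms above.

## Clinical statistics

`paired_test(before, after)` performs the paired samples *t*-test on
`d = before − after` with pairwise deletion of incomplete rows
(degrees of freedom can therefore differ across parameters);
`pearson_pair()` gives the pair correlation, `describe_series()` the
descriptive row (range, min, max, mean ± SD, adjusted Fisher–Pearson
G1 skewness ± SE). `paired_from_summary(mean_diff, sd_diff, n)`
recomputes SE, t, CI and p from printed summary moments alone — useful
to audit published tables when the raw data are unavailable.

## Worked example

```r
library(neolungseg)

ph <- make_phantom(grade_default_spec(2, seed = 7))
ph
#> Phantom radiograph: grade II, 256 x 256, seed 7
#>   lung mask area: 18510 px (28.2% of frame)

res <- segment(ph$image)
res
#> Lung segmentation result (256 x 256)
#>   threshold used: 164
#>   binarize        17666 foreground px
#>   dilate          20540 foreground px
#>   remove_small    20540 foreground px
#>   roi             20540 foreground px
#>   apply_mask      20540 foreground px
#>   close           20540 foreground px

evaluate_pair(ph$gt_mask, res$closed)
#> Segmentation performance indicators
#>   sensitivity  0.9957
#>   specificity  0.9552
#>   accuracy     0.9666
#>   precision    0.8973
#>   f_measure    0.9440
#>   dice         0.9440
#>   mcc          0.9228
#>   jaccard      0.8939
#>   auc          0.9754
```

The Otsu threshold (164) separates the radiolucent lung fields from
the soft-tissue background; the Dice of 0.944 says the recovered mask
overlaps 94 % of the true lung area. On the statistics side, auditing
a published base-excess row (mean difference −7.97 ± 6.55 over 32
pairs):

```r
paired_from_summary(-7.97, 6.55, 32)
#> $se       1.16
#> $ci_low  -10.3
#> $ci_high  -5.61
#> $t        -6.88
#> $df       31
#> $p        1.02e-07
```

i.e. a highly significant post-treatment improvement in acid–base
status.

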