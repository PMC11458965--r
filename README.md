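# ReefChange

Quantifying coral-cover change from shallow-water multispectral radiance
scenes.

Coral reefs are monitored from satellites because field surveys are
expensive and sparse, but two obstacles stand between a Landsat-like scene
and a coral map: the water column, which attenuates light exponentially
with depth and swamps the bottom signal, and site specificity, because a
classifier trained on one reef's surveys rarely transfers to another reef.
ReefChange implements a complete, tested pipeline for both problems plus
the downstream change analysis, aimed at remote-sensing scientists and reef
ecologists who want a reproducible desk-scale implementation of the method.

## The method

Radiance in band $i$ over a shallow bottom follows the two-flow model
$L_i = L_{si} + a_i r_i e^{-f k_i z}$.  The pipeline:

1. **Preprocessing** — quality-band masking (cloud/land bits), NIR water
   masking (water absorbs NIR), and dark-pixel subtraction of the mean
   deep-water radiance $L_{si}$, with non-positive corrected pixels
   flagged invalid rather than clipped.
2. **Water-column correction** — for each visible band pair, the
   attenuation ratio comes from the log-radiance moments alone,
   $a = (\sigma_{ii}-\sigma_{jj})/(2\sigma_{ij})$,
   $k_i/k_j = a + \sqrt{a^2+1}$, giving the per-pixel depth-invariant
   index $DII_{ij} = \ln(L_i-L_{si}) - (k_i/k_j)\ln(L_j-L_{sj})$, which
   depends on the bottom type but not on depth.
3. **Classification** — percent-cover ground truth binarized to
   coral/non-coral, balanced by stratified undersampling, then a
   radial-basis SVM tuned by stratified 5-fold grid-search CV over
   $(\gamma, C)$, producing posterior-probability and thresholded class
   rasters.  Protocols: single-site, cross-site (train A, test B), and a
   consolidated model pooling multiple sites.
4. **Evaluation** — precision, recall, specificity, accuracy, F-measure,
   Cohen's kappa, and ROC/AUC.
5. **Change analysis** — per-pixel transition raster between two epochs
   over the shared valid mask, with pixel→km² conversion, percent change
   and coral share of the shallow benthic area.

A seeded radiative simulator (module one of the package, not a test
helper) generates two-epoch Landsat-like scene pairs — depth field, benthic
patches, deep-water strip, land, clouds, sensor noise, and a programmed
coral→non-coral conversion — so every stage is testable against known
truth.

## Worked example

Simulate a reef, lose 10 % of its coral, and see whether the pipeline
notices:

```r
library(ReefChange)
sim <- simulateSite("A", seed = 1, changeFraction = 0.10)
res <- runSingleSite(sim)
res$metrics
#> MetricsReport (n = 404):
#>   accuracy    0.9950
#>   precision   0.9950
#>   recall      0.9950
#>   specificity 0.9950
#>   F-measure   0.9950
#>   kappa       0.9901
res$change
#> Coral-cover change report
#>   transitions: coral->coral 2130, coral->non 272, non->coral 57, non->non 7824
#>   coral pixels: 2,402 -> 2,187  (2.16 -> 1.97 km^2 at 30 m)
#>   change in coral cover: 9.0%
#>   coral share of shallow benthic area: 23.4% -> 21.3%
```

The survey of 1287 points balances to 404 (202 per class); out-of-fold CV
metrics are near-perfect on this clean simulation, and the programmed 10 %
coral loss is recovered as 9.0 % — classifier error leaks a little across
the epochs, which is exactly what the stochastic acceptance property
bounds (±2 percentage points on the median over 10 seeds).

The same metric and accounting machinery applied to published-scale
inputs — a balanced 448-point evaluation with counts TP = 165, FN = 59,
FP = 71, TN = 153, and a 282,302-pixel shallow scene whose coral count
drops from 147,014 to 130,225 at 30 m resolution:

```r
classifierMetrics(confusionFromCounts(tp = 165, fn = 59, fp = 71, tn = 153))
#> MetricsReport (n = 448):
#>   accuracy    0.7098
#>   precision   0.6992
#>   recall      0.7366
#>   specificity 0.6830
#>   F-measure   0.7174
#>   kappa       0.4196
changeReportFromCounts(147014, 130225, nValid = 282302)
#> Coral-cover change report
#>   coral pixels: 147,014 -> 130,225  (132.31 -> 117.20 km^2 at 30 m)
#>   change in coral cover: 11.4%
#>   coral share of shallow benthic area: 52.1% -> 46.1%
```

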