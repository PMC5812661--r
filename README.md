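# hepamri

Multiparametric MRI quantification of liver regeneration after partial
hepatectomy, as a tested R pipeline.

After a large liver resection the remnant regenerates within days, and
whether it can is the clinical question behind small-for-size syndrome
and fatal post-hepatectomy liver failure (PLF). Quantitative MRI tracks
this process non-invasively: longitudinal relaxation T1 rises with the
water influx of hepatocyte hypertrophy, transverse relaxation T2 rises
later, the apparent diffusion coefficient (ADC) falls as swollen cells
restrict water diffusion, and the magnetization transfer ratio (MTR)
falls as the cytoplasm dilutes. `hepamri` implements the full
quantification chain for a longitudinal mouse cohort (conventional 70%
hepatectomy, extended 86% hepatectomy, its fatal PLF subgroup, and SHAM
surgery, measured on days 0–7):

* **Voxel-wise parameter maps** — inversion-recovery trueFISP T1 fitting
  (Levenberg–Marquardt on the magnitude model
  `|S0(1 − INV·e^(−TI/T1*))|`, then `T1 = T1*·cos(α/2)·(INV−1)`),
  three-parameter multi-echo T2 fitting (`S0·e^(−TE/T2) + N`),
  closed-form two-point ADC (`ln(S(b0)/S(b))/b`) and MTR
  (`(M0 − Msat)/M0`) maps, with plausibility gates and explicit validity
  masks.
* **Noise handling** — Rician background-noise estimation from a corner
  ROI (Rayleigh-mean inversion) and squared-subtraction bias correction
  `sqrt(max(S² − N², 0))`.
* **ROI statistics and volumetry** — polygon rasterization
  (voxel-centre even-odd rule), automatic placement of three vessel-free
  parenchymal ROIs, slice-summation liver volume and baseline-normalized
  relative volume.
* **Cohort statistics** — group summaries, integer percent changes of
  group means, two-way (group × day) ANOVA with Bonferroni-adjusted
  per-day group contrasts on censored unbalanced data, Pearson
  correlation of MR parameters against regenerating volume, and binomial
  logistic regression of PLF death with Nagelkerke R².
* **A digital liver phantom and cohort simulator** — ellipsoidal liver
  with embedded vessel tubes and published group-mean/SD trajectories,
  Rician noise and the study's censoring structure, providing ground
  truth for every stage (no image data are deposited with studies of
  this kind).

NIfTI images with JSON sidecars are the interchange format
(`writeAcquisitionSeries()`, `writeParameterMap()`, `writeRoiSet()`);
`runPipeline()` ties simulation, fitting, ROI readout, volumetry and
statistics together under a single seed.

## Worked example

Simulate the study cohort, summarize it, and check the headline
percent-change figures:

```r
library(hepamri)

co <- simulateCohort(seed = 42)
s  <- groupSummary(co$table)
s[s$parameter == "T1" & s$group == "ePH", ]
#>  group day parameter n      mean        sd
#>    ePH   0        T1 7  986.3824  61.59576
#>    ePH   1        T1 7 1323.3766 143.52934
#>    ePH   2        T1 7 1432.3185 137.56319
#>    ePH   3        T1 7 1313.9484  53.07794
#>    ePH   5        T1 7 1161.9084  67.63178
#>    ePH   7        T1 7 1076.2633  81.43235
```

The extended-resection group's T1 jumps from ~986 ms to ~1430 ms by day
2 and then relaxes back toward baseline — the regeneration signature the
method is built to measure. Correlating T1 with the regenerating volume:

```r
r <- pearsonVolumeCorrelation(co$table, "ePH", "T1")
#> ePH T1 vs volume: r = -0.785, p = 7.5e-10, n = 42
```

a strong negative correlation: the smaller the remnant, the longer its
T1. Feeding the *reference* group means (rather than a finite cohort
draw) through the percent-change arithmetic reproduces the nine
published integer figures exactly:

```r
reproduceAbstractChanges(referenceGroupValues())
#>  parameter day group direction expected computed pass
#>         T1   1   cPH  increase       18       18 TRUE
#>         T1   1   ePH  increase       40       40 TRUE
#>         T1   2   cPH  increase       24       24 TRUE
#>         T1   2   ePH  increase       49       49 TRUE
#>         T2   5   cPH  increase       21       21 TRUE
#>         T2   5   ePH  increase       41       41 TRUE
#>        ADC   1   cPH  decrease       13       13 TRUE
#>        MTR   1   cPH  decrease       11       11 TRUE
#>        MTR   1   ePH  decrease       15       15 TRUE
```

Voxel-wise fitting on a phantom:

```r
ph   <- buildPhantom(dim = c(24, 24), seed = 3)
s    <- simulateAcquisitions(ph, protocolMeta("ir_truefisp"), sigma = 20)
fit  <- fitT1Map(s, mask = liverMask(ph))
rois <- autoPlaceRois(ph)
roiStatistic(parameterMaps(fit)$T1, rois)$mean   # ~997 ms
```

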