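# imatQuant

Dual-modality quantification of **intramuscular adipose tissue (IntraMAT)**
on 2-D mid-thigh MR cross-sections, for muscle physiology and body
composition researchers who need to understand — and reproduce — why
T1-weighted and two-point Dixon estimates of the same muscle disagree.

Fat within a muscle's boundary rises with age and disease and tracks
insulin resistance and loss of contractile function. Two standard
estimates exist for a muscle mask *M* on an axial slice:

* **T1-weighted thresholding.** After N3-style correction of the
  multiplicative coil bias field, a reference histogram is pooled from six
  25 mm² ROIs (three on the vastus intermedius, three on subcutaneous
  fat), Otsu's criterion gives the threshold *t* (mean of three random
  ROI-placement trials), and

  IntraMAT (%) = n(I > t) / [n(I ≤ t) + n(I > t)] × 100.

* **Two-point Dixon.** With water and fat channel means over the mask,

  IntraMAT (%) = 100 · F̄ / (W̄ + F̄)   (ratio of means).

The package implements both pipelines end to end, plus the agreement
toolbox used to localize their discrepancy: Bland-Altman limits of
agreement with proportional-bias testing (d = 2PD − T1W), ICC(2,1)
reproducibility, the *boundary value* (the T1W threshold that would
reproduce the Dixon percent) with its discrepancy correlation, and
subtraction-method SNR. A parametric thigh phantom (`makePhantom`) with
exact per-muscle ground truth, marbled infiltration, a fat-dominant
partial-volume band, Gaussian/Rician noise and a smooth bias field makes
every stage testable without subject data.

## Worked example

Simulate a 12-subject cohort spanning low to high infiltration with a
2-px partial-volume band, quantify every muscle with both methods, and
test for proportional bias:

```r
library(imatQuant)
spec  <- phantomSpec(noiseSD = 5, biasAmplitude = 0, partialVolumeWidth = 2)
study <- runPhantomStudy(nSubjects = 12, spec = spec,
                         fatFractionScale = seq(0.45, 3, length.out = 12),
                         seed = 1, correctBias = FALSE)
head(study$quant, 6)
#>  subject muscle method thresholdMean nMuscle nFat intramatPercent csaCm2
#>      S01     VL    T1W      112.0421    1567  229       12.750557  17.96
#>      S01     VL    2PD            NA      NA   NA       10.124279  17.96
#>      S01     AM    T1W      112.0421    1620  176        9.799555  17.96
#>      S01     AM    2PD            NA      NA   NA        7.744074  17.96
#>      S01    BFL    T1W      112.0421    1601  195       10.857461  17.96
#>      S01    BFL    2PD            NA      NA   NA        9.123135  17.96

study$blandAltman$pooled
#> Bland-Altman (d = 2PD - T1W), n = 36
#>   mean diff -4.866%, LoA [-7.349, -2.383]
#>   proportional bias: r = -0.836, p = 2.11e-10 (significant)
```

Read: with a partial-volume band, T1W binarization counts majority-fat
mixed pixels as wholly fat, so T1W runs ~5 points above Dixon on average
and the gap grows with infiltration — the significant negative
proportional-bias correlation. The per-subject Otsu threshold (~112 a.u.)
sits at the right edge of the muscle peak, and `boundaryValue()` shows the
Dixon-equivalent threshold sits higher; `discrepancyAnalysis()` correlates
the two gaps across subjects.

Other entry points: `n3Correct()` (bias-field correction, optional
coarse-to-fine `stages`), `thresholdTrials()` / `quantifyT1W()` /
`computeCSA()`, `quantifyDixon()` / `fatFractionMap()`, `icc21()`,
`snrSubtraction()`, `compareGroups()`, NIfTI/TIFF readers and writers
(`readImage2D`, `writePhantom`), and `runPipeline()` over a YAML config.
A thin command-line front end with verbs `phantom`, `biascorrect`, `t1w`,
`dixon`, `agree` and `run` is installed at `inst/cli/imat.R`.

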