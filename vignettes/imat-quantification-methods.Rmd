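---
title: "Quantifying intramuscular adipose tissue from T1-weighted and two-point Dixon MRI"
author: "imatQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intramuscular adipose tissue from T1-weighted and two-point Dixon MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imatQuant)
```

## The measurement problem

Intramuscular adipose tissue (IntraMAT) — fat located within a muscle's
anatomical boundary — rises with age and disease and correlates with
insulin resistance and loss of muscle function. Two MR approaches dominate
its per-muscle quantification on axial thigh slices:

* **T1-weighted thresholding.** Fat is bright on T1W images. A reference
  histogram is built from small regions of interest (ROIs) placed on a
  tissue known to be essentially pure muscle (the vastus intermedius, VI)
  and on subcutaneous fat; Otsu's criterion picks the intensity threshold
  separating the two classes; each analysed muscle's pixels are then
  classified, and
  $$\mathrm{IntraMAT}\,(\%) = \frac{n_{\mathrm{fat}}}{n_{\mathrm{muscle}}
  + n_{\mathrm{fat}}} \times 100 .$$
  Pixels exactly at the threshold count as muscle ("lower than the
  threshold" is muscle; the classification rule is $>$ for fat).
* **Two-point Dixon (2PD).** In/out-of-phase echoes give co-registered
  water ($W$) and fat ($F$) images, and
  $$\mathrm{IntraMAT}\,(\%) = \frac{\bar F}{\bar W + \bar F} \times 100,$$
  the **ratio of channel means** over the muscle mask — not the mean of
  per-pixel ratios. The two differ on heterogeneous masks (a Jensen gap);
  `quantifyDixon(..., method = "mean_of_ratios")` exposes the alternative
  for sensitivity analysis.

The two estimates disagree in practice, most strongly in fatty muscles.
The package implements both pipelines, the agreement statistics used to
characterize the disagreement, and a synthetic phantom that reproduces its
mechanism with known ground truth.

## The phantom

`makePhantom(phantomSpec())` builds a 256 × 256 px axial mid-thigh slice at
1 mm spacing: an elliptical thigh with a subcutaneous fat ring, femur
(signal-poor cortical shell around fat-bright marrow), and four muscle
compartments (VL, VI, AM, BF-L). Choices that matter:

* **Exact-count infiltration.** Each infiltrated muscle receives exactly
  `round(p * N)` fat pixels, the top-ranked pixels of a Gaussian-smoothed
  noise field (correlation length `marblingScale`, default 3 mm), with
  rank ties broken by pixel index. Ground truth is therefore quantized and
  exact, not an expected value: recovery can be tested to one pixel
  quantum ($100/N$ percentage points).
* **The vastus intermedius stays fat-free** by construction — it is the
  pure-muscle reference the ROI protocol assumes.
* **Uniform proton signal.** Dixon channels are $W = S(1-\mathrm{ff})$,
  $F = S\,\mathrm{ff}$ with the proton signal $S$ spatially uniform over
  tissue, so the noiseless channels sum to $S$ everywhere and the
  ratio-of-means recovers the mean fat fraction exactly. Water and fat
  proton densities are similar enough that this idealization is the
  natural reference condition for validating the estimator itself.
* **Fat-dominant partial-volume band.** Pixels within
  `partialVolumeWidth` (default 2 px) of a fat cluster get linearly mixed
  intensity and fat fraction with
  $\alpha(d) = (1 - d/(w+1))^{q}$, $q = 0.5$. The concave profile makes
  near-cluster voxels majority-fat, for two physical reasons: a voxel
  adjacent to a resolved fat streak usually contains sub-voxel extensions
  of the streak, and T1-weighting over-represents fat — at a short
  repetition time the T1W signal per unit fat volume is roughly 2.3 times
  that of muscle ($1-e^{-TR/T_1}$ with $T_1 \approx$ 370 ms for fat vs
  1400 ms for muscle at 3 T), so mixed voxels read fat-bright. This band
  is the knob that reproduces the observed inter-method bias: binarization
  counts a majority-fat voxel as wholly fat, while the Dixon ratio counts
  its actual fat content.
* **Noise is Gaussian** (default sd 5 a.u. = 5% of muscle signal) so
  analytic checks stay exact; a Rician option exists (`rician = TRUE`)
  for magnitude-image realism. At the phantom's SNR (20:1) the Rician
  bias on tissue is negligible.
* **The bias field** is the exponential of smoothed white noise
  (default scale 60 mm), affinely rescaled so its mean over tissue is 1
  and its peak deviation **on tissue** equals `biasAmplitude`
  (default 0.2) — referencing the amplitude to the anatomy rather than to
  a background corner makes "amplitude 0.3" mean what it says for the
  muscles.
* Default fat fractions (VL 0.12, AM 0.09, BF-L 0.13) sit at the values
  reported for healthy adult thighs by Dixon imaging.

What the phantom does **not** model: through-plane averaging (acquisitions
with different slice thicknesses are treated as the same 2-D slice),
chemical-shift displacement, T2*/B0 effects, k-space artifacts, and
anatomy beyond parametric ellipses. Passing tests therefore validate the
estimators and their failure mechanism, not scanner physics.

## Bias-field correction

`n3Correct()` implements a 2-D nonparametric intensity-nonuniformity
correction in the N3 family, with the parameter block conventionally used
for thigh T1W data: end tolerance $10^{-4}$ on the coefficient of
variation of the per-iteration field change, at most 100 iterations,
signal threshold 1 a.u., field distance 25 mm, subsampling factor 4,
sharpening kernel FWHM 0.15 (log-intensity units), Wiener noise constant
0.01, 200 histogram bins. Per iteration: (1) the foreground log-intensity
histogram is sharpened by Wiener deconvolution of the Gaussian kernel;
(2) each pixel's expected true log-intensity under the sharpened density
is computed; (3) the residual is smoothed by a Gaussian of
$\sigma = \mathrm{fieldDistance}/2.355$ (a stand-in for the B-spline
smoother at the same smoothness scale) via normalized convolution over the
foreground, with the weights floored at 0.05 so the estimate decays to
zero away from foreground support instead of amplifying empty
neighbourhoods; (4) the smoothed residual accumulates into the log-field.
The final field is upsampled bilinearly, exponentiated, normalized to mean
1 over the foreground; the background passes through unchanged.

Two practical notes, both visible in the tests:

* **Signal threshold.** The threshold is in image units and must sit above
  the background noise floor. On synthetic images with $N(0, 5)$
  background, threshold 1 admits half the background, whose log-intensities
  destabilize the field; phantom studies therefore use
  `signalThreshold = 15` ($3\times$ the noise sd) while the default stays
  at the protocol value.
* **Coarse-to-fine stages.** When the bias spread approaches the
  muscle/fat contrast (amplitude 0.3: log-spread ~0.26 vs class
  separation 0.69), dark-region fat can overlap bright-region muscle in
  intensity, and a histogram-only estimator can lock onto a sign-flipped
  field. `n3Correct(..., stages = 3)` first estimates the field at 4x and
  2x the field distance, correcting as it goes; capturing the global
  gradient first keeps class assignment in the right basin. A small
  fraction of field realizations remains intrinsically ambiguous (the
  intensity overlap is exact); no histogram method resolves those without
  spatial priors, which is why the validation reports a median over
  realizations.

## Thresholding protocol

`placeROIs()` places six 25 mm² square ROIs — three on the VI, three on
subcutaneous fat — at random fully-interior, non-overlapping sites;
`thresholdTrials()` repeats placement + histogram (256 bins over the
pooled range) + Otsu three times and averages the thresholds, mimicking
the averaging of manual placements; the mean threshold is applied to all
muscles of the subject. Otsu ties — including the flat
between-class-variance plateau that a well-separated bimodal reference
histogram produces across its empty gap — resolve to the **lowest** cut
(with a $10^{-10}$ relative tolerance so exact mathematical ties are not
broken by summation order). Consequently the threshold sits at the right
edge of the muscle peak, just above the largest sampled reference muscle
intensity. Two consequences follow:

* a small, fat-fraction-dependent inflation of T1W IntraMAT from the
  muscle noise tail (about $(1-2p)\cdot 0.9$ percentage points at 5%
  noise), which is why the noisy-cohort validation bounds the **mean**
  absolute recovery error rather than each single measurement;
* every partial-volume pixel above the muscle peak is counted as fat,
  which — combined with the fat-dominant band — yields the T1W > 2PD
  bias that grows with infiltration.

## Agreement analyses

* **Bland-Altman** (`blandAltman`): differences are $d =$ 2PD − T1W,
  limits of agreement at mean ± 1.96 sd, proportional bias as the Pearson
  correlation of $d$ with the pair mean (significant at $p<0.05$). With
  the convention above, T1W overestimation growing with fat level appears
  as a **negative** proportional-bias correlation.
* **Boundary value** (`boundaryValue`): the smallest masked intensity
  whose strict-exceedance fraction is at most the target percent — the
  threshold that would reproduce the Dixon percent on the T1W histogram.
  `boundaryRecord` stores `deltaIntensity = boundaryValue − threshold`
  (how far the applied threshold sits below the Dixon-equivalent one) and
  `deltaIntramat = 2PD − T1W`; `discrepancyAnalysis` correlates them.
  Because both deltas are monotone functions of the threshold's position
  through the same exceedance curve, the correlation is negative by
  mechanism; the validation cohort forces thresholds progressively below
  each subject's boundary value to span the axis, and recovers
  $r \approx -0.96$.
* **ICC(2,1)** (`icc21`): two-way random effects, absolute agreement,
  single measure, from directly accumulated sums of squares (so identical
  sessions return exactly 1).
* **Student's unpaired t-test** (`unpairedTTest`, `compareGroups`):
  pooled variance by default, Welch behind a flag. The protocol applies an
  unpaired test even to within-subject method comparisons; this is kept
  for fidelity, and a paired analysis is available through
  `stats::t.test(paired = TRUE)` if wanted. No multiple-testing
  correction is applied, matching the protocol ($\alpha = 0.05$,
  two-tailed).
* **Subtraction SNR** (`snrSubtraction`): per corner ROI, mean of the
  two-image average divided by sd(difference)$/\sqrt2$; a zero difference
  sd returns an infinite-SNR sentinel.

## Worked example

```{r example, eval = FALSE}
spec <- phantomSpec(noiseSD = 5, biasAmplitude = 0, partialVolumeWidth = 2)
study <- runPhantomStudy(nSubjects = 12, spec = spec,
                         fatFractionScale = seq(0.45, 3, length.out = 12),
                         seed = 1, correctBias = FALSE)
head(study$quant)
study$blandAltman$pooled
study$discrepancy
```

## Numerical choices and degenerate inputs

* Histograms: 256 bins over the pooled ROI range; a degenerate
  (single-valued) range is an error, as is a single nonempty bin.
* `boundaryValue` at target 0 returns the masked maximum; at target 100,
  the masked minimum; re-thresholding reproduces the target within one
  pixel quantum when intensities are untied.
* Zero-variance inputs error in `icc21`, `discrepancyAnalysis` and
  `unpairedTTest`; constant Bland-Altman differences return `NA`
  proportional-bias fields rather than an error.
* All randomized operations (`makePhantom`, `placeROIs`,
  `thresholdTrials`, `runPhantomStudy`) are pure functions of their seed;
  pipeline outputs embed the configuration hash and seed.

## Validation scale

The shipped validation (tests and `scripts/acceptance.R`) uses cohorts of
8–12 phantoms at 256 × 256 px, three muscles per subject, 10-seed paired
experiments for the correction study, 1000 random histograms for the
Otsu oracle, 500 boundary round-trips, 100 ICC matrices, $10^5$
Bland-Altman pairs and $10^4$-pixel SNR ROIs — sizes at which every check
completes in minutes on one CPU while keeping the statistical margins
described above.

## Known limitations

* Histogram-only bias correction cannot resolve intensity-ambiguous field
  realizations (see above); correlations with the true field are reported
  as medians for that reason.
* The threshold pipeline's tie rule makes T1W estimates slightly
  conservative-high at low fat fractions; this is a property of the
  protocol being modeled, not a removable bug, and is quantified in the
  tests.
* Real tissue texture, fascia, vessels and nerve bundles are absent; real
  histograms are broader and less cleanly bimodal than the phantom's, so
  absolute thresholds on real data will differ even though the mechanism
  carries over.
* Registration between T1W and Dixon images is assumed perfect (phantom
  channels are constructed co-registered); none is performed.
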