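---
title: "Pixel-level NIR hyperspectral detection of codling moth infestation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pixel-level NIR hyperspectral detection of codling moth infestation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calyxscan)
```

## The problem

Codling moth (*Cydia pomonella*) larvae enter apples preferentially at the
calyx (blossom) end and tunnel inward, leaving little external evidence.
Infested tissue reflects systematically less light in the near infrared
(900--1700 nm) than healthy tissue, because infestation alters water
content, cell structure and pigment composition. A line-scan (push-broom)
NIR camera produces a *hypercube* -- two spatial axes by one spectral axis
-- in which every pixel carries a full reflectance spectrum, so infestation
can be detected and localized at the pixel level rather than per fruit.

`calyxscan` implements this workflow end to end: reflectance calibration,
automatic calyx-centered region-of-interest (ROI) acquisition, chemometric
preprocessing, a deterministic train/validation split, PCA-based
classification with a bank of standard classifiers, and greedy wavelength
selection for designing cheaper multispectral instruments. Because real
infested-apple hypercubes are not openly deposited, the package ships a
synthetic scene generator that emulates the salient structure of such data
and makes every stage testable.

## Reflectance calibration

Raw counts are converted to relative reflectance with daily white/dark
reference images:

$$R = \frac{R_0 - R_d}{R_w - R_d}$$

where $R_0$ is the raw cube, $R_w$ the white reference (a high-reflectivity
PTFE panel) and $R_d$ the dark current (lens capped). Two conventions are
supported for the reference geometry: full-frame references, and per-column
line averages (`collapse_reference()`), which is the natural convention for
a push-broom instrument where every image row is acquired by the same
sensor line; the line average is the default recommendation because it
suppresses reference noise. Denominator cells where $|R_w - R_d|$ falls
below `epsilon` (default `1e-6` counts) are set to 0 and counted in the
output metadata rather than propagating infinities. Negative reflectance
(raw below dark) is preserved by default -- clipping is opt-in -- because
the preprocessing chain is scale- and offset-tolerant and clipping discards
information.

Calibration is exactly invariant under a common affine change of all three
images (gain and offset of the sensor), which the test suite verifies on
random cubes.

## Automatic calyx ROI acquisition

The acquisition chain works on the single band nearest 1084 nm, where the
calyx cavity appears dark against bright fruit flesh and the background is
darker still:

1. **Threshold** the band image. The default is Otsu's
   between-class-variance maximizer on a 256-level histogram over the
   observed range (parameter-free and reproducible); a fixed threshold is
   available as an override. Bright pixels form the *flesh* mask.
2. **Isolate the cavity**: fill the holes of the flesh mask and subtract
   the flesh, leaving dark regions enclosed by the fruit disk. This
   two-stage rule separates the calyx from the (equally dark) background.
3. **Erode** the candidate region with a Euclidean disk element (default
   radius 2 px) to remove thin artifacts and leave a solid area. Pixels
   outside the image count as background. Digital disks are not
   radius-additive, so iterated erosion is not bit-identical to a single
   larger erosion; the package always erodes once with the configured
   radius.
4. **Centroid** of the largest 8-connected remaining component -- the
   stem/calyx cavity is the dominant dark feature in calyx-view images.
5. **Circular ROI** of 50 px diameter (default) around the centroid.
   A pixel belongs to the ROI iff the Euclidean distance from its center
   to the centroid is at most diameter/2, boundary inclusive, clipped at
   the image borders.

The erosion radius, threshold method, connectivity and boundary rule are
all deliberate choices where the procedure is conventionally described
only as "thresholding, erosion, centroid, circle"; each is exposed in the
API and recorded in the returned `roi_result` so a run is fully
reproducible from its outputs.

Two comparison extraction modes are provided: the whole-fruit **mean
spectrum** (one observation per apple) and a **manual 10 x 10 rectangle**
at the calyx (100 pixel spectra per apple). These mirror the common
alternatives to automatic pixel-level extraction and share the same
downstream pipeline.

Every ROI pixel inherits the apple-level label (`infested` apples
contribute only `infested` pixels). This is the standard labeling
shortcut of pixel-level fruit studies and a known label-noise source: ROI
pixels of an infested apple that happen to be healthy tissue are still
labeled infested. The synthetic generator reproduces this situation
faithfully (the lesion occupies only part of the ROI).

## Preprocessing chain

Applied to the pixel-spectra table in fixed order:

1. **Wavelength trimming** (default 950--1650 nm) removes the noisy sensor
   edges. The defaults are a conventional choice for InGaAs line-scan
   instruments; the exact endpoints are configurable.
2. **Maximum normalization** divides each spectrum by its own maximum, so
   every spectrum peaks at exactly 1. This cancels flat multiplicative
   factors: illumination gain, path length, fruit curvature.
3. **Savitzky--Golay smoothing** (second-order polynomial, 31-point window
   by default) along the band axis. Edges use the polynomial-fit mode (the
   local polynomial is evaluated at the ends) rather than shrinking the
   window, so no bands are lost after trimming has already sacrificed the
   edges. The filter reproduces polynomials up to the fitting order
   exactly in the interior, which the tests assert to 1e-8.
4. **Mean centering** with the *training* mean. The package deliberately
   computes centering statistics on the training split only and reuses
   them on validation data, preventing information leakage; this is
   stricter than centering the pooled table.

Normalization precedes smoothing, matching the conventional listing of the
chain; the reverse order is also seen in the literature and can be
emulated by composing the exported steps manually.

## Dataset split

The Kennard--Stone algorithm selects the training set deterministically:
seed with the two most distant spectra, then repeatedly add the spectrum
whose minimum distance to the selected set is largest, until 70% of rows
are selected. Distances are plain Euclidean in full band space -- not PCA
space -- so the split does not depend on PCA settings. Because Euclidean
distances are invariant to subtracting a common vector, the split is
unaffected by whether centering happened before it; the pipeline exploits
this by splitting first and re-centering with the training mean.

The split is performed on pixels pooled across apples, which matches
pixel-level practice but lets pixels of one apple straddle the split;
constructing per-apple tables and splitting those by hand is the stricter
alternative for users who want grouped validation.

## Classification

PCA is fitted on the training spectra (covariance eigendecomposition,
loadings sign-fixed so the largest-magnitude entry is positive). Three
components are the default feature set -- on NIR apple spectra the first
three components typically carry upward of 98% of the variance -- with a
cumulative-variance target available instead.

The classifier bank: LDA, kNN (k = 5), SVM (RBF, C = 1), random forest
(500 trees), gradient tree boosting (500 rounds, depth 3, learning rate
0.1), PLS-DA and AdaBoost (100 stumps). PLS-DA is PLS1 regression on a
0/1-coded response thresholded at 0.5, the standard discriminant use of
PLS. None of these hyperparameters is canonical; all are exposed and
logged in every report. `infested` is the positive class throughout, and
reports carry per-class precision, recall, F1 ($2RP/(R+P)$) and total
accuracy for train, validation and stratified 5-fold cross-validation
(mean and fold standard deviation).

Stratified folding lays the classes out in a single cycling fold sequence
so total fold sizes differ by at most one while both classes appear in
every fold. The fold assignment is drawn once from the seed and returned
with the result, making every cross-validated number exactly reproducible.

## Wavelength selection

Sequential forward selection is a wrapper: at step $t$ every unselected
band is appended to the current set, scored by stratified-CV mean accuracy
(or F1), and the best band is kept; ties break toward the lower band
index. The fold assignment is frozen once per run so all candidates at all
steps are judged on identical folds and the greedy path is deterministic
given the seed. No early stopping is applied -- the accuracy-vs-k curve is
returned in full and the user picks the knee, because the conventional
stopping rule ("the curve approaches an asymptote") is visual, not
numeric. Only forward addition is implemented: the selection path adds one
wavelength per iteration and never removes one.

The criterion classifier defaults to the final model family (GTB) with a
cheaper 100-round profile for tractability inside the wrapper loop; any
bank member can be substituted, and the package's own recovery checks use
LDA, which is two orders of magnitude faster and equally able to rank a
mean-shift band signal.

## The synthetic scene generator

`generate_scene()` emulates what matters about calyx-view apple
hypercubes, and nothing more:

* **Spectral shape.** Healthy flesh is a smooth concave baseline times
  $(1 - \sum_i d_i e^{-(\lambda-c_i)^2/2w_i^2})$ with Gaussian absorption
  valleys at 950, 1200 and 1400 nm (first O--H overtones of water at
  950/1200; combined C--H second and O--H first overtone near 1400).
* **Infestation effect.** Infested reflectance is
  `healthy * (effect + (1 - effect) * 0.8 * (1 - u))` with `u` the
  normalized wavelength and `effect = 0.85` by default: strictly lower
  reflectance at every band, with a wavelength-dependent depression. The
  wavelength dependence is essential -- a flat multiplicative factor would
  be erased exactly by maximum normalization, leaving nothing to detect;
  a spectrally varying one changes the normalized curve shape, which is
  what real biochemical change does.
* **Scene geometry.** A bright fruit disk on a dark background, a darker
  calyx cavity (healthy x 0.25), and for infested apples a lesion disk
  around the calyx. Ground-truth masks are returned for every region.
* **Sensor model.** Per-pixel scalar gain (sd 0.03, a path-length proxy),
  additive band noise (sd 0.01 reflectance units), a mildly non-flat white
  envelope (~3500 counts) and a dark current of 80 counts. Reflectance maps
  to counts through the same forward model that `calibrate()` inverts, so
  a zero-noise scene calibrates back to its endmembers exactly. Raw counts
  clamp at zero, as a real sensor's do.
* **Between-apple variability** (`generate_study()`) is a geometric jitter
  of the fruit/calyx placement plus a scalar per-apple reflectance gain.
  Both are exactly the nuisances the preprocessing chain removes, which is
  a deliberate pair of design decisions: with `effect = 1` the study is a
  true null (no classifier should beat chance even though pixels of one
  apple can land on both sides of the pooled split), and the preprocessing
  chain is meaningfully exercised rather than decorative.

What the generator does **not** emulate: radiative transfer, cultivar
chemistry, larval tunnel morphology, specular highlights, sensor smile or
spatial noise correlation. Consequently, passing end-to-end tests
demonstrates that the pipeline is correct and well calibrated -- it does
not certify field performance on real fruit, where the class effect is
subtler and confounded with cultivar and geometry.

## Problem sizes and numerical choices

The shipped test suite and acceptance script run desk-scale versions of
the study: 96 x 96 px scenes with 80 bands, 6 control + 6 infested apples,
26 px ROI diameter (about 6,400 labeled pixels), GTB at 150 rounds, and
wavelength-selection fixtures of 480 x 128 with a 5-band signal. These
sizes were chosen so the full suite completes in minutes on one core while
every statistical conclusion (null calibration within the 99% binomial
band, power >= 0.95, band recovery in >= 8/10 seeds) remains well
separated from its threshold. The 200 x 200 x 128 generator default and
the 256-band preset reproduce the full-scale geometry when wanted.

Numerical conventions worth knowing:

* wavelength-to-band resolution is nearest-center with ties to the lower
  index, refusing targets beyond half the median band spacing outside the
  grid;
* Kennard--Stone ties break toward the lower row index, and the seed pair
  is reported lower-index first;
* PCA eigenvalue ratios are computed against the total variance of all
  components; the variance-target mode picks the smallest count reaching
  the target (with a 1e-12 slack against floating rounding);
* all stochastic learners take explicit seeds, and the pipeline derives
  per-stage seeds from the master seed so any stage can be reproduced in
  isolation;
* degenerate inputs fail loudly with classed conditions
  (`calyxscan_*_error`) naming the offending field, row or stage.

## Known limitations

* The ROI chain assumes a calyx-view image with a single dominant dark
  cavity; stem-view images (where the stem plays the same role) work, but
  side views without a cavity correctly raise a no-calyx error rather than
  guessing.
* Pixel labels inherit the apple label; on real data some "infested"
  pixels are healthy tissue, bounding attainable pixel-level accuracy.
* The pooled pixel split can place pixels of one apple in both partitions;
  grouped splitting is available but not the default, to match pixel-level
  practice.
* PLS-DA uses a fixed latent-variable count (default 10) rather than
  internal CV tuning.
* ENVI support covers BIL/BIP/BSQ interleaves with uint16/float32 samples,
  little endian, which spans common line-scan exports but not every ENVI
  dialect.
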