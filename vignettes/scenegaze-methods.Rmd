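---
title: "Methods: gaze metrics and image statistics for aerial scene viewing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze metrics and image statistics for aerial scene viewing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis problem

When experienced observers categorize aerial (overhead) scene photographs
under free viewing, their eye movements carry information about which image
properties drive attention: texture, luminance, salient diagnostic objects,
or higher-level category structure.  `scenegaze` implements a complete
analysis chain for such experiments: it screens raw fixation/saccade event
tables, computes five eye-movement variables per observer and image,
computes nine image statistics spanning low to object level, relates the two
sets through luminance-controlled stepwise regression at the image and the
scene-category level, and tests whether the image statistics are invariant
to right-angle image rotation.  A seeded synthetic-data generator emulates
the experimental design end to end, so every stage is testable against
planted ground truth.

The default design constants describe a typical laboratory setup: 12 scene
categories with 20 images each, 20 observers, 3-s trials, 600 x 600 px
stimuli at roughly 40 px per degree of visual angle (dva).

## Event screening

Recording starts 100 ms before stimulus onset, so the first recorded
fixation begins on the pre-stimulus cross and is treated as uninformative;
it is dropped before anything else happens.  Trials are then excluded when
(1) the scene was categorized incorrectly, (2) fewer than three valid
fixations remain, or (3) tracking was lost for more than 100 ms in a gap not
attributable to a blink.  After the trial rules, a participant is dropped
entirely if over 25% of their viewing time was lost to trackloss or over
25% of their trials were excluded.  Fixation filters then remove events
outside the image region, shorter than 100 ms, or longer than the dataset
grand mean plus two standard deviations of duration; saccade filters remove
onsets within 75 ms of stimulus onset (anticipation errors) and saccades
whose start or landing point lies outside the image.

Three decisions here were genuinely open:

* **Valid-fixation counting for trial rule 2.**  The rule needs fixation
  validity before the dataset-level duration statistics exist (trial rules
  run first).  We count fixations that pass the deterministic per-event
  rules only — not first, inside the image, at least 100 ms — which makes
  the trial stage self-contained.
* **The 2-SD cutoff scale and timing.**  Durations are near-lognormal, but
  the grand mean and SD are reported on the millisecond scale, so the
  cutoff is applied on that scale by default (`sd_scale = "log"` switches
  to log-space).  The grand statistics are computed after the < 100 ms
  removal by default (`sd_after_min`).
* **Idempotence.**  A data-dependent cutoff shrinks when recomputed on
  already-truncated data, so blind re-screening is not a no-op.
  `screen_fixations()` therefore records the cutoff it used and accepts it
  back as `duration_cutoff_ms`; with the recorded cutoff, screening is
  exactly idempotent (and tested to be).

The image region is the half-open rectangle `[0, W) x [0, H)` with origin at
the top-left corner, x rightward and y downward; the boundary coordinate
`W` is outside.  Events in the pre-stimulus window carry negative onsets and
are never valid.

## Eye-movement variables

For each observer x image cell the package computes:

* **Mean fixation duration** and the **number of fixations** per 3-s
  viewing.
* **Fixation density map (FDM) entropy.**  Fixation locations are binned
  on the pixel grid, convolved with an isotropic Gaussian of 0.5 dva full
  width at half maximum (about 20 px — matched to typical video-tracker
  accuracy), renormalized to unit mass, and summarized by Shannon entropy
  \(-\sum_{ij} p_{ij}\log_2 p_{ij}\).  Base-2 logarithms are used
  everywhere so both entropies share units (bits); the kernel is truncated
  at 4 standard deviations and edge mass handled by renormalization rather
  than reflection, the simplest choice that preserves unit mass.
* **Mean saccade amplitude** in dva.
* **Normalized gaze transition entropy (GTE).**  The image is divided into
  an \(n \times n\) grid of areas of interest (AOIs; \(n = 6\), giving
  N = 36 cells of 2.5 dva on a 15-degree image, matched to the typical
  median saccade amplitude; 5, 8 or 10 are selectable).  From the occupancy
  distribution \(v\) and the row-normalized transition matrix \(M\) of
  consecutive within-trial fixation pairs,
  \(\mathrm{GTE} = -\sum_i v_i \sum_j M_{ij}\log_2 M_{ij}\), divided by the
  maximum \(\log_2 N\).  Cells on a partition boundary belong to the
  higher-index AOI (half-open cells); empty AOIs contribute nothing
  (\(v_i = 0\)) and their undefined rows are stored as zeros.  Empirical
  occupancy is used for \(v\) rather than the stationary distribution of
  \(M\), since scanpaths are short and \(M\) may be reducible.
* **Center bias.**  The mean distance of fixations to the image center,
  normalized as \(100\,(1 - \bar d / E[d \mid \mathrm{uniform}])\): 0 for a
  uniform fixation distribution, 100 when every fixation is exactly at the
  center.  The uniform baseline has a closed form for rectangles.  The
  normalization is linear because that is the unique affine form matching
  both anchors; peripherally concentrated samples yield negative scores,
  which are reported, not clamped.  A bootstrap over fixations (1000
  resamples) supplies the standard error.

Aggregation is strictly hierarchical: the image value is the unweighted
mean over its observers, the category value the unweighted mean over its
images.  The geometric center used by center bias (and by object centrality
below) is the continuous point \((W/2, H/2)\); with continuous polygon
geometry this makes the full-image annotation exactly central, so the
boundary anchors of both scores hold exactly rather than to within half a
pixel.

## Image statistics

Nine statistics per image (plus the luminance covariate):

* **Gabor energy, low and high spatial frequency.**  A quadrature bank of
  12 orientations (0-165 degrees in 15-degree steps; energy filters make
  orientations 180 degrees apart redundant, and a full-circle variant is
  available by configuration) times 8 frequencies log-spaced from 0.35 to
  8.56 cycles/dva yields a 96-dimensional energy vector.  Filters are
  built in the frequency domain as single-lobe Gaussian transfer functions
  with the DC term forced to zero, so energies ignore constant offsets;
  the complex modulus of the filtered image is the quadrature energy.
  Energies are pooled under population-receptive-field (pRF) Gaussian
  windows and averaged across the pRF grid; because the average is taken
  immediately, the default grid is a single uniform full-image window, with
  an explicit grid available for users who want localized pooling.  The
  low-SF statistic averages the four lowest frequency bands over all
  orientations; high-SF the four highest.
* **GLCM homogeneity.**  The image is quantized to 64 gray levels (linear
  mapping of its own min-max range), co-occurrences are tabulated at offset
  distance 1 (horizontal by default; the four-direction average is
  available and is exactly rotation invariant), and homogeneity is
  \(\sum_{ij} P(i,j)/(1+|i-j|)\).  The default "windowed" mode evaluates
  homogeneity in every sliding 3 x 3 window and averages — computed exactly
  by a box filter over per-pair similarity weights — with a whole-image
  "global" mode for sensitivity analysis.  Constant images score exactly 1.
* **Luminance** is the pixel mean of CIE L\*a\*b\* lightness under the
  standard sRGB conversion (D65), used only as a covariate.
* **Critical-object saliency (COS).**  Scene-diagnostic objects are
  annotated as polygons or rectangles.  Each object contributes
  \(\mathrm{Size}^{0.7}\times\mathrm{Location}\), where Size is the
  fraction of image area enclosed (the 0.7 exponent is Stevens' power-law
  compression of apparent size) and Location falls linearly from 1 at the
  image center to 0 at the corners.  Area and centroid come from the
  shoelace formula on vertex coordinates — deterministic and
  resolution-independent; a rasterized pixel-counting oracle backs it in
  the tests.  The Stevens transform applies to Size only.  An image without
  annotations scores 0; only a full-image object scores 1.
* **Within/across-category similarity (WS/AS).**  Per-image embedding
  vectors (any external representation; the package ships an adapter and a
  synthetic generator, deliberately not a trained network) are compared by
  Pearson correlation with all other images of the same/different
  category, optionally restricted to correctly classified images.
* **PCA-space L2 norms** for up to three embedding layers: a
  mean-centered, unscaled principal-component rotation retaining all
  components, then the Euclidean norm of each score vector.  With this
  centering the norm equals the centered vector's norm exactly, which the
  tests exploit as an invariance.

## Regression and power

Luminance is regressed out of each eye-movement variable by ordinary least
squares before model selection; only the responses are residualized.
Selection is a greedy bidirectional stepwise search minimizing AIC
(penalty 2), starting from the full nine-predictor model.  Ties are broken
toward the smaller model, then alphabetically, making the result
deterministic and invariant to predictor order; exactly collinear columns
are dropped up front.  Category-level fits (12 observations) are supported
but carry an explicit small-sample warning.  Variance inflation factors
\(1/(1-R^2_j)\) diagnose collinearity.

The power utility evaluates the repeated-measures within-factor F test
with noncentrality \(\lambda = f^2 m n/(1-\rho)\), \(df_1 = m-1\),
\(df_2 = (n-1)(m-1)\), no sphericity correction, and \(\rho = 0.5\) by
default — the conventions of the standard power tools.  Under the design
defaults (12 levels, f = 0.25, alpha = 0.05) the smallest sample reaching
0.80 power is 13 subjects, and 20 subjects give over 0.95.

## Rotation invariance

Images are rotated counterclockwise in 90-degree steps by pure index
permutation — never resampling — and annotation vertices by the matching
exact coordinate transform, so no interpolation noise enters; oblique
angles are out of scope because they would require padding.  All statistics
are recomputed per orientation and compared by per-category one-way ANOVA
with orientation as the factor.  All images enter this analysis regardless
of classifier correctness.  Statistics defined purely on geometry (COS)
must be *bit-identical* across orientations: COS evaluates the shoelace
formula in center-origin coordinates, where a quarter turn permutes and
negates the accumulated terms without re-rounding, so identical group means
are guaranteed for vertices on a dyadic grid (integer or quarter-pixel
coordinates, as annotation tools produce).  The ANOVA flags such
statistics `invariant_exact` (between-group variance exactly zero) instead
of reporting a meaningless F.

## The synthetic generator

`synth_config()` encodes the study conditions: 12 categories x 20 images x
20 observers, 3000 ms viewing, 600 px / 40 px-per-dva geometry, lognormal
fixation durations with mean 296 ms and SD 139 ms (converted analytically
to location/scale), a central-Gaussian fixation component, attraction
kernels over planted critical objects, and a uniform exploration
component.  The incorrect-trial (2.12%) and too-few-fixations (2.71%)
rates are the protocol's reported exclusion percentages; the remaining
invalid-event rates (trackloss 0.5%, short fixations 2%, out-of-image
fixations 1%, early saccades 1%, blinks 2%) are not reported anywhere and
were chosen once as realistic laboratory rates.  Backgrounds are
Gaussian-smoothed noise whose smoothing scale orders the categories by
GLCM homogeneity; planted objects are rectangles on a quarter-pixel grid
with closed-form COS.  Two effects are planted deliberately: the expected
fixation count falls log-linearly with COS, and the spatial spread of the
central component shrinks with the homogeneity rank, depressing FDM
entropy — giving the regression stage a known truth at image-level
signal-to-noise (model R-squared near 0.4).

Simplifications, stated plainly: fixation locations are i.i.d. given the
spatial mixture (no saccade-length dynamics or inhibition of return);
trial assembly may clip the last fixation at stimulus offset, so the
distributional guarantee (Kolmogorov-Smirnov agreement with the configured
lognormal) applies to the duration sampler, not to the clipped tail; and
images are textured noise, not photographs.  Consequently, passing tests
demonstrate the correctness of the computations and the recoverability of
planted structure, not photorealism.

For screening-exactness fixtures the generator offers `duration_band`:
valid durations are truncated to [110, 300] ms and first fixations forced
to at least 200 ms, so the data-dependent 2-SD cutoff (which lands near
313 ms on this band, comfortably above it) and the 75-ms anticipation rule
cannot remove unflagged events.  Every planted violation carries a flag
column, making screening precision and recall exactly 1.0 by construction
when the implementation is correct — and the tests require exactly that.

## Problem sizes in the test suite

Unit and property tests run the full design logic at reduced size (3-4
categories, 3-5 images each, 4-12 observers, 64-120 px images), which
exercises every code path in seconds.  Stepwise-recovery checks run 100
replicates at the full image-level size (n = 240); the rotation-ANOVA
type-I calibration uses 1000 null replicates.  These sizes were chosen so
the whole suite completes in well under a minute while keeping every
statistical check at its intended scale.

## Known limitations

* Event detection is upstream: the package consumes fixation/saccade event
  tables and does not parse vendor binaries or detect events from raw gaze
  samples.
* Deep-network features are a pluggable input; the package neither trains
  nor ships a classifier, so embedding-based statistics on real images
  require an external feature extractor.
* Category-level regressions with 12 observations are intrinsically
  underpowered; the package runs them but says so.
* The center-bias baseline assumes fixations distributed over the full
  image rectangle; stimuli with masked borders would need a different
  baseline.
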