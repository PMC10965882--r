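# scenegaze

Analysis toolkit for eye-tracking studies of **aerial scene
categorization**: how observers deploy gaze when they classify overhead
imagery, and which image properties — texture, luminance, salient
"critical" objects, category structure — drive that behavior.

The package covers the full analysis chain for a free-viewing
categorization experiment (observers view each scene for a few seconds and
report its category while gaze is recorded):

1. **Screening** of fixation/saccade event tables: incorrect trials, trials
   with fewer than three valid fixations, trackloss gaps over 100 ms
   (blinks excused), participants with over 25% trackloss or exclusions;
   then fixation filters (outside image, < 100 ms, > grand mean + 2 SD of
   duration) and saccade filters (onset < 75 ms, endpoint outside image).
2. **Gaze metrics** per observer and image: mean fixation duration,
   fixation count, fixation-density-map entropy
   (−Σ p log₂ p over the Gaussian-smoothed fixation map, 0.5° FWHM kernel),
   mean saccade amplitude, normalized gaze transition entropy over a 6 × 6
   area-of-interest grid (GTE = −Σᵢ vᵢ Σⱼ Mᵢⱼ log₂ Mᵢⱼ / log₂ N), and a
   center-bias score (0 = uniform viewing, 100 = all fixations at center),
   aggregated observer → image → category.
3. **Image statistics**: Gabor-bank energies (12 orientations × 8 spatial
   frequencies, 0.35–8.56 cycles/°, low- and high-frequency averages),
   GLCM homogeneity (Σ P(i,j)/(1+|i−j|), 64 gray levels, sliding 3 × 3
   window), CIELAB luminance, critical-object saliency
   (COS = Σ_c Size_c^0.7 × Location_c over annotated objects), and
   embedding-based statistics (within/across-category Pearson similarity,
   PCA-space L2 norms) from pluggable per-image feature vectors.
4. **Regression**: luminance residualized out of each eye-movement
   variable, then bidirectional stepwise AIC selection over the nine image
   statistics, at image and category level, with VIF diagnostics and a
   repeated-measures power utility (noncentral F,
   λ = f²·m·n/(1−ρ)).
5. **Rotation invariance**: all statistics recomputed at 0°/90°/180°/270°
   by exact index permutation, compared per category by one-way ANOVA.

A fully seeded synthetic generator (`synth_config()`, `gen_dataset()`)
emulates the design — 12 categories × 20 images × 20 observers, 3-s trials,
lognormal fixation durations (M = 296 ms, SD = 139 ms), central fixation
bias, object attraction, and configurable planted violations of every
screening rule — so each stage is testable against ground truth.

## Worked example

```r
library(scenegaze)

cfg    <- synth_config(n_categories = 4, images_per_category = 5,
                       observers = 10, image_size_px = 120, seed = 42)
bundle <- gen_dataset(cfg)
scr    <- screen_gaze(bundle$gaze, screening_config(image_size_px = 120))
print(scr$report$trials)
#> Screening stage 'trials': 200 in, 187 retained
#>   incorrect                   7  (3.50%)
#>   too_few_fixations           6  (3.00%)
#>   trackloss_gap               0  (0.00%)
#>   participant_excluded        0  (0.00%)
```

Thirteen of 200 synthetic trials violated a planted screening rule; the
per-rule counts match the generator's flags exactly.  Gaze metrics are
aggregated to the image level:

```r
m   <- summarize_gaze(scr$data, image_size_px = 120, px_per_deg = 8)
img <- aggregate_gaze(m, "image",
                      setNames(bundle$meta$category, bundle$meta$image_id))
head(img[c("image_id", "n_fixations", "fdm_entropy_bits",
           "gte_normalized", "center_bias")], 4)
#>      image_id n_fixations fdm_entropy_bits gte_normalized center_bias
#> 1 cat01_img01        5.44             7.91         0.0184       17.00
#> 2 cat01_img02        6.11             8.08         0.0375       16.04
#> 3 cat01_img03        6.30             8.08         0.0214        7.99
#> 4 cat01_img04        5.50             7.93         0.0184        8.80
```

Low normalized GTE (~0.02–0.04) means scanpaths are far from random;
positive center bias reflects the central fixation tendency.  The
regression stage recovers planted structure — here, negative effects of
critical-object saliency and homogeneity on the number of fixations —
after controlling luminance:

```r
tab <- gen_regression_table(240, seed = 42)   # image-level analysis table
ry  <- residualize_luminance(tab$n_fixations, tab$luminance)
stepwise_aic(ry, tab[1:9])
#> Stepwise AIC fit: 2 predictor(s) [cos, homogeneity], adj R^2 = 0.300
#>          term estimate std_error       t         p
#> 1 (Intercept) -0.01005   0.06904 -0.1455 8.844e-01
#> 2 homogeneity -0.49118   0.07279 -6.7476 1.143e-10
#> 3         cos -0.39954   0.07071 -5.6501 4.582e-08
```

Both planted predictors are selected with their planted (negative) signs;
the seven noise statistics are rejected.  Design planning uses the power
utility:

```r
required_n(f = 0.25, m = 12, alpha = 0.05, target_power = 0.8, rho = 0.5)
#> [1] 13
```

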