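# veinrlf

Finger-vein recognition from near-infrared images: mean-curvature valley
detection, Radon-like feature (RLF) aggregation, binary template matching,
and FAR/FRR/EER verification — with a seeded synthetic vein-image generator
for fully reproducible experiments.

## What it does

NIR transmission images show finger veins as dark, smooth, curvilinear
valleys on a brighter finger region, in images that are low-contrast,
blurred and noisy. `veinrlf` extracts a binary vein pattern in four stages:

1. **Valley response.** The mean curvature of the intensity surface,
   computed as half the negated divergence of the regularized unit gradient
   field,

   κ̄ = −½ ∇·( ∇I / (|∇I| + ε) ),

   is negative in valleys; the response is its negative part max(−κ̄, 0) —
   invariant to intensity offsets and contrast scaling.

2. **Radon-like features.** A Canny edge map of the response defines
   "knots" where eight families of digital scan lines (0°–315° in 45° steps,
   each family tiling the image exactly once) cross an edge. Every pixel of
   a knot-to-knot segment receives the mean response over that segment, and
   the per-direction rasters are averaged into the mean RLF image — a
   smoother, better-connected vein map.

3. **Binarization.** Min-max normalization followed by Otsu's 256-bin
   threshold yields the 0/1 vein pattern. (Binarizing the valley response
   directly, skipping stage 2, gives the mean-curvature baseline used for
   comparison.)

4. **Matching and evaluation.** A template cut with margins (cw, ch) from
   the registered pattern slides over the probe; the match ratio
   Rm = Ncommon / (Ntemplate + Ninput) ∈ [0, 0.5] is maximized over offsets
   (0.5 = exact match). A first-image-as-template genuine/impostor protocol,
   a 5001-point threshold sweep over [0, 0.5], and the equal error rate
   (FAR = FRR operating point) summarize verification quality.

Because the standard finger-vein databases are registration-gated, the
package includes a deterministic generator of class-labelled synthetic NIR
datasets (vein skeletons, Gaussian cross-profiles, illumination gradients,
blur, noise, intra-class shift/rotation) with ground-truth masks.

## Worked example

```r
library(veinrlf)

# a small synthetic dataset: 4 finger classes, 3 images each
ds   <- dataset_spec(n_classes = 4, m_images = 3, seed = 42)
data <- generate_dataset(ds)

# extract the binary vein pattern of one image
feats <- extract_features(data$class_001$img_01$image, fv_config())
attr(feats$pattern, "vein_count")
#> [1] 3557

# genuine match: another capture of the same finger
probe <- extract_features(data$class_001$img_02$image, fv_config())$pattern
match_ratio(feats$pattern, probe, match_config())
#> Match ratio 0.3084 at offset (dy = 22, dx = 25); common 811, template 1351, input 1279

# impostor match: a different finger
imp <- extract_features(data$class_002$img_01$image, fv_config())$pattern
match_ratio(feats$pattern, imp, match_config())
#> Match ratio 0.1550 at offset (dy = 43, dx = 26); common 362, template 1351, input 985

# full verification experiment
ver <- run_verification(data, fv_config())
ver
#> Verification result: EER 13.194% at threshold 0.1772 (8 genuine, 36 impostor attempts)
glance(ver)
#> # A tibble: 1 × 4
#>     eer threshold n_genuine n_impostor
#>   <dbl>     <dbl>     <int>      <int>
#> 1  13.2     0.177         8         36
autoplot(ver)   # FAR/FRR curves with the EER point marked
```

The genuine attempt scores 0.31 (the maximum is 0.5) while the impostor
scores 0.15; the margin-cropped search has recovered the intra-class shift
(the best offset sits near the centred position (30, 30) for the genuine
pair). The tiny 4×3 experiment above has only 8 genuine attempts, so its
EER is coarse; at the default scale (20 classes × 6 images) the RLF
pipeline reaches an EER of about 3%, against about 4% for the
mean-curvature baseline.

A command-line interface with `simulate`, `extract`, `match` and `eval`
subcommands is installed at `system.file("cli", "veinrlf.R", package =
"veinrlf")`; see the methods vignette (`vignettes/vein-rlf-methods.Rmd`)
for the model, parameter meanings and numerical conventions.

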