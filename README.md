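# pepperview

Viewpoint analysis for colour-based maturity classification of sweet peppers
(*Capsicum annuum*).

Sweet peppers ripen nonuniformly — a contiguous region of the surface turns
from green to red or yellow — so the maturity a camera sees depends on which
side of the fruit it faces. For a harvesting robot this matters twice: the
side that happens to face the camera cannot be chosen, and extra viewpoints
cost cycle time. `pepperview` is for researchers in agricultural robotics
and machine vision who want to quantify that dependence: how accurate is
maturity classification from one viewpoint, from combinations of viewpoints,
and in the best and worst case over viewpoints?

## What it computes

Fruit are graded on an ordinal 1–4 scale from the colored surface fraction
*f* (1 = fully green, 2 = majority green, 3 = majority colored, 4 = fully
colored); single viewpoints are graded with >95% / >50% rules on the visible
fraction. The analysis chain is:

* **Synthetic data** — ellipsoidal fruit with a spherical-cap ripening front
  of exact surface fraction *f*, rendered from three side viewpoints
  (± a bottom viewpoint) as 8-bit RGB, optionally with aligned 16-bit depth,
  foliage clutter and sensor dropout; ground-truth masks and visible
  fractions are analytic, and everything is seed-deterministic.
* **Segmentation** — dark-background photocell images: intensity threshold +
  Chan–Vese active contours; cluttered RGB-D scenes: hue rotation (+90° so
  red–green is contiguous), nearest-neighbour depth fill, a colour+depth
  foreground window with 3×3 opening/closing, Canny edges dilated ×10 and
  eroded ×5, ripe-colour add-back, size filtering, lowest-mean-hue object
  selection, convex hull.
* **Features** — 18 statistics (mean, sd, min, max, median, 5% trimmed mean
  of hue, R, and R−G) over the segmented pixels, with multi-view fusion by
  *pixel pooling*: the pixels of a viewpoint combination are concatenated
  before the statistics are computed.
* **Classification** — one random forest (500 trees, 5 features per split)
  per pepper colour, trained on all-viewpoints features of training fruit,
  with whole peppers held out per (class, colour) stratum.
* **Scenario analysis** — classification accuracy (CA) per viewpoint
  combination; optimistic / pessimistic bounds (a pepper is correct if any /
  only if every considered combination classified it correctly); viewpoint
  classification accuracy (VCA) against per-view ground truth; Cohen and
  Light kappa agreement between viewpoints, excluding fully green / fully
  colored fruit, which agree by definition.

## Worked example

```r
library(pepperview)

# a red pepper, 60% colored, ripening front facing the side1 camera
pep <- generate_pepper(pepper_spec("demo", "red", colored_fraction = 0.6,
                                   front_orientation = c(1, 0, 0), seed = 42))
views <- render_viewpoints(pep, "photocell")
round(vapply(views, `[[`, numeric(1), "visible_colored_fraction"), 2)
#>  side1  side2  side3 bottom
#>   1.00   0.37   0.37   0.63
classify_viewpoint(vapply(views, `[[`, numeric(1), "visible_colored_fraction"))
#> [1] 4 2 2 3
```

The same class-3 fruit looks fully ripe from `side1` (the front faces that
camera), majority-green from the other sides, and — the informative one —
63% colored from below: the bottom view samples all azimuths, so its visible
fraction tracks the true *f* = 0.6. Segmentation and pooled features:

```r
mask <- segment_photocell(views$side1$rgb)
mask_iou(mask$mask, views$side1$truth_mask)
#> [1] 0.991
samples <- lapply(views, function(v) collect_pixels(v$rgb, v$truth_mask))
round(pool_and_extract(samples)[c("hue_mean", "hue_median", "red_mean",
                                  "red_minus_green_mean")], 1)
#>             hue_mean           hue_median             red_mean
#>                 52.3                  7.8                133.8
#> red_minus_green_mean
#>                 30.0
```

Scenario bounds on a correctness matrix (4 peppers × 3 viewpoints; each cell
says whether that viewpoint classified that pepper correctly):

```r
m <- rbind(pepper1 = c(TRUE, TRUE,  TRUE),
           pepper2 = c(TRUE, FALSE, TRUE),
           pepper3 = c(FALSE, TRUE, FALSE),
           pepper4 = c(FALSE, FALSE, FALSE))
colnames(m) <- c("VP1", "VP2", "VP3")
scenario_bounds(m)
#> per-combination CA: 0.50 0.50 0.50; optimistic 0.75; pessimistic 0.25
```

Every single viewpoint scores 50%, but if the most favourable viewpoint
always faced the camera 75% of peppers would be graded correctly, and only
25% if the least favourable one did — the spread a robot lives in.

A full simulation study (generate → segment → features → train → predict →
analyze) is one call:

```r
rep <- run_pipeline(run_config("photocell", n_per_class_per_color = 10))
rep$overall_all_viewpoints_ca
rep$colors$red$per_combination_ca
```

A thin CLI with verbs `simulate / segment / features / train / predict /
analyze / run / adapter` ships in `inst/cli/pepperview`; `adapter`
normalises a locally downloaded real-image dataset into the package's
manifest format.

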