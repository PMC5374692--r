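---
title: "Measuring maize tassel morphology from booth photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring maize tassel morphology from booth photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tasselmorph)
```

## The measurement problem

The maize tassel — the male inflorescence atop the plant — is fragile and
deforms within hours of removal, so shape traits must be captured in the
field, quickly, and from a single profile photograph if throughput is to
reach population scale. `tasselmorph` measures a tassel from a pair of
photographs taken in a light booth: one of the empty booth (the
*background* image) and one with the tassel mounted upright at the booth
centre (the *sample* image). From that pair it derives tassel length,
branch number, area, tortuosity, compactness, box-counting fractal
dimension, skeleton length, and perimeter, and it computes the downstream
statistics used to judge a phenotyping platform: trait repeatability from
variance components, correlations of genotype means, and the coefficient
of variation of the root mean squared error against hand measurements.

## The pipeline, stage by stage

**Segmentation and quality control.** The two RGB images are collapsed to
8-bit grayscale with the standard luminance weights (0.299, 0.587, 0.114)
and subtracted pixel-wise; the absolute difference makes the operation
symmetric and indifferent to whether the tassel is darker or lighter than
the booth. The difference image is thresholded at the level that
maximizes between-class variance over the 256-bin histogram (Otsu's
criterion, computed exhaustively; ties resolve to the lower threshold).
Three gates reject images that cannot be measured: a chosen threshold
below `min_threshold` (default 10 of 255) indicates no tassel or too
little contrast; an empty mask after filtering; and any foreground pixel
on the image border, which means the tassel extends out of frame. Only
the largest 8-connected component is kept, which removes debris,
reflections and dirt.

**Skeleton and main path.** The mask is convolved with a truncated,
renormalized isometric Gaussian (31 x 31 pixels, sigma 55 — with this
support the kernel is nearly uniform, so it acts like a majority filter)
and re-thresholded at 0.5. This erases protrusions narrower than about
half the support (spikelets, rough edges) so that thinning produces a
skeleton without spurious spurs. The smoothed mask is thinned to a
one-pixel-wide skeleton by Zhang-Suen passes followed by sequential
removal of remaining simple pixels (Yokoi connectivity number 1), which
eliminates the staircase corners sub-iteration thinning leaves behind.
Skeleton pixels form a graph (8-adjacency, step weights 1 and sqrt(2));
the endpoint closest to the bottom-centre of the frame is the base, and
geodesic distances from it to all endpoints are computed with Dijkstra's
algorithm. Endpoints closer than 75 px along the skeleton to a branch
point are excluded from tip candidacy; the farthest surviving endpoint is
the spike tip, and the shortest path to it is the main path.

**Lowest branch and tassel length.** Tassel length is conventionally
measured from the lowest branch point to the spike tip, so the lowest
branch must be located on the main path. Single-row sums of the
*unsmoothed* mask within a 301-px window centred on the path give a width
profile: narrow along the bare stem, wide in the branching zone. The
profile is smoothed with a width-41, sigma-5 Gaussian and scanned from
the base; the first position where its derivative with respect to path
position exceeds 0.2 marks the lowest branch. (Scanning base-to-tip with
a positive threshold is the only orientation for which the *first*
crossing is the *lowest* branch.) Cubic smoothing splines of row and
column versus arc length are fitted from the lowest branch to the tip;
tassel length is the line integral of the spline, evaluated by dense
sampling (10 samples per path pixel; refinement converges well below
0.1%). Tortuosity is the Euclidean distance between the spline's
endpoints divided by the tassel length — using the spline's own
endpoints guarantees chord <= arc, hence a value in (0, 1].

**Branch number.** Circles of radius 100, 150, 200, ... px centred on the
lowest branch are intersected with the binary mask; each circle's
rasterized pixels are traversed in angular order and maximal foreground
runs counted (with wrap-around merging). Radii extend while the circle
still meets the object; the maximum count is the branch number. The
circles cross the stem below and the spike above the lowest branch, so
the count intrinsically includes those two crossings; no correction is
subtracted, matching the published behaviour of the method (its
image-based counts have a floor near 2 where hand counts reach 0).
Single-pixel gaps along the circle are closed before counting: a 1-px
notch in a noisy binarized limb edge is below the rasterization noise
floor, whereas genuine gaps between limbs span many circle pixels at
these radii.

**Size and shape.** Area is the foreground pixel count. Compactness is
area divided by the convex-hull area of the foreground pixel centres
(shoelace formula). Fractal dimension uses box counting: occupied-box
counts over power-of-two box sizes from 2 up to a quarter of the smaller
image dimension, grid anchored at the mask's bounding box, and the slope
of log N(s) against log(1/s) by unweighted least squares. Skeleton
length is the skeleton pixel count; perimeter is the count of foreground
pixels with at least one non-foreground 8-neighbour (the frame counts as
background). A scale factor (mm per pixel, from the tassel-holder base)
converts pixel measures to mm when supplied.

**Statistics.** For a replicated field design, each trait is fitted with
the linear mixed model y = u + G + B + e (genotype G random, replication
B fixed) by REML, and repeatability is sigma_G^2 / (sigma_G^2 +
sigma_e^2 / b) with b the number of field replications. Correlations
between traits use Pearson's r on genotype means across replications.
CV(RMSE) regresses hand-measured on image-based genotype means and
divides the residual RMSE (n - 2 denominator) by the mean hand value, so
it is invariant to affine recalibration of the image measurements.

## Tunable parameters

All knobs live in one `tassel_params()` object whose hash is recorded in
every output row. Defaults follow the published protocol where it states
a value:

| parameter | default | units | role |
|---|---|---|---|
| `min_threshold` | 10 | intensity | low-contrast rejection gate |
| `smooth_kernel_size` / `sigma` | 31 / 55 | px | mask smoothing before thinning |
| `rethreshold_level` | 0.5 | — | re-binarization of smoothed mask |
| `spur_min_dist` | 75 | px | spur exclusion from tip candidacy |
| `profile_window` | 301 | px | row-sum window around main path |
| `profile_kernel_width` / `sigma` | 41 / 5 | px | width-profile smoothing |
| `deriv_threshold` | 0.2 | px/px | lowest-branch detector |
| `circle_r0` / `circle_dr` | 100 / 50 | px | branch-count circle radii |
| `spline_df_per_px`, `spline_min_df` | 0.01, 5 | — | spline stiffness |
| `scale_mm_per_px` | NA | mm/px | unit conversion |

The spline degrees of freedom are `max(spline_min_df, spline_df_per_px *
arc_length, 4 + net_turn / 15)` where `net_turn` is the path's net
heading change in degrees, measured on a 40-px-decimated copy. The third
term matters: a purely length-based rule cannot be simultaneously stiff
enough to suppress the local skeleton wobble that branch junctions
induce (which would inflate the arc and depress tortuosity) and flexible
enough to follow a strongly curved axis. Net heading change separates
the two cases — wobble cancels, genuine curvature accumulates. With this
rule a straight-spec tassel measures tortuosity 0.9995–1.0000 while a
semicircular test path recovers arc length within 0.1% and tortuosity
within 0.006 of 2/pi. The residual RMS on +-1 px jittered straight lines
is about 0.3 px.

## The synthetic-tassel generator

Real validation data for this instrument (thousands of field images plus
hand measurements) is not distributable, so the package ships a seeded
generator (`synthetic_spec()` / `generate_tassel()`) whose every output
quantity is known exactly from its parameters. It emulates the booth:
a bright background (default 215/255) with a planar illumination
gradient and Gaussian intensity noise (sd 2, independent between the
background and sample exposures), and a dark tassel (default 40/255)
composited with softened, anti-aliased edges. The tassel's main axis is
an arc-length-parameterized circular arc entering at the bottom centre —
a stem (424 px), a branching zone (220 px) and an unbranched spike
(450 px) — with straight branches on alternating sides, lower branches
longer (about 420 px) and more horizontal (65 degrees from vertical)
than upper ones (about 300 px, 30 degrees), widths 24/20/18 px for
stem/spike/branches. Optional spikelet bumps stress spur pruning, and
optional bright-floor debris blobs (sample image only) exercise the
largest-component filter. Ground truth — arc length from the lowest
branch to the tip, its chord (hence tortuosity), branch count, lowest
branch pixel, rendered area, expected circle count k + 2 — comes from
the generating geometry, never from the rendered images.

Sizing choices worth knowing. Limb widths exceed half the smoothing
support (15.5 px) so limbs survive the 0.5 re-threshold; real tassel
limbs at the original imaging resolution are comfortably wider. Default
branch lengths are nudged by up to 25 px so each limb's rounded end-cap
lies midway between two counting radii, and the stem length (424 px)
does the same for the stem's bottom cap after accounting for the ~11 px
base-ward bias of the detected lowest branch: an end-cap lying almost
exactly on a counting circle is clipped tangentially by rasterization
and can fragment into two runs, which would make the k + 2 circle-count
ground truth ambiguous rather than exact. This is the radial analogue of
keeping branches angularly separated.

What the generator does *not* emulate: out-of-plane curvature and
occlusion (branches crossing in projection), anther and pollen texture,
specular reflections, holder hardware in frame, and lens distortion.
Passing its suites therefore demonstrates correctness of the geometry
and of the measurement chain, not robustness to every pathology of field
images; on real data, occlusion is the dominant known error source for
branch counting, and tilt out of the focal plane biases length low.

## Numerical and degenerate-case decisions

* Otsu ties resolve to the lower threshold; a degenerate (single-bin)
  histogram has no valid split and is rejected.
* Component ties (equal pixel counts) resolve to the component whose
  topmost-leftmost pixel is lexicographically smallest.
* Geodesic tie between candidate tips resolves to the smaller row, then
  column; base anchoring ties likewise (column, then row).
* The 75-px spur rule uses *path* distance to the nearest junction
  pixel and only removes endpoints from tip candidacy; the skeleton is
  never edited.
* The derivative in branch detection is a central difference of the
  smoothed profile with respect to cumulative arc length; the profile's
  Gaussian smoother renormalizes its truncated kernel at the edges.
* Fewer than four path pixels fall back to a straight segment instead
  of a spline; a branchless (smooth) spike raises "no branch detected"
  and the pair is reported as `REJECT_NO_BRANCH`.
* Box counting requires at least three usable box sizes; smaller images
  are an error rather than a silent two-point fit.
* Negative variance components cannot occur (REML boundary constraint);
  repeatability with both components zero is an error, not NaN.

## Validation suites and problem sizes

The test and acceptance suites regenerate everything from seeds at the
generator's default image size (1500 x 1000): a 50-image suite spanning
branch counts 0–12, three curvatures and two noise levels for geometry
recovery (median tassel-length error well under 1%, straight-spec
tortuosity within 0.01 of 1); a 60-image sweep (k = 1..12, five seeds
each) for exact k + 2 branch counting; analytic oracles (semicircle
tortuosity 2/pi, fractal dimensions of a line, a filled square and a
depth-7 Sierpinski gasket, the 36-px perimeter of a 10 x 10 square);
exact-agreement checks of Dijkstra distances against brute-force
uniform-cost search on 100 random pixel graphs and of the Otsu threshold
against exhaustive search on 200 random histograms; a 500-genotype x
2-replication simulation recovering repeatability 0.75 with REML matching
the ANOVA method-of-moments estimator on balanced data; and batch-level
checks that every input pair yields a row, that frame-clipped and
low-contrast pairs are rejected with the right reason codes, and that
reruns are byte-identical. `scripts/acceptance.R` recomputes all of these
from scratch against the installed package.

## Known limitations

* Branch counting from a single 2-D view cannot resolve occluded
  branches; counts saturate well below true branch numbers on dense
  tassels (the original instrument topped out near 15 of 28
  human-countable branches).
* Spike length (tip to *uppermost* branch) is not measured: the highest
  branch point cannot be located reliably in projection. Tassel length
  is its recommended predictor.
* The lowest-branch detector has a systematic base-ward bias of roughly
  10–15 px (about 2 sigma of its profile smoother); at booth resolution
  this is ~2–3 mm, small against tassel lengths of 200–500 mm, and it
  partially cancels the tip-ward shortening that mask smoothing induces.
* The bare-spike fractal dimension is not comparable to branched values:
  a strip-shaped mask keeps all box sizes in the locally two-dimensional
  regime.
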