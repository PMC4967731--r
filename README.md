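# falm — flicker-assisted localization microscopy in R

Mitochondria in fully differentiated cells are small, densely packed and
optically cluttered: in a time-averaged fluorescence image, neighbouring
organelles merge into blobs and individual boundaries cannot be drawn.
`falm` segments **individual** mitochondria from time-lapse recordings of
a membrane-potential-sensitive dye (such as TMRE) by exploiting
stochastic transient depolarizations of the mitochondrial membrane
potential — *flickers*. All pixels of one electrically contiguous
organelle dim and recover together, while overlapping neighbours flicker
on independent schedules, so temporal covariance separates what optics
cannot.

The package is aimed at cell biologists quantifying mitochondrial
architecture and dynamics in native cells: it provides the covariance
segmentation pipeline, minimum-bounding-ellipse morphometry with
population statistics, organelle tracking with drift correction and
motility classification, signed distance fields from a traced cell
edge, and a synthetic movie simulator with complete ground truth for
validation.

## The method in brief

For a stack `I(x, y, t)` with frame interval Δt and pixel size p:

1. `All_On(x, y, t)` — mean of the brightest 20% of `I(x, y, ·)` in a
   rolling ±60 s window (robust fully-polarized baseline).
2. `Delta = All_On − I` — instantaneous depolarization.
3. `dD/dt(t) = Delta(t + dt/2) − Delta(t − dt/2)` with `dt` = 4 s —
   de/repolarization rate.
4. For a seed pixel `(xs, ys)`:
   `COVMAP(x, y) = cov( dD/dt(x, y, ·), dD/dt(xs, ys, ·) )` over a
   40 × 40 px region, normalized by its maximum.
5. Pixels with normalized covariance ≥ +0.4, restricted by flood fill to
   the 8-connected component containing the seed, form the organelle
   mask.

Each mask's **minimum bounding ellipse** (smallest-area ellipse
containing all pixel-corner points, fitted by Khachiyan iteration)
yields length, width and the length:width ratio; areas come from pixel
counts (one 225 nm pixel = 0.051 µm²). Motility is classified from
drift-corrected centroid tracks (motile: excursion > 0.45 µm within
10 min), and organelle positions are related to the cell edge through an
exact signed Euclidean distance field.

## Worked example

Two parallel rod organelles 2 px apart are blurred into a single blob by
the PSF, but flicker independently; the covariance pipeline recovers
both:

```r
library(falm)

cfg   <- scene_preset("overlap_pair", rng_seed = 1)
truth <- build_scene(cfg)
movie <- render_stack(truth)
movie
#> <flstack> 48 x 40 px, 240 frames | 225 nm/px, 0.5 s/frame (120 s total)

seg <- segment_stack(movie, list(seed_point(20, 18), seed_point(20, 22)))
for (m in seg$masks) print(m)
#> <mito_mask> seed (20, 18), 28 px, status: ok
#> <mito_mask> seed (20, 22), 28 px, status: ok

recs <- lapply(seg$masks, shape_record, pixel_size_nm = 225)
for (r in recs)
  cat(sprintf("area %.3f um^2, length %.2f um, width %.2f um, ratio %.2f\n",
              r$area_um2, r$length_um, r$width_um, r$aspect_ratio))
#> area 1.417 um^2, length 1.93 um, width 1.26 um, ratio 1.53
#> area 1.417 um^2, length 1.93 um, width 1.26 um, ratio 1.53
```

Each true 8 × 2 px rod is recovered together with the blur skirt that
genuinely covaries with it (28 px); the two masks are distinct pixel
sets even though the time-averaged image is one blob. The ellipse gives
each rod a 1.93 µm length and 1.53 aspect ratio — neither "long"
(> 2 µm) nor "elongated" (ratio > 3).

A full analysis (segmentation → shapes → occupancy → motility) is
wrapped by `run_pipeline()`, and a thin command-line interface lives at
`inst/scripts/falm`:

```sh
Rscript inst/scripts/falm simulate --preset aged --seed 1 --out scene/
Rscript inst/scripts/falm segment --stack scene/movie.tif --auto-seeds \
        --frame-interval-s 0.5 --out seg/
Rscript inst/scripts/falm shapes --masks seg/masks.tif --out shapes/
```

See `vignettes/falm-methods.Rmd` for the model, every tunable parameter,
and the numerical design choices.

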