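---
title: "Flicker-assisted localization microscopy: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flicker-assisted localization microscopy: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(falm)
```

## The physical idea

Mitochondrial membrane potential is not constant: organelles undergo
stochastic transient depolarizations ("flickers"), for example during
transient openings of the permeability transition pore. A rapidly
repartitioning potentiometric dye such as TMRE reports these events as
organelle-wide dips in fluorescence. Because every pixel of one
electrically contiguous organelle sees the same membrane potential, the
pixels dim and recover *together*, while a neighbouring organelle — even
one whose image overlaps optically — flickers on its own schedule. The
temporal covariance of pixel intensities therefore carries information
that the time-averaged image does not: it demarcates electrically
discrete units. `falm` segments organelles by thresholding that
covariance around user- or automatically-chosen seed pixels.

## The segmentation pipeline

Given a calibrated stack `I(x, y, t)` the pipeline computes, in order:

1. **All_On** — a rolling estimate of the fully polarized fluorescence:
   for each pixel and frame, the arithmetic mean of the brightest 20% of
   that pixel's values inside a window of ±`window_s` (default 60 s),
   clamped at the ends of the recording. The count of averaged values is
   `ceiling(0.2 * window length)`, so even one-frame windows are
   defined. The window bounds are read as inclusive, which matches the
   requirement that a ten-frame window averages exactly its two
   brightest values. The rolling construction absorbs photobleaching and
   slow cell movement while ignoring the transient dips.
2. **Delta** = All_On − I, the instantaneous depolarization.
3. **dD/dt** — the two-point derivative `Delta(t + dt/2) − Delta(t −
   dt/2)` over `dt_s` (default 4 s). `dt` in frames must be even so that
   `dt/2` is an integer. Frames where the stencil would leave the
   recording are *excluded* from the covariance series rather than
   zero-padded: padding would inject spurious covariance between
   unrelated pixels.
4. **Covariance map** — for a seed pixel, the temporal covariance of
   every pixel's dD/dt series with the seed's series, over a region of
   40 × 40 pixels centred on the seed (`xs − 20 ≤ x < xs + 20`, clipped
   at image borders rather than reflected). The *population* covariance
   (division by the number of usable frames `m`) is used; the choice of
   denominator is irrelevant after normalization but is fixed so that an
   independent brute-force oracle can match it exactly.
5. **Normalization** — the map is divided by its maximum, discarding the
   inseparable mixture of flicker variance and brightness. The maximum
   of every normalized map is exactly 1; the lower bound is not −1 in
   general (the literal formula is kept). If the seed series has zero
   variance, or the raw maximum is not positive, the seed is reported as
   `no_flicker` rather than normalized through zero.
6. **Threshold and flood fill** — pixels with normalized covariance
   ≥ 0.4 form a binary mask, reduced to the single 8-connected component
   containing the seed. Distant above-threshold pixels (noise) are
   thereby excluded. A seed below its own threshold is a rejected seed
   (`seed_below_threshold`), distinct from an empty mask.

Per-seed failures never abort a multi-seed run, and masks from distinct
seeds are kept separately even when they overlap: electrically discrete
organelles may genuinely overlap in the image. Seeds can be supplied as
a CSV of 0-based `x,y` pixels or suggested automatically from local
maxima of the temporal maximum of |dD/dt| (default acceptance bar: a
quarter of the strongest peak; a deliberate bias towards strong, clean
flickers since a suggestion list is a starting point, not a census).

All user-facing coordinates — seed files, mask tables, track tables —
are 0-based `(x, y)` pixels; conversion to R's 1-based array indexing
happens only at array access.

### Default parameters

| parameter | default | units | origin |
|---|---|---|---|
| `pixel_size_nm` | 225 | nm | effective pixel size of the reference acquisition |
| `frame_interval_s` | 0.1 | s | 10 Hz acquisition |
| `window_s` | 60 | s | baseline half-window |
| `dt_s` | 4 | s | derivative stencil |
| `region_half` | 20 | px | 40 × 40 covariance region |
| `threshold` | +0.4 | — | normalized covariance cut |
| `mbe_tolerance` | 1e-4 | — | ellipse convergence |
| `motility_window_min` | 10 | min | motility observation window |
| `motility_threshold_um` | 0.45 | µm | motile excursion cut (2 px) |
| `sampling_interval_s` | 1 | s | tracking sample spacing |

All are overridable through `load_config()` (JSON/YAML) or function
arguments.

## Morphometry

The mask point set for ellipse fitting is the set of distinct **pixel
corners**, not centres — each pixel `(x, y)` contributes `(x, y)`,
`(x+1, y)`, `(x, y+1)`, `(x+1, y+1)` — so a one-pixel organelle has a
non-zero length (its minimum bounding ellipse is the circumcircle of
the unit square, diameter √2 ≈ 0.32 µm at 225 nm).

The **minimum bounding ellipse** (minimum-area enclosing ellipse, centre
and rotation free) is computed by Khachiyan's reweighting iteration with
Wolfe–Atwood "away" steps, which reach the default 1e-4 tolerance in
tens of iterations where the increase-only scheme needs tens of
thousands. Two numerical guards matter: the interior-optimal decrease
step only exists for leverage `M > 1`, otherwise the point is dropped
from the support; and if floating-point weight collapse ever makes the
support degenerate, the iteration restarts from uniform weights. After
convergence the quadratic form is rescaled so every input point
satisfies the ellipse inequality exactly — containment is unconditional
at the cost of at most a `1 + tolerance` area inflation. Degenerate
(collinear) point sets, which cannot arise from a non-empty pixel mask
but are guarded anyway, fall back to the minimal enclosing circle of
the farthest pair.

Shape records convert to physical units (`area_um2 = area_px ×
pixel²`), with two population flags: **long** (major axis > 2 µm) and
**elongated** (major:minor > 3). Population summaries report the
geometric mean area (uncertainty as the back-transformed SEM of
log-areas), the 95th percentile (type-7 quantile), the mean of the
largest `ceiling(0.05 n)` organelles, and the **modal area**. Since mask
areas are integer pixel counts, the mode is estimated on a histogram
whose bins are centred on integer multiples of the single-pixel area
(0.050625 µm² at 225 nm) and reported as the bin centre — equivalently,
the most frequent pixel count times the pixel area. Bins anchored at
zero would put every observed area on a bin edge and could not reproduce
a one-pixel mode of 0.051 µm² or a fourteen-pixel mode of 0.710 µm².

**Occupancy** is the union of all organelle masks, intersected with the
traced cell mask, divided by the cell area; organelle pixels outside the
cell are clipped with a warning rather than counted.

**Population comparisons** use a two-sample Kolmogorov–Smirnov test on
areas (the asymptotic form — pixel-quantized areas are heavily tied) and,
for each proportion (long, elongated), both a pooled two-proportion
z-test and an unpaired t-test on the 0/1 indicator vectors. The t-test
on proportions is unusual but is reported alongside the z-test because
the reference analysis states it used one; the two agree closely at
these sample sizes.

## Motility

**Drift.** Whole-cell movement is estimated per frame by phase
correlation against the first frame, with parabolic sub-pixel
refinement, and subtracted from all tracks; the correlation peak sits at
minus the scene displacement. Featureless frames yield zero drift with
a warning.

**Tracking.** Each organelle is followed by an intensity-weighted
centroid in a small window around its predicted position (previous
position plus the drift step). Three choices keep the tracker honest in
crowded fields:

- the window background is the window median, and weights below 30% of
  the peak are zeroed, so diffuse shot noise cannot drag the centroid;
- each step is clamped to `max_step_px` (default 1.5 px per sample):
  directed transport tops out near 100 nm/s, so larger jumps are
  localization failures, not movement;
- a **departure check**: two identical organelles crossing paths are
  ambiguous to any local tracker, but a static organelle's own starting
  pixel never goes dark. Each track records the intensity retention of
  its starting pixel (plus 4-neighbours, which absorb one-axis drift
  rounding without being fooled by an organelle parked diagonally
  adjacent), drift-compensated, relative to the first frame. An
  organelle whose home was never vacated (retention ≥ 0.5 throughout)
  is vetoed from the motile class regardless of what its tracking
  window did.

An organelle is **motile** if its drift-corrected excursion from the
start of any 10-min window exceeds `motility_threshold_um` (default
0.45 µm = 2 px; the manual counting this automates registered movements
down to roughly 0.5 µm) *and* it passed the departure check. Mean speed
is measured over a coarse lag (default 20 s) restricted to windows
moving at ≥ 60% of the track's peak rate, so pixel-quantization jitter
and the ramp-in/out edges of a burst do not dilute a burst's speed. In
densely packed fields a localization window of ±1 px (`window_half =
1`) is appropriate; the default ±2 px suits sparser preparations.

**Edge distance.** The signed distance from the traced cell edge is the
exact Euclidean distance transform, positive inside, negative outside,
with a half-pixel offset so that the zero level sits on the mask
boundary (an interior pixel adjacent to the edge is half a pixel from
it). This is the unit-speed Eikonal solution for this geometry; a
fast-marching solver would approximate the same field with first-order
error. Discretely, its gradient magnitude is 1 to within ±0.05 once the
probe point is ~10 px clear of the pixel-quantized boundary and of the
medial skeleton; closer in, facet error of order `0.5/r` is inherent to
any solver fed a binary mask. Each organelle's distance is interpolated
bilinearly at its *first observed centroid* (the reference position is a
choice; the alternative — nearest mask pixel — systematically shrinks
distances for long organelles). Motile and non-motile distances are
compared with a Welch t-test; an empty motile set is reported as a note,
not an error.

## The simulator

`scene_config()` / `build_scene()` / `render_stack()` generate
TMRE-like movies with complete ground truth (footprints, flicker
schedules, motion paths, cell mask, planted summary). The model:

- organelles are rods, discs or compact 14-px blobs on a placement grid
  inside a rectangular "cell";
- flickers are a per-organelle Poisson process (default 3 events/min)
  of organelle-wide dips of fractional depth 0.8, with a 5 s
  depolarized plateau and mono-exponential on/off kinetics (0.5 s / 1 s)
  — the reference recordings show flicker shape but do not parameterize
  it, and these constants keep events resolvable at the 4-s derivative
  stencil;
- motile organelles take one directed run along the cell axis (speed
  40–95 nm/s, distance 0.8–12 µm, direction chosen to stay inside the
  cell) on top of Brownian jitter (15 nm/√s);
- the camera model is baseline 400 counts per organelle pixel over a
  40-count background, exponential photobleaching (default 1%/min),
  optional whole-field drift (applied as rounded cumulative shifts),
  optional Gaussian PSF (σ 1 px ≈ 225 nm; off by default so footprints
  stay exact for oracle tests), Poisson shot noise and Gaussian read
  noise (σ 3), with frames rounded to integer counts so written movies
  round-trip bit-exactly.

Everything stochastic derives from `rng_seed`; identical configs give
bit-identical scenes.

Four presets bundle the study conditions. `aged`: 400 static organelles
(modal area 14 px = 0.710 µm²; 21 longer than 2 µm and 17 of those with
aspect ratio > 3, the closest integer counts to 5.3% and 4.2%;
occupancy 0.180), 120 s at 2 Hz. `young_structure`: 600 static
organelles with a 1-px mode (0.051 µm²) and occupancy ≈ 0.085, 120 s at
2 Hz. `young_motility`: 1135 small organelles in a long thin cell with
exactly 215 planted movers (19%), movers drawn preferentially from
peripheral rows, 600 s at 0.5 Hz, flickers off. `overlap_pair`: two
parallel rods 2 px apart under a 1-px PSF — optically one blob,
electrically two units — noiseless, for the separation oracle.

The structure scenes are sampled at 2 Hz and the motility scene at
0.5 Hz rather than 10 Hz; every stage of the method is parameterized in
seconds and is identical at any rate, and these sizes keep a full
pipeline run on one CPU in the tens of seconds. The derivative stencil
(4 s), baseline window (60 s) and motility window (10 min) are the
reference values throughout.

### What the simulator does and does not emulate

It emulates the features the method exploits or must withstand:
organelle-wide synchronous flickers, independent schedules across
organelles, optical overlap via the PSF, photobleaching, shot noise,
whole-field drift, Brownian plus directed motility. It does **not**
emulate Nernstian dye repartitioning kinetics, camera-specific noise,
sub-pixel organelle boundaries, fission/fusion, out-of-focus light, or
the full young-animal size distribution (a realistic heavy tail of
large organelles does not fit a desk-scale placement grid; the young
preset reproduces the 1-px mode and the occupancy, not the geometric
mean). Real flicker rate and duration distributions are not published;
the defaults are stand-ins. Passing the recovery suites therefore shows
the *algorithms* are correct under the stated model — it does not
validate the biological numbers on real myocytes, which require real
recordings.

## Known limitations

- Covariance segmentation presumes organelles are stationary within the
  recording; movers smear their covariance support. Motility is
  accordingly classified from tracks over footprint masks, and
  structure from separate (static) recordings — mirroring the reference
  workflow, where motility was counted by inspecting stacks rather than
  from the covariance traces.
- Two organelles whose flickers happen to coincide within the
  derivative stencil can merge; with 3 events/min over 120 s this is
  rare but non-zero, and it is the main residual error in the recovery
  tests.
- An organelle that never flickers during the recording cannot be
  segmented (reported as `no_flicker`, never silently dropped).
- The mode estimator is pixel-granular by design; for populations whose
  modal bin is not pixel-quantized (e.g. after resampling) a kernel
  estimate would be preferable.
- Masks from duplicate seeds inside one organelle are returned
  separately; deduplication is left to the caller.
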