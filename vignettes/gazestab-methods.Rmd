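---
title: "Methods: vestibulo-ocular performance, swim kinematics and canal morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vestibulo-ocular performance, swim kinematics and canal morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazestab)
```

`gazestab` implements the quantitative chain that links the geometry of the
horizontal semicircular canal to gaze-stabilizing reflex performance and to
swimming behaviour in larval amphibians (*Xenopus laevis* tadpoles and the
axolotl). This vignette explains the models and procedures behind each
analysis stage, the parameters that matter and why their defaults are what
they are, what the synthetic generators do and do not emulate, and the
numerical choices a maintainer would want written down.

## The biological chain in one paragraph

Semicircular canals transduce angular head acceleration through endolymph
displacement. Biomechanics makes the maximum displacement — a proxy for
canal sensitivity — proportional to the circuit radius R and the square of
the lumen radius r, `X_max = Cst * R * r^2`; small or irregular canals
therefore detect head rotation poorly. Weak canal input shows up as a low
angular vestibulo-ocular reflex (aVOR) gain, and the spinal efference copy
that drives eye movements during swimming inherits the same maturation.
The package quantifies every link: canal morphometry from 3D volumes, VOR
and optokinetic (OKR) gain/phase from stimulus/eye traces, spino-ocular
coupling from paired eye-tail traces, swim-bout statistics from pose-tracked
video, and an integrative resampling PCA over per-animal feature vectors.

## Oculomotor gain and phase

Recordings are a sinusoidal stimulus (head rotation at 0.5 Hz, +/-10
degrees, or a visual pattern at 0.1 Hz) with one or two eye-angle traces.
The estimator chain is:

1. **`preprocess()`** — resample everything to 200 samples/s and apply a
   4 Hz low-pass Butterworth of order 4. The filter is run
   forward-backward (zero-lag), because a causal filter at these
   frequencies would add several degrees of phase lag to a 0.5 Hz response
   — a bias the phase metric cannot tolerate. Reflection padding suppresses
   edge transients. When both eyes are present their conjugate average is
   the analysis channel. The *unfiltered* eye velocity is carried along,
   because resetting fast phases live above the low-pass corner and would
   be invisible afterwards.
2. **`segment_cycles()`** — cycles run peak-to-peak on the stimulus, so n
   stimulus peaks give n-1 full cycles. A cycle is excluded when its raw
   peak eye velocity exceeds `jerk_factor` (default 5) times the largest
   stimulus-following velocity compatible with a gain cap of 1.5
   (`1.5 * A * 2 pi f`). Manual exclusion indices are also accepted,
   mirroring analyst-flagged artefacts.
3. **`average_cycles()`** — non-excluded cycles are interpolated onto a
   common cycle-phase grid (400 points) and averaged pointwise.
4. **`gain_phase()`** — gain is peak-to-peak eye over peak-to-peak
   stimulus. Phase compares the timing of the average response peak with
   the stimulus peak, in degrees of cycle wrapped to (-180, 180], negative
   = lead. Peak times are located by quadratic interpolation around the
   discrete maximum; without it a 400-point grid would quantize phase to
   0.9 degrees.

**Sign conventions.** Compensatory (vestibular) responses are anti-phase to
the stimulus; the eye trace is sign-reflected before the peak comparison so
that a perfect compensatory response scores phase 0 and the published
convention (lead negative, e.g. a -54.3 degree lead for the stage-54
*Xenopus* aVOR) falls out directly. For the visual condition the eye
follows the stimulus and no reflection is applied. Both conventions can be
forced through `reflect`.

Circular statistics (`circular_summary()`, `watson_williams()`) summarise
phases across animals: the mean vector direction and its length r (1 =
perfectly clustered), and the Watson-Williams high-concentration F test
with the standard `1 + 3/(8 kappa)` correction; a warning is raised when
the pooled resultant falls below 0.45, where the approximation degrades.

## Swim kinematics and bout detection

`compute_kinematics()` converts a six-landmark pixel trajectory (30
frames/s) to body-centre speed (mm/s, via the pixel scale), cumulative
distance, tail deflection angle (between the skull-to-centre-of-mass axis
and the centre-of-mass-to-tail axis; `tail1` defines the tail axis by
default, `tail2` by option), tail angular velocity, head angle (the
inter-eye line against the image horizontal) and head angular acceleration.
Derivatives are central differences on the native frame grid; the
acceleration uses the central second difference, whose spectral gain
`sinc^2(pi f / f_s)` stays within 2% of the continuous value for the head
oscillation frequencies of interest. Speed and tail velocity are smoothed
with a Savitzky-Golay filter (window 15 frames, order 3).

`detect_bouts()` marks a frame active iff smoothed speed > 3 mm/s **and**
smoothed |tail velocity| > 3 deg/s — the conjunction excludes passive drift
or glides (motion without tail beat) and tail wiggling in place. Both
comparisons are strict, and maximal runs of active frames become bouts, with
one refinement: isolated single-frame gaps are bridged (`bridge_frames = 1`,
set 0 for strict runs). A smoothed zero-mean tail oscillation passes through
zero twice per beat, and when a video frame happens to land on that instant
the conjunction drops for exactly one frame; at 30 frames/s such a gap is an
artefact of sampling, not a pause in locomotion.

`summarize_bouts()` reports percent time swimming and the duration-weighted
bout-length density: each bout contributes mass proportional to its own
duration, so a 30 s bout counts 30 times a 1 s bout; the histogram (default
bin 0.5 s) is normalized to unit integral. Pooled distributions (e.g. head
angular accelerations of two species) are compared with the two-sample
Kolmogorov-Smirnov test (`compare_distributions()`).

## Spino-ocular coupling

During head-fixed swimming the spinal efference copy drives conjugate eye
movements anti-phase to the tail. `detect_tail_cycles()` delimits tail
cycles at successive upward zero crossings of the mean-subtracted tail
angle (ignoring oscillations under 2 degrees peak-to-peak, a configurable
noise floor). `match_eye_cycles()` calls a tail cycle matched when the eye
trace within it moves in the opposite direction — negative eye-tail
covariance — with at least 0.5 degrees of excursion. The published
matching rule is qualitative; the covariance-sign-plus-amplitude criterion
is this package's explicit operationalization, and both thresholds are
arguments. `cycle_ratio()` is the matched percentage;
`gain_vs_amplitude()` fits an ordinary least-squares slope over
amplitude-bin means of the per-cycle gain (eye amplitude / tail amplitude).

## Canal morphometry

2D: `fit_ellipse_2d()` is the numerically stable direct least-squares conic
fit with the ellipse constraint, used for the canal circuit (giving
`circuit_radius()` = sqrt((Ra^2 + Rb^2)/2), the RMS of the semi-axes, which
reduces to the radius for a circle) and for the ampulla outline
(`ampulla_shape()`, major/minor ratio, 1 = circle).

3D: `segment_volume()` blurs (Gaussian, default 4 voxels), thresholds
(Otsu by default) and keeps the largest 26-connected component.
`fit_ellipsoid_3d()` takes the inertia-equivalent ellipsoid of the
foreground (semi-axes `sqrt(5 lambda_i)` from the second moments, the
convention of common 3D measurement plugins), giving the elongation ratio
a/b (lower = rounder circuit) and flatness ratio b/c (higher = more planar
canal). Because second moments are rotation-invariant, the default mode
cannot distinguish a tilted canal from a planar one; the `c_axis = "z"`
mode instead measures c as half the vertical extent between the lowest and
highest detected limits, which is the quantity that changes when a canal is
tilted out of the horizontal plane. Both modes are tested.

`extract_centerline()` follows the standard vascular-modeling recipe: a
chamfer distance transform assigns every lumen voxel its depth; the two
geodesically farthest voxels seed a minimum-cost path whose step cost is
the step length weighted by the inverse squared depth, which pins the path
to the medial axis. The raw path necessarily starts and ends on the duct's
cut faces at off-axis voxels, so the off-ridge end runs (depth below 0.8 of
the median) are trimmed, the path is smoothed (moving average, window 5)
and refined by two passes of perpendicular-plane centroid recentring, and
the end runs are rebuilt by marching along the local tangent to the cut
face. Duct length is the arc length of the result. A closed (looped) duct
cannot be ordered end-to-end; it is flagged by comparing the lumen volume
with the tube volume implied by the recovered path (ratio above 1.6 is an
error, above 1.25 a side-branch warning).

`cross_section_profile()` resamples the volume on planes perpendicular to
the centerline tangent at 200 equally spaced arclength stations (trilinear
interpolation at the native voxel pitch), keeps the in-plane connected
region containing the centre, and reports its area. Stations are inset from
each duct end by about 1.2 local radii — a section straddling the cut face
is not a cross-section — and the `s` coordinate stays normalized to the
full duct length so positions remain comparable. The stenosis summary
follows the published logic: the profile minimum over the profile mean,
with a stenosis *call* when the minimum lies more than one profile SD below
the mean and under half of it, searched in the ampulla-proximal third by
default (the centerline is oriented so the wider end, the ampulla when one
exists, sits at s = 1). The profiles measure areas; the equivalent diameter
`2*sqrt(area/pi)` is reported alongside, since descriptions of the original
3D measurements alternate between diameters and areas.

`xmax()` evaluates the sensitivity model `Cst * R * r^2`. The constant
aggregates endolymph fluid parameters that are not recoverable here, so
`Cst = 1` and only relative (between-species) sensitivities are
interpretable; `xmax_grid()`/`plot_xmax_curves()` draw the iso-sensitivity
plane.

## Cohort integration by resampling PCA

`cs_features()` interpolates all cross-section profiles to a common length,
centres them on the mean profile, and uses the first five principal
components as unsupervised shape features (empirically: mean area offset,
pre-ampullary constriction, ampulla-opening width, monotone trend,
mid-ampulla width).

Different measures exist for different, partly disjoint cohorts of animals.
`resample_cohorts()` builds complete semi-synthetic feature vectors: each
missing cell is drawn with replacement from the observed values of that
variable *within the same species* — the most conservative reading, since
it assumes variables are independently drawn from their species-level
distributions (a pooled-donor switch exists). Each replicate is z-scored
per variable, and the draw is repeated (10,000 times by default; tests and
examples use 100-200, which already stabilize the components for the
cohort sizes involved). `average_components()` runs a PCA per replicate and
averages the loadings. Averaging eigenvectors is ill-defined up to sign, so
each component's sign is first fixed by making its largest-magnitude
loading positive — an invented but necessary convention — and the average
is re-orthonormalized by its polar factor (the nearest orthonormal frame).
`representative_dataset()` picks the replicate with the smallest
elementwise sum of squared differences to the mean replicate (lowest index
on ties), `project_cohort()` scores animals by the dot product, and
`loading_map()` scales loadings by their component's explained-variance
share for the signed heat map. Whether normalization statistics should be
per replicate or computed once on the original cohort is not determinable
from the source procedure; per-replicate is implemented (and is what the
no-missing-data identity test pins down: with nothing missing the whole
pipeline collapses to plain PCA of the z-scored cohort).

## The synthetic generators

No raw recordings are distributable, so every input type has a seeded
generator whose defaults *are* the study conditions, with ground truth
attached to each object:

* **`simulate_swim()`** emulates one-minute, 30 frames/s pose-tracker
  exports in an 18.8 cm dish (0.157 mm/pixel). The two presets encode the
  published per-minute swim budgets: `xenopus_54` swims 28.8 s in four long
  bouts of 7.2 s (near the published duration-weighted bout mean of about
  7 s); `axolotl_54` swims 10.7 s in twelve sub-second bursts
  (10.7/12 s each, matching the published weighted mean below 1 s), each
  followed by a passive glide (exponential decay, time constant 0.3 s).
  Within a bout the tail beats at 4 Hz with 25-degree amplitude; strokes
  build over 0.1 s and the final stroke dies over one half beat period,
  because an instantaneous stop is both unphysical (deceleration is
  drag-limited) and inconsistent with any smoothed-velocity thresholding.
  Landmark jitter is 0.02 mm SD, the sub-pixel accuracy of modern pose
  trackers. Heading is fixed per bout; the generator does not emulate wall
  interactions, turning during bouts, or multi-animal occlusion, so passing
  recovery tests demonstrates detector correctness under clean kinematics,
  not robustness to crowded arenas.
* **`simulate_eyes()`** produces `A sin(2 pi f t)` stimuli with eyes
  following (visual) or opposing (vestibular) at a programmed gain and
  phase, Gaussian position noise, and optional resetting fast phases:
  100 ms linear ramps sweeping about three stimulus amplitudes against the
  slow-phase direction, large enough to exceed the jerk-exclusion velocity
  bound, as real resetting saccades do. Position noise is white at the
  sample rate; jerk screening therefore differentiates over a 50 ms base
  rather than sample-to-sample.
* **`simulate_eye_tail()`** oscillates a tail for n cycles with amplitudes
  jittered +/-30% and couples a programmed fraction of cycles to
  opposite-direction eye excursions, optionally with a linear gain decline
  in amplitude.
* **`simulate_canal()`** voxelizes an elliptic-torus segment with optional
  out-of-plane tilt, a Gaussian ampulla bulge over the last 15% of arc, a
  localized stenosis (radius multiplied by a constriction factor), blunt
  (flat) end faces as a cropped segmentation would have, and optional blur
  and noise for segmentation tests. Ground truth includes the analytic
  centerline length, the area profile `pi r(s)^2` and the stenosis
  min/mean ratio. It does not simulate optics beyond Gaussian blur, nor
  real ampullary anatomy.

## Numerical choices and degenerate inputs

* Problem sizes: recovery checks use 60 s trajectories (1800 frames),
  10-20 stimulus cycles, phantoms of roughly 150-450 um circuit radius at
  2-6 um voxels, and 100-4000 PCA replicates; these sizes already give
  sub-tolerance recovery and keep any single check in seconds to a couple
  of minutes.
* Missing landmark frames are linearly interpolated up to 5 frames
  (`fill_landmark_gaps()`); longer dropouts stay missing and are reported
  so the affected bouts can be discarded.
* Trajectories shorter than the smoothing window, traces shorter than two
  stimulus cycles or than the filter warm-up, flat stimuli, all-excluded
  cycle sets, empty segmentations, sub-2-voxel lumens, fewer profiles than
  requested components, and donor-less variables all raise classed errors
  rather than returning numbers.
* Ties: the representative replicate takes the lowest index; component
  signs follow the largest-|loading| rule; `which.min`/`which.max`
  tie-breaks are therefore deterministic.
* All generators are bit-reproducible under a fixed seed.

## Known limitations

* The centerline is a single end-to-end path: true side branches are only
  warned about, not reconstructed.
* The moment-based ellipsoid describes the voxel cloud, not a fitted
  bounding surface; its semi-axes match analytic solids well but are a
  convention, and ratios are the quantities to interpret.
* The ellipse fit of a short partial arc (well under half a turn) is
  ill-conditioned; circuit radii should be fitted on (near-)complete
  circuits, as the full-torus phantoms and the 2D boundary workflow do.
* The Watson-Williams test assumes concentrated von Mises samples; the
  implementation warns, but does not switch tests, below the usual
  concentration rule of thumb.
* Percent-time-swimming recovery is validated against scripted generator
  schedules; real tracker output adds identity swaps and dropouts that the
  generator only models as Gaussian jitter and short gaps.
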