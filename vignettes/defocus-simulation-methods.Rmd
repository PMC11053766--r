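---
title: "Simulating gaze-contingent defocus and autofocal correction"
author: "focalsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating gaze-contingent defocus and autofocal correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focalsim)
```

## The problem

Presbyopia is the age-related loss of accommodation: the eye can no longer
add the focusing power (up to about 3.3 D for an object at 30 cm) that near
vision demands. Focus-tunable "autofocal" eyewear corrects this by changing
lens power on the fly, which raises a control problem: from gaze and scene
depth, decide where the lens should focus, and how fast and with what delay
it can get there. Evaluating such control policies on hardware is slow;
`focalsim` instead simulates the whole loop — optics, scene, lens, gaze,
control, and a psychophysical task that scores the outcome — so that
policies and lens parameters can be compared under identical, repeatable
conditions.

## Optical model

All optics are first-order. An object at distance $d$ metres demands $1/d$
diopters of vergence. The eye accommodates optimally within its residual
amplitude $A$: the achieved accommodation is
$\mathrm{clamp}(D_\mathrm{obj} - P_\mathrm{lens} + R,\ 0,\ A)$, where $R$ is
the spherical refractive error at far. No accommodative lag or lead is
modelled — the simplest policy consistent with "objects too close for the
residual amplitude are blurred". The residual defocus error
$\Delta D = |D_\mathrm{obj} - (P_\mathrm{lens} + A_\mathrm{ach} - R)|$
produces a retinal blur disk of angular diameter

$$\beta = p \cdot \Delta D$$

with $p$ the pupil diameter in metres — the standard small-angle thin-lens
circle-of-confusion relation, chosen because it is analytically checkable
and linear in both arguments (a 3 mm pupil with 1 D of defocus gives 3 mrad,
about 10.3 arcmin). Higher-order and chromatic aberrations are out of scope;
a sphero-cylindrical extension is available as an elliptical kernel whose
long axis follows the cylinder axis (focal-line convention).

In `computeBlurField()` the accommodation response is applied per pixel by
default, i.e. each location is blurred as if it were fixated. This is an
upper bound on sharpness for eyes with usable amplitude; for the presbyopic
eyes (amplitude 0) that the simulator chiefly targets the distinction
vanishes, and gaze-contingent runs can pin accommodation to the fixated
demand with `accommodation_demand_D`.

## Scenes and projection

Scenes are RGB-D rasters under a pinhole camera: image centre on the optical
axis, $x_{px} = f_{px}\tan(\mathrm{azimuth})$ with
$f_{px} = (W/2)/\tan(\mathrm{FOV}/2)$, row 1 at the top, elevation positive
upward. Angular blur converts to pixels as $\beta f_{px}$.

The default office scene places three bright screens in front of a flat
wall at 6.5 m: a 12 x 7 cm phone at 0.30 m, a 24-inch display at 1 m and a
55-inch TV at 6 m, at non-overlapping visual directions inside a 90 degree
field of view. Only distances are constrained by the task design; sizes and
directions are typical-device choices, and the background depth is set just
beyond the far screen. The depth histogram therefore has modes at exactly
{0.3, 1, 6, 6.5} m. Scenes are deliberately non-photorealistic (flat
rectangles, no lighting or texture): the quantities under study depend on
depth structure, not appearance.

## Blur rendering

The blur field assigns every pixel a disk diameter in pixels. Kernels are
discretised disks — a pixel is in the support if its centre lies within
diameter/2 — normalised to sum 1; diameters at or below one pixel map to the
identity kernel, so a zero-defocus rendering is bit-identical to its input.
Convolution uses reflect padding, which preserves mean intensity away from
the border.

Two renderers share the contract. `gather` applies each pixel's own kernel
directly — $O(HWk^2)$, the reference oracle used in tests. `layered`
quantises the blur field into at most 16 diameter levels, blurs each level's
masked layer and coverage mask with that level's kernel, composites
far-to-near, and renormalises by accumulated coverage. In the interior of a
level the composite reduces to the gather result exactly (the tests require
agreement within 2/255 there, and observe agreement at floating-point
precision); within a kernel radius of a level boundary the two differ — the
edge-bleed that layered depth-of-field methods accept in exchange for
tractable cost. Quantisation is exact whenever the field has at most 16
distinct diameters, which covers every piecewise-planar scene the package
generates.

## Lens dynamics and control policies

The tunable lens has exactly the two temporal parameters a real
focus-tunable lens datasheet states: a transport delay and a slew-rate
limit. A command matures after the delay, then the power tracks the
range-clamped command at up to the rate limit and settles exactly, with no
overshoot and no further invented dynamics. Maturation instants inside a
step are handled by piecewise integration, so trajectories are step-size
independent and a 0.2 s delay shifts the whole trajectory by exactly 0.2 s.

Three policies command the lens:

* **gaze point** — the demand of the depth under gaze, robustified as the
  median of a 5 x 5 pixel window (raw depth at a saccadic sample is noisy),
  optionally smoothed over a window of recent commands;
* **depth mode** — the median demand inside the modal 0.25 D-wide dioptric
  bin among pixels within a configurable foveal radius (default 2 degrees),
  ties broken toward the nearer bin; binning is dioptric rather than metric
  because blur scales with diopters;
* **manual** — piecewise-constant user events, effective at $t \ge$ event
  time.

Invalid or out-of-image gaze holds the last command. Progressive lenses are
modelled as an elevation-dependent power map: distance power above the
corridor, distance + add below, linear inside — continuous and monotone.

## Gaze simulation

Hardware eye-tracking is replaced by a generator: fixations at scheduled
targets with isotropic Gaussian angular noise (default 0.3 degrees SD, a
typical video-oculography figure), linear angular sweeps between targets
labelled as saccades (default 40 ms). Traces are monocular cyclopean.
The generic gaze CSV format (timestamp_s, gaze_x_px, gaze_y_px,
azimuth_deg, elevation_deg, pupil_mm, validity, label) round-trips exactly
for text-representable values, and a small state machine mirrors a
device-agnostic recorder: device and sampling thread start/stop separately,
sampling requires a started device, stopping the device cascades.

## The matching task and its observer

Each trial shows a Landolt ring (8 orientations, gap = diameter/5) on one
screen, a Sloan letter (8-letter alphabet C D H K N O R S) on another, and
an 8-column orientation-letter table on the third; the subject answers
whether the presented pair occupies one table column. The table screen is
uniform over the three screens so no fixed fixation order works; the match
prior is fixed at 1/2 so chance performance is well defined at 0.5. On
non-match trials the presented pair is guaranteed absent from the table.
Stimulus angular size is configurable (10 arcmin gap by default — a
suprathreshold size that blur, not resolution, should limit); placements are
center or corner with Gaussian jitter (SD 5 % of the screen extent).

No human observer exists in the loop, so responses come from a synthetic
observer: each optotype is identified correctly with probability
$1/8 + 7/8\,\sigma\!\left(-s(\log r - \log r_{50})\right)$, where $r$ is
blur diameter over gap size, $r_{50} = 1$ (identification halves when the
blur disk equals the gap) and slope $s = 4$; misidentifications are uniform
over the 7 alternatives, table lookup is errorless, and the answer follows
the identified pair — which makes heavily blurred performance converge to
0.5 without any extra guessing rule. Reaction time is
$(0.8 + 0.4\,n_\mathrm{refocus>1D})\,\mathrm{s} \times e^{N(0,0.15)}$.
All observer constants are declared synthetic: they exercise the task
machinery and give the right limiting behaviour (ceiling 1.0 at zero blur,
chance 0.5 at saturating blur, monotone in between), but they are not fitted
to human data, so absolute accuracies in between the limits carry no
empirical claim.

## Protocols, logging, reproducibility

A protocol is an ordered list of parameterized scene ids; pools load from
JSON, selection is explicit or seeded-random. Subject folders never
overwrite: `sub01`, then `sub01_1`, `sub01_2`. Each protocol position gets
its own subfolder, into which components write system-timestamped CSVs
(gaze, tuning power changes, task responses, questionnaire answers);
a repeat control writes a second timestamped file set into the same
subfolder, a skip records the scene as skipped. Questionnaires load by
abbreviation from JSON (a NASA-TLX definition ships with the package).
Interactive run control is a scriptable command stream so tests are
deterministic.

Every stochastic component takes a seed and restores the caller's RNG
state. Default problem sizes (office scenes at 256 x 192 or 128 x 96,
32 x 32 oracle comparisons, 30-60 Hz gaze, blocks of a few trials for
end-to-end runs and 2000-3000 draws for distributional checks) keep a full
test run and the acceptance script in the tens of seconds on one core while
leaving binomial error well inside the asserted bounds.

## Known limitations

First-order optics only; no occlusion-aware layer composition beyond
blurred-mask alpha (edge bleed at depth boundaries); per-pixel
accommodation as the default blur-field policy; a stylised scene without
photometric realism; a declared, unfitted observer; and no modelling of
display resolution limits or the vergence-accommodation conflict of real
stereoscopic presentation. Conclusions about control policies therefore
transfer to real autofocal hardware only at the level the model captures:
dioptric geometry, lens dynamics, and gaze statistics.
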