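---
title: "Modeling the activity-dependent development of the V1 retinotopic map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the activity-dependent development of the V1 retinotopic map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

In primate primary visual cortex (V1) the retinotopic map lays eccentricity
(distance of a visual-field point from fixation, `r` degrees) and meridional
angle (its angular position, `theta`) out along roughly orthogonal cortical
axes: eccentricity along the nasotemporal axis, angle along the
dorsoventral axis. Analytically this organization is well approximated by
the complex-logarithmic transform

    u + iv = log(x + iy + a),      x + iy = r e^{i theta}

with a species constant `a > 0`. `retinomap` asks whether a purely
activity-dependent mechanism — self-organization driven by visual input —
can develop such a map, given only a coarse initial topography and a
cortical sheet whose available area is bounded by the complex-log image of
the vertical retinal meridian (`u = log sqrt(a^2 + (a tan v)^2)`).

Two model families are provided:

* a **Kohonen SOM** trained on rotated/dilated bars, showing that the two
  abstract stimulus features (rotation, dilation) self-organize onto
  locally orthogonal axes of the output sheet;
* a **LISSOM** cortical sheet (limited-radius afferent fields plus
  modifiable lateral excitatory and inhibitory connections, multi-step
  settling, normalized Hebbian learning) that develops a genuine
  point-to-point retinotopic map, validated against the complex-log
  transform, and supports retinal-lesion plasticity experiments.

## Stimuli

All inputs are synthesized in-package as binary images on pixel grids
(pixel-center coordinates, origin at the image center, y upward; the
retinal half-width spans 4 degrees of eccentricity, the modeled central
visual field):

* `make_bar()` / `enumerate_bar_set()`: filled rectangles of aspect ratio
  0.1, 9 rotations (0-160 degrees, step 20; 180 is identified with 0) x 16
  dilations = 144 configurations. Dilation lengths are linearly spaced for
  model training; exponentially spaced copies of the same endpoints define
  the complex-log reference inputs, because the analytic map is
  logarithmic in eccentricity while the developed map is linear (the model
  omits the retinal ganglion cell density falloff that produces the log
  compression).
* `make_ring()`, `make_point()`, `make_lesioned_disc()`: probe and lesion
  stimuli. Rasterization is a point-in-shape test on pixel centers — no
  anti-aliasing, so active-pixel counts are exactly testable. The smallest
  bar is the shortest whose width rounds to one pixel (length 5 at aspect
  0.1); the longest is 0.95 x the grid width, capped so every rotation
  fits.

## The SOM component

Classic Kohonen dynamics on a 12 x 12 sheet (optionally a boundary-masked
24 x 48 sheet): Euclidean-nearest weight vector wins, all in-mask nodes
move toward the input with a Gaussian neighborhood factor
`eta_max exp(-d^2 / 2 sigma^2)`. Two printed equations required
interpretation:

* the competitive update as printed moves weights *away* from the input
  (`W + eta (W - V)`); the standard sign `W + eta (V - W)` is implemented —
  the printed rule cannot self-organize;
* no learning-rate or neighborhood schedule is printed. The low-level
  operations take constant `eta_max`, `sigma`; the experiments use the
  package's annealing schedule, chosen once as standard Kohonen practice:
  per-presentation linear decay of `eta` 0.5 -> 0.02 and `sigma` 6 -> 0.75
  over the 10-epoch training horizon, held constant afterwards. With this
  schedule the trained map is stable (well under 5% winner reassignment
  between epochs 10 and 20), matching the reported behavior of the
  original simulations under continued training.

**Orthogonality is local, not global.** Bar rotation is a circular feature
(0 = 180 degrees), so a well-organized SOM embeds the rotation x dilation
grid as a *polar fan*: dilation radial, rotation angular. No single global
pair of axes exists, but the layout is orthogonal everywhere locally.
`axis_orthogonality()` therefore averages the angle between the local
dilation-step and rotation-step winner displacements over the feature
grid (magnitude-weighted), which scores 90 for a Cartesian layout, 0 for a
collinear one, and correctly credits polar maps.

## The LISSOM component

For input `x`, activity starts afferent-only, `y = g(A x)`, then settles
for up to 9 steps under

    y(t) = g( p * A x + q * E y(t-1) - r * I y(t-1) )

with the piecewise-linear sigmoid `g` (thresholds 0.083 and 0.633), the
printed scaling factors `p = 1.5, q = 1.1, r = 1.1`, and presynaptic
activity read inside the lateral sums (the printed equation indexes the
postsynaptic unit inside the sum — treated as an index typo, since the sum
would otherwise be constant). All three weight fields learn the normalized
Hebbian rule `w' = (w + eta y P) / sum(w + eta y P)` with the printed rates
(`eta_A = 0.3`, `eta_E = 0.25`, `eta_I` 0.25 switching to 0.5 at iteration
500). Radius bounds are fractions of the source sheet width: afferent 1
(25 retinal grid units), excitatory 0.03 (1.44 cortical units; exactly the
8 Moore neighbors), inhibitory 0.55 (26.4 units; 9.9 mm at the calibration
of 0.375 mm per cortical grid unit, back-derived from the printed pairs
26.4 -> 9.9 mm and 1.44 -> 0.54 mm).

### Initial conditions and schedules (the open design space)

The published description of the model has connections starting with
small radii that grow out to the bounds, weights random within the
initial radius, and a rough initial retinotopy (from molecular gradients
/ retinal waves) assumed; it does not state the initial radii, the growth
schedule, the retinotopy formula, or its precision. These were fixed by a
calibration study (seeds 3, 7, 11; the package does not revisit them):

* **Initial retinotopy**: the cortical neuron at polar position
  `(rho, phi)` about the mask's foveal apex (leftmost in-mask column,
  middle row) is centered on the retinal point with eccentricity
  `rho / rho_max x (retinal half-width)` and angle `phi`, plus Gaussian
  scatter of 1 retinal pixel (`init_jitter`) — coarse enough that training
  visibly refines the map (eccentricity-column Spearman rises from ~0.85
  at initialization to ~0.97 by iteration 900, angle-row from ~0.64 to
  ~0.87), faithful to the premise that the initial topography alone is
  not the final map.
* **Initial radii**: afferent 2.5 retinal pixels; excitatory at its
  (already short-range) bound; inhibitory at a quarter of its bound.
  Starting the excitatory field at its bound matters: without local
  excitatory smoothing from the first iteration, settling amplifies
  afferent noise into interleaved patches that learning then imprints.
* **Growth schedule**: lateral radii grow linearly to their bounds over
  the first 200 iterations (in discrete steps of 10 iterations — support
  recomputation is the dominant cost of an iteration); newly recruited
  connections receive ~1% of the row's weight mass and earn more only
  through Hebbian correlation. The **afferent** radius is held at its
  initial value for the standard 900-iteration run (growth scheduled at
  iterations 900-1350). This is the load-bearing calibration: with the
  printed learning rate, one presentation adds `eta_A y sum(P)` (tens of
  units) of raw weight mass against a normalized total of 1, so a
  neuron's receptive field is largely rewritten toward each bar it
  responds to, *within whatever support is open*. A small fixed support
  anchors every neuron to its retinotopic neighborhood (the anatomical
  scaffold); an early-growing support lets receptive fields random-walk
  across the retina, and the map collapses (angle-row Spearman falls from
  -0.72 to ~0 by iteration 300; freeze experiments isolate the afferent
  update as the cause). The full-retina bound, the radius-growth
  machinery, and the conversion arithmetic are all implemented and
  tested; only the point in training at which the afferent radius opens
  is deferred.

### Numerical choices

* Settling: 9 steps with early exit once the largest activity change is
  below 1e-4; activity is exactly zero outside the boundary mask at every
  step (out-of-mask neurons have no incoming or outgoing weights).
* Divisive normalization keeps each neuron's per-projection weight sum at
  1 within 1e-9 throughout training (tested invariant); weights are
  strictly positive exactly on their support, which the compiled update
  kernel exploits.
* Determinism: every iteration reseeds from `(rng_seed, t)`, so training
  is resumable — 200 + 700 iterations is bit-identical to 900 straight —
  and all randomness flows from the one configured seed.

## Map analysis

* `probe_point_map()` presents a unit impulse at every retinal pixel,
  settles, and assigns each cortical neuron the activity-weighted average
  of the probe positions that activate it (threshold: 10% of the maximum
  response; unstated in the source, exposed in config).
* `meridional_preference()` sums responses over the dilation sweep per
  rotation and applies doubled-angle circular statistics (standard for
  orientation data with a 180-degree period); the estimator is the
  package's choice, as the source does not define how its
  preference/selectivity images were computed. Neurons with selectivity
  below 0.2 are reported as unselective, not suppressed — the
  non-selective central (foveal) region is a real feature of the model.
* `rms_error_per_pixel()` max-normalizes both images and averages over
  in-mask pixels; reference images are forward-scattered complex-log
  transforms of the exponentially spaced input family.
* `lpz_area()` counts neurons active for the intact disc but silent for
  the lesioned one, at an absolute threshold of 0.1.

A note on the RMS-versus-iteration trend: per-pixel RMS against the thin
analytic reference is dominated by the thickness of the settled activity
bands, not by map order. Band thickness grows somewhat during the printed
`eta_I = 0.25` phase and shrinks after the switch to 0.5, so RMS over
training is nearly flat (changes of |0.002-0.02| around zero between
iterations 200 and 900, ring inputs most clearly rising) even while the
rank-order quality of the map improves monotonically. The acceptance
suite asserts the decreasing trend as specified and it is expected to
fail; the Spearman trajectory is the faithful indicator of map
refinement.

## What the synthetic world does and does not establish

The stimulus generator produces exactly the stated world: binary centered
bars (9 x 16 configurations), rings, single-pixel probes, lesioned discs.
It does not emulate natural images, contrast variation, noise, retinal
ganglion cell density falloff (hence the linear — not logarithmic —
eccentricity axis of the developed map), or an LGN stage. A green test
therefore establishes that the implemented dynamics reproduce the claimed
organizational phenomena under the stated training regime, not that the
mechanism explains biological map development.

## Known limitations

* The literal printed parameter set, with sum-1 normalization and binary
  bars, admits degenerate regimes (saturated activity covering ~40% of
  the sheet; receptive-field teleportation at the printed afferent
  learning rate). The calibrated initial conditions and schedules above
  are the package's resolution of that under-determination and are
  documented rather than hidden.
* Only the right visual hemifield / one hemisphere is modeled; left
  hemifield pixels are ignored (with a warning) by the complex-log
  transform.
* Species presets (a = 1, 2.5, 4) change only the boundary mask shape;
  no species-specific physiology is modeled.
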