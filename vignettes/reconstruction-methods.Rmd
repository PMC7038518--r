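---
title: "Planning and reconstructing minirhizotron tube panoramas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning and reconstructing minirhizotron tube panoramas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizopan)
```

`rhizopan` models one specific instrument class: an automated minirhizotron
imager in which a small CMOS camera on a motorized carriage rotates through
360° inside a transparent soil tube, photographing the tube wall as a
sequence of overlapping snaps, strip by strip down the tube. This vignette
explains the models and numerical choices behind each stage, what the
synthetic scene generator does and does not emulate, and the limitations a
user should know about.

## Scan geometry and the planner

All planning operations are closed form. Snaps per rotation is
`ceil(360 / (fov · (1 − overlap)))`: covering the circle with frames of
angular width `fov` while each shares the fraction `overlap` with its
neighbour. Because the count is rounded up, the *realized* overlap
`1 − 360/(n · fov)` is at least the requested one; with a 60° lens and 40%
requested overlap, n = 10 and the realized overlap is exactly 0.4.
Strip count uses `floor(tube_len / step)` — the final partial step of a
tube is not scanned — while angular coverage counts use `ceil`, since an
uncovered wedge is not acceptable. Vertical overlap between strips is
`(frame_h − step)/frame_h`; the default 15 mm step on a 28 mm frame gives
46.4%, comfortably above the 40% the stitcher assumes as usable.

The energy budget chains per-cycle energy (`Σ power · active_s / 3600` over
the component load table) through daily demand, conversion efficiency,
battery sizing (`daily · autonomy_days / DOD`) and solar panel sizing
(`battery / (charge_eff · charge_h)`). Two conventions are exposed: exact
arithmetic (default) and `paper_rounding`, which rounds daily energy to a
whole Wh before loss-scaling, keeps the supply-side figure unrounded for
battery sizing, and rounds final battery/panel figures to whole units and
transfer time to whole minutes — the way such budgets are quoted on a
datasheet. `battery_ah()` additionally offers `ceiling` rounding, the only
mode that guarantees the amp-hour figure actually stores the requested
energy. Transfer time first rounds the payload to whole megabytes
(`round(n · kB/1000)`) and then applies `MB · 8 · (1 + overhead) / Mbps`.

One ambiguity deserves note: manual-coverage protocols sometimes fix the
number of vertical camera positions by convention rather than by frame
arithmetic (40 positions on a 1 m tube with a 24 mm frame, where
`1000/24 ≈ 41.7`). `manual_coverage()` therefore accepts explicit count
overrides instead of enforcing one rounding rule.

`acquisition_time()` defaults to 3.5 s per rotation and 2.9 s per vertical
step, chosen so a full 66-strip tube takes about seven minutes — the
operating point of the prototype locomotive this package models.

## The synthetic scene generator

`tube_scene()` builds the ground truth the whole test suite scores against:
an unwrapped cylinder texture whose width corresponds to the circumference
(π · 63.5 ≈ 199.5 mm) and height to the tube length, at 1/3 mm per pixel by
default. Soil is band-limited noise: white noise smoothed with circular
Gaussian kernels at three scales, shading and tinting a brown base colour.
The circular boundary makes the texture angularly seamless, as a real
cylinder is. Roots are random-walk polylines biased downwards, stamped with
a Gaussian cross-section (σ = half the root width) and drawn brighter than
any soil pixel, with occasional branching; pale root tissue against dark
soil is the contrast regime of white-light root imaging. All randomness
derives from one seed, and a scene with n + 1 roots contains the same first
n roots, which makes root-count monotonicity testable.

`render_snap()` extracts the angular window `[angle − fov/2, angle + fov/2]`
and the vertical window `[depth, depth + frame_h]`, resamples it to the
sensor grid bilinearly (wrapping across the angular seam), then applies the
degradations in a fixed order: forward barrel distortion, quadratic
vignetting, a log-normal exposure gain, specular reflection streaks,
additive Gaussian noise, clipping, and 8-bit quantization. Two conventions
are fixed here: `depth_mm` is the *top edge* of the snap footprint (so the
strip sequence 0, 15, 30 … mm keeps every window inside the tube), and
angle 0 is the tube top, increasing clockwise seen from the open end.

Reflection streaks are modelled as near-vertical bright bands whose hue is
set to a fixed artifact hue (default 0.83, a magenta well separated from
soil browns and root yellows), saturation reduced and value boosted. The
real instrument's streaks arise from LED light reflecting off the tube
wall; their hue statistics are an instrument property, so the simulator
makes the artifact hue configurable rather than claiming a physical value.
The true streak mask is attached to each rendered snap, giving detection
tests an exact reference.

What the generator does **not** emulate: motion blur (removed in hardware
by a capture delay), focus variation across the curved wall, condensation
droplets, soil movement between sessions, and real root optical properties
(translucency, specular root surfaces). Passing round-trip tests therefore
demonstrates that the *reconstruction chain* is geometrically and
photometrically consistent, not that detection thresholds will transfer to
any particular field instrument unchanged.

The multispectral mode renders single-band snaps as luminance scaled by a
per-wavelength gain for the ten LED bands (395–850 nm). The default gains
rise towards the near infrared — the regime in which root/soil contrast is
strongest — but they are modelling choices, not measurements.

## Radial distortion

The lens-plus-cylinder geometry is modelled as a single radial mapping
about a distortion centre:

  r_d = r_u (1 + k₁ρ² + k₂ρ⁴ + k₃ρ⁶),  ρ = r_u / r_norm.

A wide-angle lens gives barrel distortion (k₁ < 0). The model is the
standard even-order polynomial used throughout photogrammetry; one measured
monotone profile stands in for the separate lens and surface contributions,
which matches how such instruments are calibrated in practice (one grid
target imaged through the actual tube).

`calibrate_distortion()` fits (k₁, k₂, k₃, cx, cy) to point
correspondences: given a centre the displacement is linear in k, so k is
solved by linear least squares inside a Nelder–Mead search over the centre.
Degenerate geometries — fewer than 12 points, fewer than 3 distinct radii,
collinear points — are rejected explicitly, because they leave the
polynomial or the centre unidentifiable. `calibrate_from_grid()` covers the
image route: dark dots are thresholded, labelled (EBImage), and their
intensity-weighted centroids paired with the ideal grid.

Correction inverts the mapping with a 1024-knot linear-interpolation lookup
table over radius, built once per image; the profile constructor refuses
non-monotone mappings (`dr_d/dr_u ≤ 0` anywhere inside the working radius),
so the inverse always exists. Images are resampled bilinearly; point
round-trips are accurate to ~10⁻³ px, image round-trips to a fraction of an
8-bit step away from the clipped borders.

A caveat worth stating: with 0.2 px centroid noise the three polynomial
coefficients are individually poorly conditioned (ρ², ρ⁴, ρ⁶ are nearly
collinear on a sensor-sized domain). k₁ — the coefficient that *is* the
barrel profile for practical purposes — is recovered to a few percent, and
the fitted radial curve agrees with the true one to sub-pixel level, but
k₂ and k₃ individually are not trustworthy at that noise level. Tests
therefore assert k₁ and the curve, not the tail coefficients.

## Reflection removal

In HSV space the streaks are bright (high V), desaturated, and concentrated
in a narrow hue band distinct from the soil/root hues, so detection is
hue-plane thresholding: membership in an artifact hue band (wraparound
aware, since hue is circular), optionally gated by V ≥ v_min and S ≤ s_max,
followed by morphological closing to consolidate broken streaks. The
default `auto` policy finds the band as the isolated secondary mode of the
hue histogram of bright pixels — reproducible without per-instrument
tuning — while `fixed` accepts explicit bounds for instruments whose
artifact hue is known.

Removal never touches unmasked pixels (asserted bit-exactly in tests). Two
fill policies exist: `interpolate` (default) diffuses values inward from
the mask boundary and smooths inside the mask for a fixed number of sweeps,
which is neutral for downstream stitching; `clamp_hue` replaces only the
hue with the local circular median of unmasked neighbours, preserving S and
V, for users who want minimal intervention. Whether a real pipeline should
interpolate or merely suppress the hue is a judgement call; interpolation
was chosen as the default because inpainted luminance blends better across
seams.

The masks are not discarded: they ride along the snap table, are warped
together with the pixels by the correction stage, and are excluded from
registration scoring (below) — inpainted texture carries no positional
information and must not steer a shift.

## Normalization and cropping

Exposure normalization is gain-only, so within-snap pixel rank order is
preserved. Each adjacent pair (within a strip, including the wraparound
pair, and vertically across strips) contributes one equation
γ_a − γ_b = log(median luminance of b's overlap) − log(median of a's), and
the whole log-gain system is solved by least squares anchored at a
reference snap. Solving jointly rather than chaining means an inconsistent
cycle (noise, clipping) is distributed evenly instead of accumulating into
the last seam. Gains are clipped to [0.5, 2]: a snap needing more than a
factor-2 correction indicates a capture fault, not exposure jitter. With no
overlap at all the function falls back to global median matching, with a
warning. Normalization runs before cropping because the overlaps it feeds
on are exactly what cropping removes.

Cropping retains each snap's central non-overlapped wedge — 360/n degrees
wide and one vertical step tall — plus a configurable guard margin on each
side (default 6 px in the pipeline). The guard is what the stitcher blends
and refines over; with guard 0 the crops butt-join exactly and stitching
reduces to concatenation. Crop offsets are recorded per snap so panorama
coordinates remain reconstructible.

## Stitching

The carriage positions are known to ~0.7° and 15 µm, far below a pixel, so
stitching is translational with a geometric prior, not feature-based
homography estimation: `register_pair()` searches integer shifts within a
small window (default ±2 px) around the prior and scores each by the
normalized cross-correlation of the overlap. Three robustness measures
matter on low-texture soil:

* patches are detrended (least-squares plane removed) before correlating,
  which cancels smooth shading — vignetting residues, inpainted fills —
  without the boundary artifacts of a high-pass filter on a narrow band;
* masked (inpainted) pixels are excluded from the correlation;
* a refined shift is accepted only if its score reaches 0.5 *and* beats the
  prior's score by 0.02 — otherwise the prior is kept. A flat overlap
  returns the prior with score 0 and a warning.

Within a strip the n seam offsets (including the wraparound seam) must sum
to the fixed strip width n · crop_w; the closure residual is distributed
uniformly across seams, one pixel at a time, so the output width is exact
regardless of refinement. Overlapping guard margins are blended with a
linear feather whose ramp spans the overlap; complementary ramps sum to
one, and the composite is normalized by total weight so partial coverage at
the canvas edges stays correct. Strips are then stacked by depth, each
registered vertically against its predecessor in the strip-overlap band,
with per-strip horizontal (angular) alignment chained from the first strip.
The result records per-seam scores, closure residuals, scales
(px/degree, mm/px) and a provenance digest, and the whole operation is
byte-deterministic for identical inputs.

## Pipeline order and configuration

`run_pipeline()` fixes the stage order: reflection cleaning, distortion
correction, exposure normalization, cropping, stitching. Cleaning precedes
correction because the streaks are artifacts of the sensor frame — straight
and hue-coherent there — and whatever the fill invents is then warped
together with the real pixels instead of being detected on curved,
interpolated streaks. Every stage is individually skippable; skipping all
of them still assembles the geometric crops into a panorama, which is the
correct baseline for ablation comparisons. Configuration is a plain list
(or YAML file) validated against defaults that mirror the reference
instrument: 60° lens, 40% overlap, 35 × 28 mm frame, 63.5 mm tube, 15 mm
step.

## Problem sizes in the tests

The test suite simulates 3-strip scenes (30 snaps of 84 × 100 px) for unit
checks and a 5-strip scene (50 snaps) for the end-to-end round trips —
small enough that the whole suite runs in well under a minute while every
geometric effect (wraparound, closure, strip stacking) is still exercised.
The end-to-end checks assert a round-trip correlation of at least 0.99
with no degradations and at least 0.90 under the default degradation set
(barrel distortion k₁ = −0.06, 8% vignetting, two streaks per snap,
exposure jitter σ = 0.05, noise σ = 2/255) with a frozen seed.

## Known limitations

* The radial model ignores tangential (decentering) distortion; if a real
  carriage tilts the camera, the residual will appear as a small
  depth-dependent shift that the registration search absorbs only partly.
* Vignetting is compensated only implicitly (detrended registration,
  feather blending); no flat-field is estimated or applied.
* Reflection detection assumes the artifact hue band does not collide with
  a legitimate image hue; on soils containing that hue the v/s gates are
  the only defence.
* Exposure normalization is scalar per snap; spatially varying illumination
  within one snap is not corrected.
* Registration is integer-pixel; sub-pixel seam alignment is deliberately
  left to the mechanical prior.
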