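---
title: "Methods and design notes for pedobaR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for pedobaR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedobaR)
```

This vignette documents the data model, the algorithms, the numerical
conventions and the deliberately made design choices in pedobaR, in the
spirit of a methods section: enough detail that every reported number can
be re-derived by hand.

## Data model and units

A `pressure_recording` holds a `T × rows × cols` array of pressures in
kPa, a `sensor_grid` (per-cell centers and polygon outlines in mm, areas
in cm², an active-cell map for trimmed insole layouts), the hardware
family, the foot side, an `event_list` of inclusive `[start, end]` frame
intervals, and named regional masks. One unit convention is fixed
everywhere: pressures kPa, lengths mm, areas cm², forces N, so that
1 kPa on 1 cm² is 0.1 N. Frames are 1-indexed (the natural R convention;
an early design sketch used 0-indexing, but in R that invites off-by-one
errors in every subscript). The coordinate origin is the bottom-left cell
center with x along columns and y along rows, increasing toward the toes
once the footprint is aligned.

`validate_recording()` checks every structural invariant (finite
non-negative pressures, positive areas on active cells, silent inactive
cells, simple cell polygons containing their centers, sorted disjoint
in-range events, unique in-grid masks) and reports all violations; every
constructor in the package produces objects that pass it, and every file
reader validates before returning.

## File formats

Real vendor exports vary by software version and are not publicly
specified. pedobaR therefore documents one simplified text dialect per
hardware family and parses strictly against it, failing loudly with
located errors (frame index, missing header key) rather than guessing.
Declared N/cm² values are scaled by exactly 10 into kPa; decimal commas
are accepted whenever the delimiter is unambiguous. Sensor-major insole
exports (pedar, pliance) carry no geometry, so geometry comes from
registered layouts — a bundled 99-sensor insole (15 × 7 trimmed grid,
11.4 × 16 mm cells) and a 16 × 16 mat — matched by sensor count;
`register_insole_layout()` adds more.

The supported archival path is the canonical format: a versioned
plain-text container with a key–value header, a per-cell geometry table,
dense frame blocks, and optional EVENTS/MASKS sections. Numbers are
written with 17 significant digits, so doubles round-trip bit-faithfully
and writing the same recording twice yields byte-identical files.

## Processing

**Whole-foot curves.** Force is `0.1 · Σ p·a` per frame; contact area sums
cell areas with pressure strictly above a threshold (default 5 kPa, the
assumed sensor noise floor); peak pressure is the spatial maximum.

**Interpolation.** `pressure_interp()` interpolates each sensor linearly
on a uniform parameter over [0, 1]. Linear interpolation is
shape-preserving and cannot overshoot below zero, which a spline could.
Endpoints are preserved exactly, the sampling rate is rescaled so the
duration is unchanged, and event frames are rescaled proportionally. The
conventional target is 101 frames = 0–100% of stance in 1% steps. For
multi-step trials the pipeline interpolates per selected step, not per
trial, since percent-stance is a per-step notion.

**Step detection.** Steps are maximal runs of frames with total force at
or above a threshold (enter at ≥ threshold, leave at the first frame
below: one frame of hysteresis). Runs shorter than `min_duration` are
dropped, then the first `discard_first` runs (gait initiation), then an
explicit `keep` index list — the programmatic replacement for an
interactive keep/discard prompt, chosen so every behavior is a pure,
testable function. Defaults: 10 N and 0.15 s; both are documented knobs,
since no universal values exist. A threshold above the global force
maximum yields an empty event list with a warning, not an error.

**Footprint alignment and side detection.** The footprint (cells whose
max-over-time pressure exceeds 5 kPa) is aligned to the principal axis of
its pressure-weighted cell cloud; the toe-ward direction is resolved by
the travel of the COP from the first to the last meaningfully loaded
frame (frames above 5% of peak force — using all frames would let
noise-only frames at either end randomize the direction). The side
classifier then uses one anatomical fact: the bulk of forefoot load
(first metatarsal head and hallux) lies medially. Viewed from above with
toes pointing away, the medial side of a right foot is on the left, so
the sign of the mediolateral offset of the anterior-third pressure
centroid decides the side. Offsets below 5% of footprint width return
`"unknown"` with a diagnostic rather than a guess; the construction is
mirror-antisymmetric by design.

**COP.** The per-frame force-weighted centroid of cell centers. Frames
below a force threshold (or with no load) carry no COP point. By
construction every valid COP point lies in the convex hull of loaded
sensor centers — a property the tests verify on random frames.

## Masking

Masks are polygons (mm) or explicit sensor sets. Polygon masks resolve to
sensors through one of two coverage rules: `center_in` (cell center
inside or on the boundary of the polygon — the boundary counts as inside,
fixed as a convention) or `fraction_ge(f)` (overlap area of the mask
polygon with the cell's own polygon, divided by cell area, at least
`f`). Overlap areas are exact: the mask polygon is clipped against each
convex cell polygon with the Sutherland–Hodgman algorithm and the area
taken by the shoelace formula — no pixel sampling. `fraction_ge`
assignments are therefore monotone non-increasing in `f`, and assignments
are invariant under rigid motions applied to grid and polygon together.

The automatic 10-region barefoot mask aligns the footprint (as above),
measures foot length L along the axis, and splits:

* longitudinally at 0.30 L / 0.55 L / 0.82 L into heel, midfoot,
  forefoot, toes;
* the forefoot band mediolaterally (medial→lateral) into MTH1–MTH5 with
  width fractions 0.30 / 0.20 / 0.175 / 0.175 / 0.15 of the band's
  measured width;
* the toe band into hallux / toe2 / toes3–5 with fractions
  0.35 / 0.20 / 0.45.

These are literature-typical foot proportions; they are parameters of a
`masking_scheme` object, not constants, because any fixed fractions will
fail on some feet. Cells exactly on a split line go to the more posterior
(longitudinal) or more medial (mediolateral) region — a deterministic
tie-break that guarantees the 10 regions exactly partition the footprint,
which the tests assert cell-by-cell. Region masks are stored as sensor
sets. Template insole schemes (3-, 9- and 10-region) ship as editable CSV
tables over the bundled 99-sensor layout; the exact published schemes they
approximate are not reproduced here, so the tables are labelled
approximations.

## Metrics

All integrals use the trapezoidal rule with Δt = 1/f\_s, which is exact
for piecewise-linear series with knots on frames — in particular the FTI
of a constant force F over duration T is exactly F·T. Definitions:

* `press_peak_sensor`: max over assigned cells and frames.
* `press_peak_mean`: *temporal* mean of the *spatial* peak over contact
  frames (the name is deliberately explicit; "mean peak pressure" without
  qualification is ambiguous in the literature).
* `fti`: ∫ regional force dt.
* `pti_melai`: FTI / A. "The contact area of the region" admits readings;
  here A is the region's **peak** contact area over the step (cells above
  the activity threshold at the frame of maximum regional contact), which
  is deterministic and makes `pti_melai · A ≡ fti` an exact identity.
* `pti_peak`: ∫ (regional spatial peak pressure) dt, in kPa·s.
* `contact_time`: sum of Δt between consecutive loaded frames (for a
  contiguous run of n frames this is (n−1)·Δt, consistent with the
  trapezoid convention).

**CPEI.** After alignment, the construction line joins the first COP
point to the most medial COP point of the anterior third of the foot (the
medial-border tangent). The deviation is the perpendicular distance from
this line to the COP path where it crosses the anterior trisection
boundary (s = 2L/3, linearly interpolated between bracketing COP points),
signed positive for lateral deviation, and CPEI = 100 × deviation /
forefoot width, with the forefoot width measured as the mediolateral
extent of footprint cells in the 0.55–0.82 L band. The construction-line
convention has a known variant (first-to-last chord instead of the medial
tangent); both are implemented (`construction = "tangent"` / `"chord"`)
and the tangent is the default, without any claim about which variant
other software uses. CPEI is dimensionless, hence invariant under uniform
scaling, and invariant under rotation of the foot on the plate up to
re-rasterization error.

**DPLI.** The dynamic plantar loading index is defined here as `1 − R²`
of a least-squares fit of `a·exp(−(t−μ)²/2σ²)` to a peak-pressure time
series, clipped to [0, 1]. The fit uses Levenberg–Marquardt with moment
initialisation (a = max, μ = argmax, σ from the half-width at half
maximum), falling back to Nelder–Mead simplex minimisation of the same
least squares when LM degenerates. Two degenerate conventions are fixed:
an exactly constant series scores 0 (a constant is the σ→∞ limit of the
Gaussian), and an all-zero series is an error. The external literature
describes this index only qualitatively, so no numeric agreement with
prior publications is claimed; the test oracle is an independent
coarse-to-fine grid search over (a, μ, σ).

## Visualization

Values map to color bins with boundaries inclusive on the lower color:
with breaks (100, 200, 300), a value of 100 takes the first color, 101
the second, anything above 300 the last; zero lands in the first bin.
The default scale is an 8-bin approximation of conventional pressure-plot
palettes with breaks at 15/40/60/100/150/220/300 kPa — documented,
overridable defaults with no claim of visual parity with any vendor.
Rendering goes through an explicit palette-indexed raster (one pixel
block per sensor cell, overlays drawn as indexed lines), so identical
inputs give byte-identical PNGs and GIFs. The GIF encoder is a minimal
GIF89a writer using fixed-width literal LZW codes with periodic clear
codes; frame delays are in units of 10 ms, so the effective frame rate is
the nearest representable one.

## The synthetic generator

The generator is the package's ground-truth oracle. A `foot_model` places
ten anatomical sites (heel, a lateral arch contribution, MTH1–5, hallux,
toe2, toes3–5) as isotropic Gaussian pressure patches truncated at 2.2 σ
(compact contact patches with a sharp footprint edge), each with a
raised-cosine activation over its own onset/peak/offset fraction of
stance. Defaults describe a typical adult barefoot trial: foot length
250 mm, heel peak 400 kPa, MTH1 peak 450 kPa, hallux 350 kPa, heel active
from 0 to 58% of stance, forefoot from ~25% to ~97%, toes from ~45% to
toe-off; the overlap of heel decay and forefoot rise produces the classic
two-peak force curve. Site positions and patch widths were chosen, once,
so that each site's core (cells within 0.75 σ of its center) lies inside
the region a standard 10-region scheme assigns to it — i.e. the fixture
geometry is designed to be anatomically consistent with the masking
proportions, as a real foot is. Trial-to-trial variability is seeded
jitter: rotation ±4° around a 7° toe-out, ±3 mm translation, 5% site
amplitude. Sensor noise is additive zero-mean Gaussian per cell per
frame, truncated at zero, default σ = 0.5 kPa (a quiet capacitive
system). The default platform pitch is 2.5 mm; coarser grids than 2 cells
per site σ are rejected rather than aliased. Multi-step in-shoe trials
place a spread-and-attenuated variant of the same model (σ × 1.6, peaks
× 0.6 — an insole diffuses and damps pressure) on the bundled 99-sensor
layout, concatenating stance and swing phases; the ground truth here is
the exact contact window of every step.

What the generator does *not* emulate: subject-to-subject anatomical
variability, pathological loading patterns (claw toes, ulcerated offload,
partial foot), shear, hysteresis or saturation of real sensors, drift,
and crosstalk. Passing tests therefore demonstrate correctness of the
geometry and arithmetic under clean, plausible loading — not robustness
to every clinical footprint; the automask in particular inherits the
known fragility of simple geometric schemes on atypical feet.

## Problem sizes and numerical tolerances

The test suite and the acceptance script run on: single steps of 71
frames (0.7 s at 100 Hz) on ~110 × 55 grids at 2.5 mm pitch; 20 seeded
feet for mask-recovery and 50 for side-detection properties; 20
three-step in-shoe trials at 50 Hz; 100 random frames for COP hull
checks; 20 noisy curves for the DPLI oracle comparison. These sizes keep
the full suite around a minute on one CPU while exercising every code
path at realistic resolution. Exact identities (force conservation,
PTI·A = FTI, canonical round trip) are asserted at machine precision;
dialect round trips at the 8-significant-digit precision of their float
text; the planted CPEI construction at 10⁻⁶ relative; the DPLI
implementation against its grid-search oracle at 10⁻³ absolute.

## Known limitations

* Vendor-dialect support is intentionally strict and simplified; real
  exports from specific software versions may need conversion to the
  documented dialects or the canonical format.
* The automask is a purely geometric scheme; it does not register
  anatomical landmarks and can mis-partition atypical footprints.
* Multi-sensor large platforms capturing several steps, pressure
  gradients and statistical parametric mapping are out of scope.
* The Tekscan loader requires calibrated pressure exports; raw sensor
  units are rejected, and no calibration model is provided.
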