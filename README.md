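# pedobaR

Processing, analysis and visualization of biomechanical pressure
distribution data in R.

Pressure sensor arrays — rigid platforms for barefoot walking, instrumented
insoles for in-shoe measurement — produce dense space–time recordings of
the load under the foot. Almost all of this data is currently processed in
proprietary vendor software, which fragments formats across hardware
families and leaves the exact definition of reported variables ambiguous
(the literature contains at least two different quantities both called "the
pressure–time integral"). pedobaR is aimed at gait researchers and
clinician–scientists who want that pipeline to be open, scriptable and
reproducible: one standardized recording object, explicit and documented
variable definitions, and deterministic outputs.

## What it does

* **Import** simplified text export dialects of five hardware families —
  emed (`.lst`), pedar and pliance (`.asc`), Tekscan (`.asf`/`.csv`),
  footscan (spreadsheet-style) — into one `pressure_recording` object
  (frames in kPa, per-sensor geometry in mm/cm², sampling rate, events,
  masks), plus a versioned plain-text **canonical archive format** with a
  lossless, byte-deterministic round trip.
* **Process**: whole-foot force / peak-pressure / contact-area curves;
  force-threshold step detection for multi-step in-shoe trials; linear
  interpolation to percent-of-stance (101 frames); automatic left/right
  detection; center of pressure (COP).
* **Mask**: manual polygon or sensor-set regions with exact
  partial-coverage handling (center-in or overlap-fraction rules via
  polygon clipping); template insole schemes; an automatic 10-region
  barefoot mask (heel, midfoot, MTH1–5, hallux, toe2, toes3–5) that
  provably partitions the footprint.
* **Analyze**: regional peak pressure, force maxima, contact area/time,
  force–time integral, both pressure–time integrals, the center of
  pressure excursion index (CPEI), and the dynamic plantar loading index
  (DPLI).
* **Visualize**: color-binned footprint plots (PNG) with COP, outline and
  legend overlays, and GIF animations — all bit-deterministic.
* **Simulate**: a synthetic gait generator (`generate_footprint()`,
  `generate_multistep()`) with known ground truth, used by the test suite
  and usable for method development.

## The variables, precisely

For pressures `p` (kPa) on sensors of area `a` (cm²), with frames at
`Δt = 1/f_s`:

* Force: `F_t = 0.1 · Σ_cells p_t·a` (N).
* Peak pressure (sensor): `max_{cells, frames} p` per region.
* Force–time integral: `FTI = ∫ F dt` (trapezoidal; N·s).
* Pressure–time integral, Melai form: `PTI = FTI / A`, `A` = the region's
  peak contact area (N·s/cm²). The identity `PTI · A = FTI` holds exactly.
* Pressure–time integral, spatial-peak form: `∫ (max_cells p_t) dt`
  (kPa·s). The two PTIs are exposed as `pti_melai` and `pti_peak` — never a
  bare "PTI".
* CPEI: the footprint is aligned to its principal axis; a construction
  line runs from the first COP point to the most medial COP point of the
  anterior third of the foot; CPEI = 100 × (perpendicular deviation of the
  COP path from that line at the anterior trisection) / forefoot width.
* DPLI: `1 − R²` of a least-squares scaled-Gaussian fit to a
  peak-pressure-versus-time series, clipped to [0, 1]; 0 = perfectly
  normal-shaped loading.

## Worked example

```r
library(pedobaR)
# simulate a barefoot step and write it out as an emed-style export
sim <- generate_footprint(foot_model(side = "right", seed = 42))
write_fixture(sim$rec, "emed", "trial.lst")

rec <- load_emed("trial.lst")          # -> standardized recording
rec <- pressure_interp(rec, 101)       # -> percent-of-stance frames
rec <- create_mask_auto(rec, "automask_novel", foot_side = "auto")
rec
#> <pressure_recording> emed, side right
#>   101 frames @ 142.8571 Hz on a 107 x 56 grid (5992 active cells)
#>   masks: heel, midfoot, MTH1, MTH2, MTH3, MTH4, MTH5, hallux, toe2, toes3_5

head(mask_analysis(rec, c("press_peak_sensor", "fti", "pti_melai", "pti_peak")), 8)
#>   region            metric       value   units
#>     heel press_peak_sensor 417.4198560     kPa
#>     heel               fti  95.4643384     N*s
#>     heel         pti_melai   3.2292377 N*s/cm2
#>     heel          pti_peak  85.2120197   kPa*s
#>  midfoot press_peak_sensor  60.2620364     kPa
#>  midfoot               fti   9.2254874     N*s
#>  midfoot         pti_melai   0.5125271 N*s/cm2
#>  midfoot          pti_peak  13.6471594   kPa*s

cpei(rec)
#> CPEI: 10.74% (right foot, deviation 10.55 mm / forefoot width 98.19 mm)
```

The heel peaks at 417 kPa with an FTI of 95 N·s; dividing by the heel's
peak contact area (29.6 cm²) gives the Melai PTI of 3.23 N·s/cm². The CPEI
of ~11% is a typical mild lateral COP bow for a healthy foot shape.

DPLI is computed from a peak-pressure time series. The *whole-foot* curve
is two-phased (heel strike, then forefoot push-off), so it fits a Gaussian
poorly (`dpli ≈ 0.68` here); a single region loads smoothly and scores low:

```r
asg <- assign_sensors(rec$masks$heel, rec$grid)
heel_peak <- apply(rec$frames, 1, function(fr) max(fr[asg$cells]))
dpli(heel_peak)
#> [1] 0.013
```

A command-line wrapper with `convert`, `simulate`, `steps`, `interp`,
`mask`, `metrics`, `cpei`, `plot`, `animate` and `run` subcommands is
installed at `inst/cli/pedobar`.

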