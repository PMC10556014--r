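Package: pedobaR
Title: Loading, Processing and Analysis of Biomechanical Pressure
    Distribution Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for working with pressure sensor-array recordings such as
    plantar (foot) pressure measurements from platform and in-shoe systems.
    Reads simplified text export dialects from common hardware families
    (emed, pedar, pliance, Tekscan, footscan) into one standardized recording
    object, archives it in an open versioned text format, and provides step
    detection, temporal interpolation to percent-stance, center-of-pressure
    computation, automatic left/right detection, manual and automatic
    regional masking of the footprint, regional pressure variables (peak
    pressure, force-time integral, two pressure-time integral definitions,
    contact area and time), the center-of-pressure excursion index (CPEI),
    the dynamic plantar loading index (DPLI), footprint plots with
    configurable color binning, GIF animation export, and a synthetic gait
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    minpack.lm,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
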