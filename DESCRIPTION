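Package: ledstim
Title: Programming and Physical Simulation of LED-Matrix Optogenetic Illumination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Desk-scale toolchain for RGB LED-matrix illumination devices used
    in optogenetic cell stimulation. Parses and validates CSV illumination
    programs, resolves multiwell-plate keywords (wells, rows, columns, plates,
    rectangles, circles) to LED coordinates on a 32x64, 3 mm-pitch matrix,
    compiles programs into deterministic 1 Hz frame timelines, emulates
    device-side operator interactions (messages, countdowns, buzzer), and
    simulates the physical outcome of any program: sample-plane irradiance
    under a generalized-Lambertian emitter model, illumination homogeneity,
    spillover into neighbouring wells, per-well cumulative light dose, and a
    first-order estimate of medium heating. Includes seeded program generators,
    packaged stimulation protocols, and a command-line front end.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
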