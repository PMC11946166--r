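Package: opusnirs
Title: Concert fNIRS Hyperscanning: Preprocessing, Short-Channel
    Correction, and Cortical Source Dissection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for dual-subject (hyperscanning) continuous-wave
    functional near-infrared spectroscopy recorded during naturalistic
    performances such as public concerts. Reads and writes SNIRF files,
    aligns two performers' recordings via shared event labels, converts raw
    intensities to optical-density and hemoglobin-concentration changes
    through the modified Beer-Lambert law, applies averaged short-separation
    channel subtraction with negative zeroing, segments recordings into
    whole-piece, piece-onset, and mid-piece analysis windows, estimates
    cortical sources on a template mesh via a diffusion-approximation forward
    model and a depth-weighted minimum-norm inverse, and summarizes region-of-
    interest trajectories across concerts with Student-t confidence intervals.
    Includes a synthetic concert-session generator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    rhdf5,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
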