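Package: dsmotion
Title: Population Coding of Complex Texture Motion by Direction-Selective Retinal Ganglion Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of how populations of direction-selective
    retinal ganglion cells encode the motion of complex textures. Provides
    bit-reproducible stimulus generators (smoothed white-noise and pink-noise
    textures, two-dimensional random-walk motion trajectories, drifting
    gratings, checkerboard white noise, flashes and flicker), linear-nonlinear
    Poisson model cells with monotonic or U-shaped nonlinearities, motion
    spike-triggered averages with shuffle-based significance testing,
    spike-triggered covariance analysis, the optimal linear multi-cell decoder
    with chronological train/test splitting, a spectral lower bound on the
    mutual information between stimulus and reconstruction, synergy and
    redundancy information ratios, canonical correlation analysis of
    stimulus-response segments, and subtractive/additive reduced population
    codes, together with experiment drivers that run the pipeline end-to-end
    on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
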