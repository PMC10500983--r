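Package: emgrid
Title: Electrode Grid Design for High-Density Surface EMG Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for designing surface
    electromyography (EMG) electrode grids for motor-unit identification.
    Generates anatomical motor-unit pools in a layered cylindrical muscle
    volume, computes surface motor-unit action potentials with an analytic
    line-source volume conductor, quantifies how many motor units are
    theoretically discriminable for any grid size and interelectrode
    distance, synthesizes high-density EMG with ground-truth spike trains,
    decomposes multichannel EMG into motor-unit pulse trains by convolutive
    blind source separation (log-cosh fixed-point with deflation), and
    computes post-decomposition metrics: recruitment classification,
    spike-triggered averaging, adjacent-electrode correlation, normalized
    unit counts and weighted logarithmic trend fits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
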