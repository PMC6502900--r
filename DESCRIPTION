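Package: civmtrace
Title: Ridge Tracing and Relative Quantification for Continuous in vivo NMR Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing continuous in vivo metabolism NMR (CIVM-NMR)
    experiments: repeated 1D 1H spectra acquired on a living sample in an
    HR-MAS rotor over hours. Provides reading of Bruker acqus metadata and
    NMRPipe-style 1D frequency-domain spectra, assembly into a spectral time
    series, the post-acquisition processing chain (DSS referencing, spectral
    trimming, water-region zeroing, time truncation, DSS normalisation, block
    summation), semi-automated ridge tracing of drifting resonances (Gaussian
    smoothing, peak picking, weighted single-linkage clustering, gap
    interpolation, remapping onto raw data), compositing of multi-peak
    compound trajectories, chemical-shift based pH estimation from a citrate
    titration curve, mirror and ridge-overlay plots, and a synthetic spectral
    series generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
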