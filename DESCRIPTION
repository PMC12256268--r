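Package: gatelog
Title: Log File-Based Quality Assurance for Respiratory-Gated Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for temporal quality assurance of respiratory gating on
    medical linear accelerators from treatment log files. Reads time-stamped
    gating logs (respiratory surrogate motion plus beam on/off flags),
    conditions the anterior-posterior respiratory signal (min-max
    normalization, centred moving-mean smoothing), segments it into
    respiratory cycles, computes 25%/75% phase-crossing times per cycle, and
    pairs them with beam trigger edges to quantify per-cycle gating latency.
    Independent beam-timing verification from portal-imager (EPID) cine frame
    stacks via ROI intensity thresholding, ion-chamber dose comparisons
    between gated and non-gated delivery, multi-session reproducibility
    trending, tolerance evaluation, and a synthetic motion-phantom simulator
    with injectable beam latencies for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
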