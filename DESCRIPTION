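Package: echoshift
Title: Echo-Shift Modeling for Asymmetric Spin-Echo EPI and qBOLD
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the effect of in-plane macroscopic magnetic field gradients
    on asymmetric spin-echo (ASE) images acquired with an echo-planar imaging
    (EPI) readout. Provides the static-dephasing qBOLD signal kernel, the
    echo-shift signal model with an effective spin-echo offset, closed-form
    apparent qBOLD parameters, a log-linear qBOLD fitter, a complex k-space
    phantom that emulates per-voxel echo displacement, the simulated-signal-
    dropout estimator of the effective offset from complex image data, and the
    phase-encode-reversal regression analysis (Theil-Sen) together with
    mitigation operators (R2 correction factor, geometric-mean combination,
    RMS y-shim combination).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
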