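Package: xetof
Title: Hyperpolarized Xenon-129 Time-of-Flight Perfusion Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction tools for hyperpolarized xenon-129
    time-of-flight (TOF) depolarization-recovery MRI of tissue perfusion. The
    package implements a one-compartment tracer-kinetic model of dissolved
    xenon wash-in after saturation, its short-time linearization, digital
    brain and tube flow phantoms with a forward gradient-echo k-space
    acquisition model (flip-angle depletion of the hyperpolarized
    magnetization, complex noise), k-space zero-padding and Fourier magnitude
    reconstruction, SNR mapping, pixel-wise slope fitting, slope-to-perfusion
    conversion, and hemodynamic-response mapping by task-minus-baseline
    subtraction. Dynamic image series and parametric maps are exchanged as
    NIfTI volumes with JSON sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    rlang,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
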