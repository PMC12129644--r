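Package: soludiff
Title: Micellar Solubilization Analysis from Pulsed-Field-Gradient NMR
    Diffusion Decays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying micellar solubilization of small
    organic molecules by surfactants from pulsed-field-gradient
    stimulated-echo NMR diffusion measurements. Provides the
    stimulated-echo attenuation model, mono- and bi-exponential
    diffusion-decay fitting with the window strategies used for
    surfactant methylene signals, a two-state fast-exchange analysis
    yielding the micelle-bound fraction, micelle-water partition
    coefficient and molar solubilization ratio, breakpoint estimation
    of the critical micelle concentration from diffusion-concentration
    curves, and a seeded synthetic decay generator emulating
    rhamnolipid/phenol systems for validation without spectrometer
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
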