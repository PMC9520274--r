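Package: sonopore
Title: Microbubble Cavitation Dynamics and Sonoporation Dose-Response
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for modelling low-frequency microbubble-mediated
    sonoporation as a drug-delivery platform. Simulates the radial
    dynamics of lipid-shelled microbubbles with the Marmottant modified
    Rayleigh-Plesset model (piecewise buckled/elastic/ruptured shell
    surface tension, shell viscosity, acoustic radiation damping),
    sweeps expansion ratio against peak negative pressure, classifies
    stable versus inertial cavitation and locates regime boundaries.
    Companion modules compute targeted-microbubble ligand budgets,
    quantify fluorescent-cell fractions from two-channel microscopy
    frames by connected-component counting, analyse uptake and
    viability dose-response tables with one-way ANOVA and Tukey
    multiple comparisons, and generate synthetic replicate tables and
    microscopy frames with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    EBImage,
    jsonlite,
    stats,
    tiff,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
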