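Package: tkrfem
Title: Subject-Specific Total Knee Replacement Finite-Element Model Building
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A semi-automatic pipeline for building total knee replacement
    (TKR) finite-element models and studying the sensitivity of tibiofemoral
    contact pressures to modeling choices. Provides triangulated-surface and
    tetrahedral mesh types with STL input/output and validity checks, a
    parametric synthetic implant geometry generator, Blankevoort tension-only
    nonlinear ligament springs with zero-load-length calibration, compressible
    neo-Hookean constitutive math for the implant materials, gait
    boundary-condition ingestion and synthesis (OpenSim motion/storage tables,
    zero-phase Butterworth filtering, parameterized stance-phase waveforms),
    automated FEBio-format solver file generation, a reduced-order
    elastic-foundation contact solver producing contact pressures, forces and
    centers of pressure over a gait cycle, and the perturbation-grid driver
    and relative-variation metrics used for ligament and implant-malalignment
    sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
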