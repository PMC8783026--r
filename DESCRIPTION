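Package: tbleis
Title: Predicting Impedance Spectra of Tethered Bilayer Membranes from
    AFM Defect Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating atomic force microscopy (AFM) maps of
    pore-forming-toxin defects in tethered bilayer lipid membranes (tBLMs)
    to their electrochemical impedance spectroscopy (EIS) response.
    Provides defect-set containers with a Voronoi-tessellation clustering
    statistic, bounding-box IoU evaluation of defect detection accuracy
    (precision, recall, F1, density ratio), kernel-density-guided synthesis
    of degraded detector outputs, a finite-element solver for the
    submembrane thin-film potential problem that predicts complex
    admittance spectra from defect coordinates, Bode phase-minimum feature
    extraction, and grid-search recovery of the electrochemical defect
    radius and submembrane specific resistance from reference spectra.
    Includes generators for synthetic defect point patterns, AFM-like
    topography images and noisy reference spectra, so the full workflow
    runs without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deldir,
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    ggplot2
Config/testthat/edition: 3
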