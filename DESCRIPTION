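Package: memfluor
Title: Membrane Biophysics Readouts from Ratiometric Fluorescence Cytometry and Imaging
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification workflows for fluorescence-based membrane biophysics:
    per-cell emission ratiometry of ESIPT (dual-band 3-hydroxyflavone) probes for
    the membrane dipole potential in flow cytometry, excitation-band ratiometry of
    electrochromic styryl dyes in spectrofluorometry, steady-state fluorescence
    anisotropy in the L-format (membrane fluidity), generalized polarization
    imaging with manually seeded watershed segmentation of the plasma membrane
    (membrane hydration), and time-correlated analysis of dual-labelled
    cell-penetrating peptide uptake with a two-compartment uptake/escape kinetic
    model. Includes event-level cytometry input/output (FCS and CSV), spectral
    compensation, gating, viability quadrant statistics, one-way ANOVA with
    Tukey's HSD, and a fully seeded synthetic-data generator producing cytometry
    events, excitation spectra, polarized intensity reads, kinetic event streams
    and two-channel membrane images with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tiff,
    pracma,
    minpack.lm,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
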