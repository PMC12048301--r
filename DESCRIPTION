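Package: vftrig
Title: Trigger and Substrate Analysis for Spontaneous Ventricular
    Fibrillation in Cardiac Optical Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for spontaneous ventricular fibrillation (VF)
    triggers in cardiac optical mapping experiments with a localized
    repolarization heterogeneity. Extracts activation-time, APD80 and
    repolarization-time maps with validity masks from fluorescence movies,
    quantifies local repolarization gradients (ms/mm), delineates the
    short-repolarization region and its border zone, detects premature
    ventricular complexes and VF episodes on a pseudo-ECG (coupling
    intervals, R-on-T, sustained/spontaneous classification), localizes
    trigger origins and classifies early VF cycles by phase mapping
    (breakthroughs versus rotors), and reproduces the associated statistical
    battery. Includes a synthetic-preparation generator: a two-variable
    monodomain reaction-diffusion simulation with a calibrated localized
    APD-shortening lesion, a fluorescence acquisition model, a
    volume-conductor pseudo-ECG forward model, and full ground truth for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    stats,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
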