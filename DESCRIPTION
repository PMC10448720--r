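Package: ketox
Title: Key-Event Pathway Modeling of Chemical Hepatotoxicity from
    High-Throughput Screening Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs concentration-response curves from high-throughput
    screening (HTS) curve-fit parameters, selects toxicity-associated assays
    by Fisher's exact test with Benjamini-Hochberg false-discovery-rate
    control, composes assays into key-event (KE) curves and scaled KE scores,
    overlays toxicokinetic steady-state plasma concentrations to estimate the
    bioavailable fraction of in vitro activity, clusters chemicals by
    structural fingerprints with the Butina sphere-exclusion algorithm, and
    fits leave-one-out-validated logistic models of in vivo hepatotoxicity
    from KE scores with and without bioavailability descriptors. Includes a
    synthetic data generator with known ground truth so the entire pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on
    the PATH (used for SMILES canonicalization, Morgan fingerprints and
    Lipinski descriptors)
Config/testthat/edition: 3
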