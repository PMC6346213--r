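Package: coelute
Title: Complex-Centric Detection of Protein Co-Elution in Co-Fractionation
    Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and error-controls protein co-elution signals in
    protein-level size-exclusion chromatography (SEC) elution profiles from
    quantitative co-fractionation mass spectrometry (SEC-SWATH/DIA).
    Implements import of long-format peptide quantification tables to dense
    elution-trace matrices, SEC-informed peptide filtering with decoy-based
    protein-level FDR control, top-N protein quantification, log-linear
    molecular-weight calibration, complex-query generation from complex
    tables and interaction networks with network-aware decoy queries,
    sliding-window correlation-based co-elution feature detection,
    target-decoy scoring with Storey pi0/q-value estimation, parameter grid
    search, feature collapsing across query sets, complex-variant
    extraction, stoichiometry estimation, assembled-state mass accounting,
    two-component Gaussian peak deconvolution, benchmarking utilities, and
    a ground-truthed synthetic-data generator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
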