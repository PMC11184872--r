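Package: pbsmdr
Title: Voxel-Wise Maximum Dose-Rate Analysis for Pencil-Beam-Scanned Proton Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes instantaneous dose-rate metrics for pencil-beam-scanned
    (PBS) proton therapy plans. Each spot's dose and dose-averaged linear
    energy transfer (LET) are computed on a voxel grid with a pluggable
    analytic pencil-beam engine, spot delivery times are read from (or
    synthesized as) machine log files, and the two are combined into
    voxel-wise maximum dose-rate (MDR) maps at plan and field level.
    Structure-level near-maximum metrics (D2, LET2, MDR2, variable-RBE D2
    via the McNamara phenomenological model) and cumulative dose above a
    dose-rate threshold are reported per case, per field and per organ at
    risk. A synthetic-cohort generator emulates an intracranial cohort with
    planted high-dose-rate fields so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
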