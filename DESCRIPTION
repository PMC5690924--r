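Package: sbrteval
Title: Dosimetric Evaluation of Lung SBRT Plans Against RTOG 0915 Criteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dose-volume histogram (DVH) analysis and protocol
    compliance evaluation of stereotactic body radiotherapy (SBRT) treatment
    plans for peripheral lung tumours. Computes the RTOG 0915 high- and
    intermediate-dose spillage metrics (conformity index R100%, R50%, D2cm,
    normal-lung V20) with planning-target-volume-dependent compliance bands,
    organ-at-risk and rib dose documentation (fixed-volume DVH doses, maximum
    point dose, 3D isocenter-to-rib distance), linear-quadratic biologically
    effective dose (BED), and cohort-level summaries and deviation counts.
    Includes a portable plan file format, a synthetic lung-SBRT dose-phantom
    generator with analytic ground truth for validation, and an embedded
    20-patient reference cohort of published per-patient metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
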