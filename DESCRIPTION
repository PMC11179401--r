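Package: trialemulate
Title: Clinical Trial Emulation from Longitudinal Ophthalmology Registry Data
Version: 0.1.0
Authors@R:
    person("Registry", "Methods Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs external comparator (pro re nata anti-VEGF) treatment
    arms from longitudinal electronic-health-record style registry event
    tables via a rule-based eligibility attrition engine, and aligns them to
    monthly clinical-trial arms by 1:1 caliper matching (maximum-cardinality
    bipartite matching) and by inverse propensity score weighting with ATT
    odds weights. Includes Snellen to approximated-ETDRS visual acuity
    conversion, per-arm outcome summaries (visual acuity change, 15-letter
    responder proportions, injection counts, drug cost, endophthalmitis
    incidence), unpaired t-tests from raw samples or summary statistics, and
    a synthetic registry/trial generator with ground-truth manifests so the
    whole pipeline is testable without access to proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
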