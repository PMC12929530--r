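Package: allocsim
Title: Simulation of Molecular Mismatch-Guided Deceased-Donor Kidney Allocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discrete allocation simulation for deceased-donor kidney
    transplantation under ABO-identical matching. Generates synthetic
    donor and candidate cohorts from a haplotype pool, scores
    donor-recipient pairs with a pluggable peptide-based molecular
    mismatch scorer (a seed-free surrogate for PIRCHE-II-style epitope
    counts, or a precomputed score matrix), runs a greedy lowest-score
    allocation engine with constant-size waitlist replenishment, and
    provides post-simulation analytics: score distribution summaries,
    risk-stratum probability curves against waitlist size, baseline
    versus deliberate patient-flow accounting, and hard-to-match
    candidate detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
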