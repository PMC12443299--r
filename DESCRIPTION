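Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pharmacovigilance signal-detection pipeline for FAERS-style
    spontaneous adverse-event report databases. Reads quarterly
    dollar-delimited DEMO/DRUG/REAC/OUTC tables, deduplicates case versions
    (keeping the latest report), normalizes free-text drug names against a
    synonym dictionary, builds 2x2 drug-event contingency tables at the
    MedDRA Preferred Term and System Organ Class level, and computes the
    reporting odds ratio (ROR), proportional reporting ratio (PRR), Pearson
    chi-squared, the Bayesian confidence propagation neural network (BCPNN)
    information component, and the empirical Bayes geometric mean (EBGM)
    relative reporting ratio with their interval bounds. A drug-event pair
    is flagged as a signal only when all four algorithms meet their
    thresholds. Includes a synthetic spontaneous-report generator with known
    ground truth for validating operating characteristics, and a solver that
    reconstructs full 2x2 tables from published summary rows so printed
    signal tables act as executable checks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
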