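Package: inversig
Title: Inverse-Signal Drug Repositioning from Adverse-Event Reports and
    Expression Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for signature-reversion drug repositioning driven by
    pharmacovigilance inverse signals.  Computes disproportionality
    statistics (reporting odds ratio, Bayesian information component,
    and the empirical Bayes geometric mean under a two-component
    gamma-Poisson mixture) from spontaneous adverse-event reports,
    builds a disease gene-expression signature by moderated-t
    fixed-effect meta-analysis across studies, scores compound rank
    signatures for reversal of that signature (RGES/sRGES), identifies
    reversal genes by leave-one-compound-out cross-validation, and
    validates candidate compounds against IC50 potency data.  Includes
    a synthetic-data generator that emulates all five input classes
    with known ground truth, so the full pipeline runs end-to-end
    without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
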