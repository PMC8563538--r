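Package: colocmr
Title: Colocalisation-Gated Cis Mendelian Randomisation from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for drug-target genetic-evidence analyses built on GWAS
    summary statistics: Bayesian colocalisation of two traits' association
    signals in a gene region via single-variant approximate Bayes factors
    (five-hypothesis posterior, with a conditional re-run that masks the
    outcome's lead signal), selection of cis and genome-wide instruments with
    p-value, direction-concordance, LD-clumping and pleiotropy filters,
    Wald-ratio and random-effects inverse-variance-weighted Mendelian
    randomisation expressed per halving of disease odds, and a z-test contrast
    of cis against genome-wide estimates. Includes a seeded generator of GWAS
    summary statistics under autoregressive linkage disequilibrium so the full
    pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
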