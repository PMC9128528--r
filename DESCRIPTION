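Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end two-sample Mendelian randomization for GWAS summary
    statistics: instrument selection (genome-wide significance filtering, LD
    clumping, proxy substitution, pleiotropy and confounder exclusion), allele
    harmonization with palindromic-variant handling, a suite of causal-effect
    estimators (Wald ratio, inverse-variance weighted with multiplicative
    random effects, weighted median, MR-Egger, and constrained maximum
    likelihood with BIC model averaging), sensitivity diagnostics (Cochran's Q,
    MR-PRESSO, leave-one-out, funnel and scatter data), instrument-strength and
    power metrics, bidirectional analysis, and a synthetic summary-statistics
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
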