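Package: mrlink
Title: Two-Sample and Multivariable Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) workflow for
    genome-wide association study (GWAS) summary statistics: instrument
    selection by p-value thresholding with greedy linkage-disequilibrium
    clumping and proxy substitution, allele harmonization with palindromic
    variant handling, univariable causal estimators (inverse-variance
    weighted, MR-Egger with SIMEX dilution correction, weighted median,
    weighted mode, robust adjusted profile score) with instrument-strength
    and heterogeneity diagnostics and Steiger directionality filtering,
    multivariable MR with conditional F statistics and weak-instrument-robust
    Q-minimization, and conversion of raw coefficients to liability-scale
    interpretation units (effects per doubling of liability, months or days
    of education, odds ratios). Includes a seeded synthetic summary-statistic
    generator so every pipeline stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
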