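Package: mrkit
Title: Two-Sample Mendelian Randomization with Mediation, Bayesian Model
    Averaging and LD-Score Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summary-statistic Mendelian randomization toolkit for
    microbiome-metabolite-disease studies. Implements instrument selection
    (p-value and allele-frequency filters, greedy LD clumping, proxy lookup,
    allele harmonization, F-statistic and Steiger directionality filtering),
    univariable two-sample estimators (inverse-variance weighted, MR-Egger,
    weighted median, robust adjusted profile score, constrained maximum
    likelihood with model averaging) with Cochran's Q heterogeneity and
    MR-PRESSO outlier diagnostics, multivariable MR via Bayesian model
    averaging with permutation p-values, two-step mediation with delta-method
    standard errors, hypergeometric metabolite-set over-representation,
    bivariate LD-score regression, and a synthetic GWAS generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
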