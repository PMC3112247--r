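Package: genoaudit
Title: Genotyping-Error Audits and Mixed-Model Error Rates for
    Microsatellite DNA Registers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to audit genotyping quality in individual-based
    microsatellite DNA registers. Compares register profiles against
    re-genotyped reference profiles, classifies discrepancies (false allele
    sizes, false homozygotes, false heterozygotes), and estimates per-locus
    and per-allele error rates with binomial standard deviations. Fits
    logistic mixed models for the error probability by maximum likelihood
    with adaptive Gauss-Hermite quadrature, ranks candidate models by AIC
    and Akaike weights, computes population-averaged per-locus and
    multilocus (profile-mismatch) error probabilities by Monte Carlo
    integration over the random effects, and attaches cluster-bootstrap
    standard errors. Includes a synthetic register generator emulating the
    sampling design of the Norwegian minke whale DNA register.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
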