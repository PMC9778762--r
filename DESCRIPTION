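Package: dnaos
Title: Open-State Dynamics of Torsional DNA Models under Single Deuterium
    Substitution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained angular (Yakushevich-type) dynamics of a
    double-stranded DNA molecule with a hydrogen-bond break/restore
    automaton, used to study how single 2H/1H (deuterium) substitutions
    change the probability of base-pair open states in the highest
    critical-energy range. Provides a deterministic fixed-step RK4
    integrator over the 2n coupled torsional equations of motion, a
    per-site substitution scanner for open-state probabilities, the
    modified Basov-Jimack site classification including the weighted
    closed-state (CSNB) correction, the accompanying statistical toolkit
    (Yates-corrected chi-squared, r x 2 chi-squared with Bonferroni
    adjustment, Kruskal-Wallis, two Spearman rank-correlation variants),
    a seeded synthetic-sequence generator with exact per-part base
    composition, and packaged reference tables with the derived ratio and
    correlation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    seqinr,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
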