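Package: scadmr
Title: Proteome- and Transcriptome-Wide Cis-Mendelian Randomization and
    Bayesian Colocalization for Spontaneous Coronary Artery Dissection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a discovery pipeline for a binary disease outcome
    (spontaneous coronary artery dissection) from GWAS summary statistics:
    cis instrument selection for circulating proteins and tissue transcripts
    with F-statistic screening and LD clumping, exposure-outcome allele
    harmonization with palindromic-variant handling, two-sample Mendelian
    randomization (Wald ratio, inverse-variance weighted, MR-Egger, weighted
    median) with Benjamini-Hochberg false-discovery-rate control, Bayesian
    colocalization under the five-hypothesis single-causal-variant
    enumeration using Wakefield approximate Bayes factors, cross-platform
    and cross-tissue evidence triangulation, and case-control differential
    protein expression statistics for a mass-spectrometry validation cohort.
    A synthetic summary-statistics generator reproduces the statistical
    structure the analysis assumes so the whole pipeline runs at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
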