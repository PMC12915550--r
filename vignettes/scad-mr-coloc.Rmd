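---
title: "Methods: cis-MR and Bayesian colocalization for a rare binary outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cis-MR and Bayesian colocalization for a rare binary outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scadmr)
```

## The scientific problem

Spontaneous coronary artery dissection (SCAD) is a rare cause of myocardial
infarction, concentrated in younger women, with poorly understood biology
and no disease-specific therapy. Because recruiting trial-scale cohorts is
impractical for a rare disease, genetic proxies are attractive: if variants
that raise circulating levels of a protein also shift SCAD risk, that
protein is a candidate causal factor and a potential drug target.

`scadmr` implements that discovery pipeline over GWAS summary statistics:

1. select *cis* genetic instruments for each circulating protein (or tissue
   transcript) and screen their strength;
2. harmonize exposure and outcome associations to a common effect allele;
3. estimate the causal effect of each exposure on the binary outcome by
   two-sample Mendelian randomization (MR), with false-discovery-rate
   control across the proteome;
4. test whether exposure and outcome share a causal variant by Bayesian
   colocalization;
5. triangulate evidence across proteomic platforms and expression tissues;
6. validate candidates in a case-control proteomics cohort.

Because the consortium datasets behind such analyses cannot be
redistributed, the package ships a synthetic summary-statistics generator
with the same statistical structure, so every stage runs and is validated
at desk scale.

## Instruments and their strength

An instrument for protein $P$ is a variant inside the encoding gene's body
extended by a flank (default $\pm$1 Mb, the *cis* convention of the large
pQTL studies; configurable) whose association with $P$ reaches
$p \le 5\times10^{-8}$ and whose F statistic $(\hat\beta/\mathrm{se})^2$ is
at least 10. Restricting to *cis* variants reduces the risk of horizontal
pleiotropy; the F screen excludes weak instruments by construction.
Independence among instruments is enforced by greedy LD clumping at
$r^2 \le 0.01$ against a user-supplied regional correlation matrix; when no
LD information is available, only the single lowest-p variant is used,
because independence cannot be verified. No proxy variants are substituted
for instruments missing from the outcome GWAS: proxies would add instruments
at the cost of selection stringency, and the availability loss is reported
instead (the scan log and manifest count traits "not available for
analysis").

## Harmonization

Exposure and outcome records are aligned to a common effect allele:
matching alleles are kept, swapped alleles flip the outcome beta and
complement its frequency, and strand flips are resolved by reverse
complement. Palindromic variants (A/T, C/G) cannot be strand-resolved from
letters; by default they are aligned by allele-frequency concordance and
dropped when either frequency lies within 0.08 of 0.5 (minor-allele
frequency above 0.42) or is missing. The 0.08 window is standard two-sample
MR practice; both the policy and the window are configurable since the
underlying analyses rarely state their rule. Indels are matched by exact
string equality or swap only — reverse complement is ill-defined for
length-mismatched alleles.

Two properties pin the implementation down and are enforced by tests:
harmonization is an involution (re-harmonizing aligned data is a no-op) and
downstream estimates are invariant to how the outcome file happened to
orient its alleles.

## MR estimators

With a single instrument the causal estimate is the Wald ratio
$\hat\theta = \hat\beta_{Y}/\hat\beta_{X}$, with the two-term delta-method
standard error
$$\mathrm{se}(\hat\theta) = \sqrt{\frac{\mathrm{se}_Y^2}{\hat\beta_X^2} +
\frac{\hat\beta_Y^2\,\mathrm{se}_X^2}{\hat\beta_X^4}},$$
which, unlike $\mathrm{se}_Y/|\hat\beta_X|$, does not ignore exposure
uncertainty and is mildly conservative at moderate instrument strength (a
one-term switch is provided). With $k \ge 2$ instruments the
inverse-variance-weighted (IVW) estimate averages the per-instrument
ratios with weights $w_j = \hat\beta_{X,j}^2/\mathrm{se}_{Y,j}^2$;
the multiplicative random-effects model (default for $k \ge 2$) scales the
fixed-effect standard error by $\sqrt{\max(1, Q/(k-1))}$, Cochran's $Q$
absorbing heterogeneity. Wald and IVW p-values use the two-sided normal
reference, the summary-statistic convention. Estimates are log odds of the
outcome per SD of protein level, reported alongside
$\mathrm{OR} = e^{\hat\theta}$ with 95% CI $e^{\hat\theta \pm 1.96\,
\mathrm{se}}$.

Sensitivity estimators require at least 3 instruments: MR-Egger (weighted
regression with a free intercept estimating average directional pleiotropy,
after orienting exposure effects nonnegative; t reference with $k-2$ df)
and the weighted median (the ratio at which the cumulative standardized
inverse-variance weight crosses 0.5, linearly interpolated; standard error
by seeded parametric bootstrap, default 2000 replicates). Below 3
instruments both return a structured `not_estimable` value rather than an
error, so a proteome-wide scan never aborts on sparse instruments — sparse
exposures are a reported outcome of the scan, not a failure.

Discovery is controlled by Benjamini-Hochberg adjustment at $q < 0.05$,
applied within each platform/tissue separately by default (matching
per-dataset reporting; a pooled universe is a config switch).

## Colocalization

A significant MR signal can still be driven by two distinct causal variants
in LD. For each trait region the package computes Wakefield approximate
Bayes factors per variant,
$$\log\mathrm{ABF} = \tfrac12\left[\log(1-r) + r z^2\right],\qquad
r = \frac{W}{W + \mathrm{se}^2},\; z = \hat\beta/\mathrm{se},$$
with prior effect variance $W = 0.15^2$ for quantitative traits and $0.2^2$
for binary (log-odds) traits, and enumerates the single-causal-variant
configurations of the two traits: H0 (neither causal), H1/H2 (one trait
only), H3 (both, distinct variants), H4 (both, shared variant), with
per-variant priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ (field-standard
defaults; configurable and echoed in output). All aggregation is done in
log space with log-sum-exp, so posteriors remain finite for $|z|$ of 100
and sum to one within $10^{-10}$; a single-variant region has exactly zero
H3 mass. Tests verify the whole enumeration against a brute-force oracle
over all configuration pairs on small regions.

Two summaries are reported: PP.H4, with "colocalization support" declared
at PP.H4 $\ge 0.8$ (configurable), and the conditional metric
PP.H4/(PP.H3+PP.H4) — the posterior share of colocalization among
configurations where both traits are causal, useful when regional power for
the small outcome GWAS leaves most mass on H0-H2.

The colocalization region is the same *cis* window used for instrument
selection (all variants, no p filter). The underlying analyses describe the
region only as the protein-coding locus; using one window for both stages
keeps the two evidence streams comparable and is documented as the
package's choice.

## Triangulation

The evidence matrix holds one cell per (trait, dataset): estimate sign,
BH-adjusted p with significance stars (0.05/0.01/0.001), and colocalization
posteriors, with explicitly marked unavailable cells. Directional
consistency across datasets requires a shared strict sign among estimable
estimates (an exact zero is inconsistent) and is assessed separately from
significance. eQTL corroboration of a protein requires both FDR
significance in that tissue and sign consistency with the protein-level
estimate. Support tiers are an interpretive layer the package defines
(the source analyses rank narratively): T1 = MR-significant in at least one
platform + colocalization support + eQTL corroboration; T2 =
MR-significant + exactly one corroboration; T3 = MR-significant only;
traits significant nowhere are excluded. The tiering is a pure function of
the result tables and is fully configurable.

## Validation statistics

The case-control proteomics module log2-transforms intensities (zeros
treated as missing by default, the usual MS convention; a pseudo-intensity
path exists), requires detection in at least half the samples of each group
(configurable), and tests case vs control means by Welch's t-test —
the source analyses do not state their test, and the unequal-variance form
is the safer default (pooled is a switch). The effect size is
$\log_2\mathrm{FC} = \overline{\log_2 x}_{\mathrm{case}} -
\overline{\log_2 x}_{\mathrm{control}}$, BH-adjusted across tested
proteins. Baseline clinical covariates are compared by Welch's t (continuous)
and Pearson's chi-square without continuity correction (categorical): the
uncorrected chi-square is the only variant that reproduces the published
baseline-table p-value recoverable from its counts (diabetes 2/50 vs 0/50
gives $\chi^2_1 = 2.04$, $p = 0.153$), which the test suite asserts to
three decimals.

## The synthetic generator

Regional summary statistics are drawn directly from the sampling
distribution of marginal GWAS estimates: with AR(1) LD
$R_{ij} = \rho^{|i-j|}$ (default $\rho = 0.9$) and a causal-effect vector
$\gamma$ (nonzero only at the causal index), the estimates are
$\hat\beta \sim \mathcal{N}(R\gamma,\; D R D)$ with
$D = \mathrm{diag}\,\mathrm{se}$ and
$\mathrm{se}_j^2 = 1/(2 n\, \mathrm{maf}_j(1-\mathrm{maf}_j))$, inflated by
$1/(\phi(1-\phi))$ for a binary trait with case fraction $\phi$. No
individual-level genotypes are simulated; the MVN draw is exactly the
object the pipeline consumes and is orders of magnitude faster. Defaults:
500 variants, $n = 20\,000$ per trait, minor-allele frequencies uniform on
(0.05, 0.5), causal effect 0.15 per allele — sized so the causal variant's
expected $|z|$ sits in the 9-21 range across that frequency span, the
regime where colocalization should (and does) separate shared from
distinct causal variants.

MR studies are simulated as independent instruments with true exposure
effects sized to a target F band (default 80-120), outcome effects
$\beta_{\mathrm{true}}\beta_X$ plus optional pleiotropic intercepts, and
outcome standard errors matching an 11209-sample GWAS with case fraction
1917/11209 — the information content of the real outcome meta-analysis.
Pleiotropic intercepts act relative to the exposure-raising allele, the
frame in which directional pleiotropy (and the Egger intercept) is defined;
otherwise random allele orientation would cancel it. Outcome allele
orientation is randomized (swaps and strand flips) so harmonization is
always exercised; alleles are drawn non-palindromic so orientation stays
letter-resolvable and the generated studies are lossless through
harmonization. The multi-trait scan generator defaults to 20 proteins on 2
platforms, 3 instruments each, 4 proteins carrying a true effect of
$|\log \mathrm{OR}| = 1$ per SD — at this outcome sample size the
per-protein standard error is about 0.27, so 1 is the scale of effect a
proteome-wide scan can actually discover, mirroring that only a handful of
proteins emerge from thousands scanned.

The proteomics generator draws log2 intensities
$\mathcal{N}(\mu, \sigma^2)$ (default $\sigma = 1$), shifts named proteins
in cases by their true log2 fold change, and can mask proteins entirely to
emulate analytes below the detection threshold.

What the generators do *not* emulate — and what passing tests therefore do
not establish about real data: realistic genome-wide LD (AR(1) only),
allele-frequency mismatch between studies, platform-specific measurement
artifacts (e.g. epitope-binding effects that attenuate pQTL estimates),
sample overlap between exposure and outcome GWAS, population
stratification, and missing-not-at-random intensity patterns in MS
proteomics.

## Numerical choices and degenerate inputs

* All colocalization arithmetic is in log space; H3 uses a guarded
  `log(exp(a) - exp(b))` that returns $-\infty$ exactly when $b \ge a$
  (single-variant regions).
* Duplicate variant keys in an input table keep the minimum-p row, ties
  broken by first occurrence — deterministic and matching common QTL-export
  conventions. Input validation is total: every dropped row carries exactly
  one named reason, and kept + dropped = input rows.
* Result tables are written with 17 significant digits, so a re-read
  reproduces every double bit-for-bit; repeated runs with the same seed are
  byte-identical (manifests contain no timestamps).
* The weighted-median bootstrap and the scan accept a seed and restore the
  caller's RNG state afterwards.
* An exposure beta of exactly 0 is a degenerate instrument (Wald ratio
  undefined) and is rejected with a clear error; zero-variance proteins in
  the DE module get $p = 1$ when the group means agree and `not_testable`
  otherwise.
* Egger on noiseless (exact-fit) inputs would divide by a zero residual
  sigma; the scale factor is then fixed at 1 so the exact slope and
  intercept are still reported.

## Problem sizes used in the checks

The statistical checks run at sizes chosen to make Monte-Carlo error small
relative to the tolerances while keeping a laptop run comfortable: 200
random small regions for the enumeration-oracle equivalence; 100 H4 + 100
H3 regions of 500 variants for scenario recovery; 2000 null and 1000
effect single-instrument studies for calibration and coverage; 500 studies
of 20 instruments for Egger's intercept; 500 cohorts of 50 + 50 samples for
the log2FC recovery; a 20-protein, 2-platform scan for end-to-end
determinism.

## Known limitations

Single-causal-variant colocalization only (no conditioning or SuSiE-style
extensions); no LD-aware fine-mapping; no proxy-variant substitution or
outcome imputation; no Steiger filtering or the newer pleiotropy-robust
estimators (MR-PRESSO, contamination mixture, mode-based); no
genome-build liftover (the build is carried as free-text metadata only);
the DE module deliberately stops at Welch's t on log2 intensities —
moderated-variance (limma-style) testing is a possible extension, not a
default, to keep the validation statistics transparent.
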