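# scadmr

Proteome- and transcriptome-wide **cis-Mendelian randomization** with
**Bayesian colocalization** for a rare binary outcome — spontaneous
coronary artery dissection (SCAD) — plus the case–control proteomics
statistics used to validate candidate proteins, and a synthetic
summary-statistics generator so the entire pipeline runs and is tested
without access to consortium data.

Built for genetic epidemiologists who want to screen circulating proteins
(and tissue transcripts) for causal relevance to a disease from GWAS
summary statistics alone, triangulate the evidence across platforms and
tissues, and check candidates in a small case–control proteomics cohort.

## What it computes

For each protein with a *cis* instrument (gene body ± 1 Mb,
p ≤ 5×10⁻⁸, F = (β/se)² ≥ 10, LD-clumped at r² ≤ 0.01):

* **Wald ratio** (single instrument): θ̂ = β̂_Y/β̂_X, with the two-term
  delta-method standard error; **IVW** (k ≥ 2): the
  inverse-variance-weighted average of ratios with weights β̂²_X/se²_Y and
  multiplicative random effects; **MR-Egger** and **weighted median**
  (k ≥ 3, otherwise a structured `not_estimable` result). Estimates are
  log-odds of disease per SD of protein; odds ratios with 95% CIs are
  reported. Discovery is Benjamini–Hochberg-controlled at q < 0.05 within
  each platform.
* **Colocalization**: Wakefield approximate Bayes factors per variant,
  log ABF = ½[log(1−r) + r z²] with r = W/(W + se²), enumerated over
  single-causal-variant configurations into posteriors PP.H0–PP.H4 (H4 =
  shared causal variant) and the conditional metric PP.H4/(PP.H3+PP.H4).
* **Triangulation**: a trait × dataset evidence matrix (estimate signs,
  significance stars on adjusted p, explicit "unavailable" cells) and
  support tiers combining MR significance, colocalization support
  (PP.H4 ≥ 0.8) and sign-consistent tissue-eQTL corroboration.
* **Validation**: Welch t-tests on log2 protein intensities
  (log2FC = case − control means, BH-adjusted, detection thresholds
  honoured) and a baseline clinical table (Welch t; Pearson chi-square
  without continuity correction).

See `vignettes/scad-mr-coloc.Rmd` for the full model description,
parameter defaults, and design rationale.

## Worked example

Simulate a two-sample MR study with three strong instruments and a true
causal effect of 0.3 log-odds per SD, harmonize, and estimate:

```r
library(scadmr)
study <- simulate_mr_study(3, beta_true = 0.3, seed = 42)
pairs <- usable_pairs(harmonize_tables(study$exposure, study$outcome))
ivw(pairs, trait_id = "PROT1")[, c("method", "n_snp", "estimate", "se",
                                   "pval", "or_point", "or_lo95", "or_hi95")]
#>    method n_snp  estimate        se      pval or_point   or_lo95  or_hi95
#> 1 ivw_mre     3 0.3213302 0.3441014 0.3503946 1.378961 0.7025096 2.706772
```

The IVW estimate 0.32 (OR 1.38 per SD, 95% CI 0.70–2.71) sits close to the
true log-odds of 0.3, but with three instruments against a small outcome
GWAS the interval is wide — exactly the sparse-instrument regime the
proteome-wide scan is built to survive.

Colocalization on a simulated region where both traits share a causal
variant:

```r
rp <- simulate_region_pair(sim_scenario("H4", n_variants = 200,
                                        causal_index_1 = 100,
                                        causal_index_2 = 100, seed = 3))
coloc_abf(rp$region1, rp$region2)[, c("pp_h3", "pp_h4", "conditional_pp")]
#>         pp_h3     pp_h4 conditional_pp
#> 1 0.000372373 0.9996276      0.9996276
```

PP.H4 ≈ 1: the region supports a shared causal variant.

The numbered scripts under `analysis/` run the full workflow on synthetic
inputs — `01_simulate_data.R` (inputs), `02_proteome_scan.R` (the
20-protein, 2-platform scan: recovers exactly the 4 simulated causal
proteins after FDR), `03_method_calibration.R` (type-I error 0.044,
CI coverage 0.956, Egger intercept 0.051 for a true 0.05, colocalization
scenario medians), `04_validation_proteomics.R` (ECM1-like protein:
log2FC 0.801, p = 9.7×10⁻⁵; masked proteins reported below detection;
baseline table with the chi-square p-values). Tables land under
`results/`.

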