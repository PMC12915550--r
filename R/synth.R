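# Synthetic summary-statistics and proteomics generators. Regional summary
# statistics are drawn directly from the multivariate-normal sampling
# distribution of marginal GWAS estimates (no individual-level genotypes):
# that is orders of magnitude faster and is exactly the object every
# downstream stage consumes.

#' AR(1) regional LD correlation matrix
#'
#' `R[i, j] = ld_rho^|i - j|`: symmetric, unit diagonal and positive
#' definite for `0 <= ld_rho < 1`.
#'
#' @param n_variants number of variants.
#' @param ld_rho decay parameter in `[0, 1)`.
#' @return `n_variants x n_variants` correlation matrix.
#' @export
simulate_ld <- function(n_variants, ld_rho) {
  if (is.na(ld_rho) || ld_rho < 0 || ld_rho >= 1) {
    stop("ld_rho must lie in [0, 1)", call. = FALSE)
  }
  idx <- seq_len(n_variants)
  ld_rho^abs(outer(idx, idx, "-"))
}

#' Define a colocalization simulation scenario
#'
#' Validates the hypothesis-specific constraints: H4 requires a single
#' shared causal index, H3 two distinct indices, H1/H2 one index for the
#' respective trait, H0 none.
#'
#' @param hypothesis one of `"H0"`, `"H1"`, `"H2"`, `"H3"`, `"H4"`.
#' @param n_variants region size (default 500).
#' @param ld_rho AR(1) LD decay (default 0.9).
#' @param causal_index_1,causal_index_2 causal variant positions (or `NA`).
#' @param effect_size_1,effect_size_2 per-allele effects at the causal
#'   variant (default 0.15, which at n = 20000 gives causal |z| around
#'   10-20 across common minor-allele frequencies).
#' @param n_trait1,n_trait2 GWAS sample sizes (default 20000).
#' @param maf_range range minor-allele frequencies are drawn from
#'   (default `c(0.05, 0.5)`).
#' @param case_fraction_2 case fraction when trait 2 is a binary outcome
#'   (`NULL` = quantitative); inflates the sampling variance by
#'   `1/(phi*(1-phi))`.
#' @param seed RNG seed.
#' @return validated scenario list of class `sim_scenario`.
#' @export
sim_scenario <- function(hypothesis = c("H4", "H3", "H2", "H1", "H0"),
                         n_variants = 500, ld_rho = 0.9,
                         causal_index_1 = NA_integer_,
                         causal_index_2 = NA_integer_,
                         effect_size_1 = 0.15, effect_size_2 = 0.15,
                         n_trait1 = 20000, n_trait2 = 20000,
                         maf_range = c(0.05, 0.5),
                         case_fraction_2 = NULL, seed = NULL) {
  hypothesis <- match.arg(hypothesis)
  c1 <- causal_index_1; c2 <- causal_index_2
  valid <- switch(hypothesis,
                  H0 = is.na(c1) && is.na(c2),
                  H1 = !is.na(c1) && is.na(c2),
                  H2 = is.na(c1) && !is.na(c2),
                  H3 = !is.na(c1) && !is.na(c2) && c1 != c2,
                  H4 = !is.na(c1) && !is.na(c2) && c1 == c2)
  if (!valid) {
    stop("causal indices inconsistent with hypothesis ", hypothesis,
         call. = FALSE)
  }
  for (ci in c(c1, c2)) {
    if (!is.na(ci) && (ci < 1L || ci > n_variants)) {
      stop("causal index out of range", call. = FALSE)
    }
  }
  structure(list(hypothesis = hypothesis, n_variants = n_variants,
                 ld_rho = ld_rho, causal_index_1 = c1, causal_index_2 = c2,
                 effect_size_1 = effect_size_1, effect_size_2 = effect_size_2,
                 n_trait1 = n_trait1, n_trait2 = n_trait2,
                 maf_range = maf_range, case_fraction_2 = case_fraction_2,
                 seed = seed),
            class = "sim_scenario")
}

# Per-variant sampling SD of a marginal per-allele GWAS estimate for a
# standardized trait; a binary trait's variance is inflated by
# 1/(phi*(1-phi)) for case fraction phi.
#' @noRd
marginal_se <- function(n, maf, case_fraction = NULL) {
  v <- 1 / (2 * n * maf * (1 - maf))
  if (!is.null(case_fraction)) v <- v / (case_fraction * (1 - case_fraction))
  sqrt(v)
}

#' Simulate a pair of regional summary-statistics panels
#'
#' Marginal true effects are `b = R %*% gamma` with `gamma` nonzero only at
#' the causal index; estimates are drawn from `MVN(b, D R D)` where `D` is
#' the diagonal of per-variant sampling standard errors
#' `sqrt(1/(2 n maf (1-maf)))` (binary traits inflated by `1/(phi(1-phi))`).
#' The reported `se` is that sampling standard error. Both traits share the
#' variant grid, LD and allele frequencies; their noise is independent
#' (two-sample setting).
#'
#' @param scenario a [sim_scenario()].
#' @return list with `region1`, `region2` (data.frames `variant_id`, `beta`,
#'   `se`, with `trait_type` attributes), `maf`, `ld` and the scenario.
#' @export
simulate_region_pair <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  with_seed(scenario$seed, {
    n <- scenario$n_variants
    maf <- stats::runif(n, scenario$maf_range[1], scenario$maf_range[2])
    R <- simulate_ld(n, scenario$ld_rho)
    U <- chol(R)
    ids <- sprintf("rs%06d", seq_len(n))

    draw <- function(causal_index, effect, n_samples, case_fraction = NULL) {
      se <- marginal_se(n_samples, maf, case_fraction)
      gamma <- numeric(n)
      if (!is.na(causal_index)) gamma[causal_index] <- effect
      b <- as.numeric(R %*% gamma)
      noise <- se * as.numeric(crossprod(U, stats::rnorm(n)))
      beta <- b + noise
      structure(data.frame(variant_id = ids, beta = beta, se = se,
                           stringsAsFactors = FALSE),
                trait_type = if (is.null(case_fraction)) "quantitative" else "binary")
    }
    region1 <- draw(scenario$causal_index_1, scenario$effect_size_1,
                    scenario$n_trait1)
    region2 <- draw(scenario$causal_index_2, scenario$effect_size_2,
                    scenario$n_trait2, scenario$case_fraction_2)
    list(region1 = region1, region2 = region2, maf = maf, ld = R,
         scenario = scenario)
  })
}

#' @noRd
NONPALINDROMIC_PAIRS <- cbind(
  ea = c("A", "A", "C", "C", "G", "G", "T", "T"),
  oa = c("C", "G", "A", "T", "A", "T", "C", "G")
)

#' Simulate a two-sample MR study
#'
#' Generates `k` independent cis instruments for one exposure and the
#' matched outcome associations. True exposure effects are sized to hit a
#' target F-statistic band; outcome effects are `beta_true * beta_exp_true`
#' plus an optional per-instrument pleiotropic intercept (`balanced`: mean
#' zero; `directional`: mean `alpha_pleio`), plus sampling noise at the
#' outcome's standard error. The outcome table's allele orientation is
#' randomized (swaps and strand flips) to exercise harmonization; alleles
#' are drawn non-palindromic so orientation is always letter-resolvable.
#'
#' @param k_instruments number of instruments.
#' @param beta_true causal effect of the exposure on the outcome
#'   (log-odds per SD).
#' @param pleiotropy `"none"`, `"balanced"` or `"directional"`.
#' @param alpha_pleio pleiotropy scale: SD of the balanced intercepts, or
#'   the mean of directional intercepts (drawn with SD `alpha_pleio/2`).
#' @param n_exp,n_out exposure and outcome GWAS sample sizes (defaults
#'   35000 and 11209, the scale of the source pQTL study and of a 1917-case
#'   / 9292-control outcome GWAS).
#' @param case_fraction_out case fraction of the binary outcome (default
#'   1917/11209); `NULL` for a quantitative outcome.
#' @param f_band target F-statistic band (default `c(80, 120)`, strong
#'   instruments around F = 100).
#' @param maf_range minor-allele-frequency range.
#' @param gene_id,chrom,gene_start,gene_end locus the instruments are placed
#'   in (positions uniform over the gene body, so every instrument is cis).
#' @param seed RNG seed.
#' @return list: `exposure` and `outcome` `trait_table`s, `locus` (one-row
#'   locus data.frame), `ld` (identity, instruments are independent), and
#'   `truth` (true effects and pleiotropic intercepts).
#' @export
simulate_mr_study <- function(k_instruments, beta_true = 0,
                              pleiotropy = c("none", "balanced", "directional"),
                              alpha_pleio = 0, n_exp = 35000, n_out = 11209,
                              case_fraction_out = 1917 / 11209,
                              f_band = c(80, 120), maf_range = c(0.05, 0.5),
                              gene_id = "GENE1", chrom = "1",
                              gene_start = 1000000L, gene_end = 1010000L,
                              seed = NULL) {
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(k_instruments >= 1)
  with_seed(seed, {
    k <- k_instruments
    maf <- stats::runif(k, maf_range[1], maf_range[2])
    se_exp <- marginal_se(n_exp, maf)
    se_out <- marginal_se(n_out, maf, case_fraction_out)
    f_target <- stats::runif(k, f_band[1], f_band[2])
    bx_true <- sample(c(-1, 1), k, replace = TRUE) * sqrt(f_target) * se_exp
    alpha <- switch(pleiotropy,
                    none = numeric(k),
                    balanced = stats::rnorm(k, 0, alpha_pleio),
                    directional = stats::rnorm(k, alpha_pleio, alpha_pleio / 2))
    bx_hat <- bx_true + stats::rnorm(k, 0, se_exp)
    # pleiotropic effects act relative to the exposure-raising allele, the
    # frame in which directional pleiotropy (and Egger's intercept) is defined
    by_hat <- beta_true * bx_true + sign(bx_true) * alpha +
      stats::rnorm(k, 0, se_out)

    pos <- sort(sample(seq(gene_start, gene_end), k))
    ids <- paste0(chrom, ":", pos)
    alle <- NONPALINDROMIC_PAIRS[sample(nrow(NONPALINDROMIC_PAIRS), k,
                                        replace = TRUE), , drop = FALSE]
    eaf <- maf  # effect allele taken as the minor allele

    exposure <- trait_table(
      data.frame(variant_id = ids, chrom = chrom, pos = pos,
                 effect_allele = alle[, "ea"], other_allele = alle[, "oa"],
                 eaf = eaf, beta = bx_hat, se = se_exp, n = n_exp,
                 stringsAsFactors = FALSE),
      trait_id = gene_id, trait_type = "protein", platform = "synthetic")

    # randomize the outcome file's orientation: allele swap and strand flip
    swap <- stats::runif(k) < 0.5
    strand <- stats::runif(k) < 0.5
    ea_o <- alle[, "ea"]; oa_o <- alle[, "oa"]
    b_o <- by_hat; eaf_o <- eaf
    ea_s <- ea_o[swap]; ea_o[swap] <- oa_o[swap]; oa_o[swap] <- ea_s
    b_o[swap] <- -b_o[swap]; eaf_o[swap] <- 1 - eaf_o[swap]
    ea_o[strand] <- reverse_complement(ea_o[strand])
    oa_o[strand] <- reverse_complement(oa_o[strand])

    outcome <- trait_table(
      data.frame(variant_id = ids, chrom = chrom, pos = pos,
                 effect_allele = ea_o, other_allele = oa_o,
                 eaf = eaf_o, beta = b_o, se = se_out, n = n_out,
                 stringsAsFactors = FALSE),
      trait_id = "outcome", trait_type = "outcome", platform = "synthetic-gwas")

    ld <- diag(k)
    dimnames(ld) <- list(ids, ids)
    locus <- data.frame(gene_id = gene_id, chrom = chrom,
                        start = gene_start, end = gene_end,
                        stringsAsFactors = FALSE)
    list(exposure = exposure, outcome = outcome, locus = locus, ld = ld,
         truth = list(beta_true = beta_true, bx_true = bx_true,
                      pleiotropy_intercepts = alpha, maf = maf))
  })
}

#' Simulate a log-normal protein intensity matrix
#'
#' Log2 intensities are normal with per-protein baseline `mu_log2` and SD
#' `sigma`; proteins named in `effect_map` are shifted in cases by the given
#' log2 effects. Proteins in `missing_proteins` are fully masked,
#' emulating analytes below the assay's detection threshold.
#'
#' @param n_case,n_control group sizes (defaults 50/50, the validation
#'   cohort design).
#' @param n_proteins total panel size (default 20).
#' @param effect_map named numeric vector of true case-vs-control log2 fold
#'   changes; names become protein ids in the panel.
#' @param sigma SD of log2 intensity (default 1).
#' @param mu_log2 baseline mean log2 intensity (default 20).
#' @param missing_proteins protein ids to mask entirely.
#' @param seed RNG seed.
#' @return list: `intensities` (proteins x samples matrix), `groups`
#'   (character vector), `truth` (the effect map).
#' @export
simulate_proteomics <- function(n_case = 50, n_control = 50, n_proteins = 20,
                                effect_map = c(), sigma = 1, mu_log2 = 20,
                                missing_proteins = character(0), seed = NULL) {
  stopifnot(n_case >= 2, n_control >= 2)
  named <- union(names(effect_map), missing_proteins)
  n_proteins <- max(n_proteins, length(named))
  ids <- c(named, sprintf("prot%03d", seq_len(n_proteins - length(named))))
  with_seed(seed, {
    n_s <- n_case + n_control
    groups <- c(rep("case", n_case), rep("control", n_control))
    lmat <- matrix(stats::rnorm(n_proteins * n_s, mu_log2, sigma),
                   nrow = n_proteins, dimnames = list(ids, NULL))
    for (p in names(effect_map)) {
      lmat[p, groups == "case"] <- lmat[p, groups == "case"] + effect_map[[p]]
    }
    m <- 2^lmat
    m[ids %in% missing_proteins, ] <- NA_real_
    colnames(m) <- c(sprintf("case%03d", seq_len(n_case)),
                     sprintf("ctrl%03d", seq_len(n_control)))
    list(intensities = m, groups = groups, truth = effect_map)
  })
}

#' Simulate a multi-trait, multi-platform scan study
#'
#' Builds the full input set for [run_scan()]: a gene locus per trait, per
#' platform a list of exposure trait tables (each trait present in a
#' platform with probability `availability`), a single outcome table
#' covering all variants, and identity LD matrices per locus. A subset of
#' traits carries a real causal effect on the outcome.
#'
#' @param n_traits number of protein traits (default 20).
#' @param platforms platform labels (default two, emulating a two-platform
#'   proteome scan).
#' @param k_instruments instruments per trait (default 3).
#' @param n_causal number of traits with a true effect (default 4).
#' @param beta_causal true log-odds effect per SD for causal traits
#'   (default 1, alternating sign: with a 1917-case outcome GWAS and 3
#'   instruments the per-protein estimate's standard error is about 0.27,
#'   so detectable discovery-scale effects sit near |log OR| = 1).
#' @param availability probability a trait is assayed on a platform
#'   (default 0.9).
#' @param seed RNG seed.
#' @return list: `exposures` (platform -> list of trait tables), `outcome`
#'   (combined trait table), `loci`, `ld` (gene -> matrix), `truth`.
#' @export
simulate_scan_study <- function(n_traits = 20,
                                platforms = c("platform_A", "platform_B"),
                                k_instruments = 3, n_causal = 4,
                                beta_causal = 1, availability = 0.9,
                                seed = NULL) {
  with_seed(seed, {
    traits <- sprintf("PROT%02d", seq_len(n_traits))
    beta_true <- stats::setNames(numeric(n_traits), traits)
    if (n_causal > 0) {
      idx <- seq_len(min(n_causal, n_traits))
      beta_true[idx] <- beta_causal * rep_len(c(1, -1), length(idx))
    }
    loci <- data.frame(gene_id = traits,
                       chrom = as.character(rep_len(1:22, n_traits)),
                       start = 5e6 + (seq_len(n_traits) - 1) * 4e6,
                       end = 5e6 + (seq_len(n_traits) - 1) * 4e6 + 20000,
                       stringsAsFactors = FALSE)
    exposures <- list()
    outcome_rows <- list()
    ld <- list()
    for (pl in platforms) exposures[[pl]] <- list()
    for (i in seq_len(n_traits)) {
      for (pl in platforms) {
        if (stats::runif(1) > availability) next
        study <- simulate_mr_study(
          k_instruments = k_instruments, beta_true = beta_true[i],
          gene_id = traits[i], chrom = loci$chrom[i],
          gene_start = loci$start[i], gene_end = loci$end[i],
          seed = NULL)
        attr(study$exposure, "platform") <- pl
        exposures[[pl]][[traits[i]]] <- study$exposure
        outcome_rows[[paste(pl, traits[i])]] <- as.data.frame(study$outcome)
        if (is.null(ld[[traits[i]]])) {
          ld[[traits[i]]] <- study$ld
        } else {
          ids <- union(rownames(ld[[traits[i]]]), rownames(study$ld))
          merged <- diag(length(ids))
          dimnames(merged) <- list(ids, ids)
          ld[[traits[i]]] <- merged
        }
      }
    }
    outcome_df <- do.call(rbind, outcome_rows)
    outcome <- trait_table(outcome_df, trait_id = "outcome",
                           trait_type = "outcome", platform = "synthetic-gwas")
    list(exposures = exposures, outcome = outcome, loci = loci, ld = ld,
         truth = list(beta_true = beta_true))
  })
}
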