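# Bayesian colocalization of two association regions under the
# single-causal-variant-per-trait enumeration, using Wakefield approximate
# Bayes factors. Hypotheses: H0 no causal variant for either trait; H1/H2 a
# causal variant for trait 1/2 only; H3 distinct causal variants; H4 a
# shared causal variant.

#' Log Wakefield approximate Bayes factor
#'
#' For an estimate `beta` with standard error `se` and a N(0, w) prior on
#' the true effect, the approximate Bayes factor against the null is
#' `0.5 * (log(1 - r) + r * z^2)` on the log scale, with `V = se^2`,
#' `r = w/(w + V)` and `z = beta/se`. Finite for all finite inputs and
#' vectorized.
#'
#' @param beta,se association estimate and standard error (`se > 0`).
#' @param w prior variance of the true effect (`w > 0`); conventional values
#'   are `0.15^2` for a quantitative trait and `0.2^2` for log-odds of a
#'   binary trait.
#' @return numeric vector of log ABFs.
#' @export
wakefield_labf <- function(beta, se, w) {
  if (any(is.na(se)) || any(se <= 0)) stop("se must be positive", call. = FALSE)
  if (any(is.na(w)) || any(w <= 0)) stop("prior variance w must be positive", call. = FALSE)
  v <- se^2
  r <- w / (w + v)
  0.5 * (log1p(-r) + r * (beta / se)^2)
}

#' @noRd
region_w <- function(region, w_quant, w_binary) {
  type <- attr(region, "trait_type")
  if (is.null(type)) type <- "quantitative"
  if (identical(type, "binary") || identical(type, "outcome")) w_binary else w_quant
}

#' Colocalization posterior probabilities for a region pair
#'
#' Enumerates the single-causal-variant configurations of the two traits
#' over the shared variant grid and aggregates per-variant log ABFs with
#' log-sum-exp (numerically safe for |z| up to at least 100):
#' `H1 ~ p1 * sum(BF1)`, `H2 ~ p2 * sum(BF2)`,
#' `H3 ~ p1*p2 * (sum(BF1)*sum(BF2) - sum(BF1*BF2))`,
#' `H4 ~ p12 * sum(BF1*BF2)`, `H0 ~ 1`, normalized to sum to one. A
#' single-variant region has exactly zero H3 mass (two distinct causal
#' variants are impossible).
#'
#' @param region1,region2 data.frames with columns `variant_id`, `beta`,
#'   `se`, aligned to a common effect allele per variant; the same variant
#'   set in the same order. An optional attribute `trait_type`
#'   (`"quantitative"` default, or `"binary"`) selects the prior effect
#'   scale.
#' @param p1,p2,p12 per-variant prior probabilities of being causal for
#'   trait 1 only, trait 2 only, and both (defaults 1e-4, 1e-4, 1e-5).
#' @param w_quant,w_binary prior effect variances (defaults `0.15^2`,
#'   `0.2^2`).
#' @return one-row data.frame: `pp_h0` ... `pp_h4` (sum to 1 within 1e-10),
#'   `conditional_pp` = `pp_h4/(pp_h3 + pp_h4)`, `n_variants`, and the
#'   priors used.
#' @export
coloc_abf <- function(region1, region2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      w_quant = 0.15^2, w_binary = 0.2^2) {
  stopifnot(p1 > 0, p2 > 0, p12 > 0, p1 + p2 + p12 < 0.01)
  if (nrow(region1) != nrow(region2) ||
      !identical(as.character(region1$variant_id),
                 as.character(region2$variant_id))) {
    stop("regions must share the same variant set in the same order",
         call. = FALSE)
  }
  n <- nrow(region1)
  if (n == 0L) stop("empty region", call. = FALSE)
  lbf1 <- wakefield_labf(region1$beta, region1$se,
                         region_w(region1, w_quant, w_binary))
  lbf2 <- wakefield_labf(region2$beta, region2$se,
                         region_w(region2, w_quant, w_binary))
  ls1 <- logsumexp(lbf1)
  ls2 <- logsumexp(lbf2)
  lsb <- logsumexp(lbf1 + lbf2)
  lh <- c(h0 = 0,
          h1 = log(p1) + ls1,
          h2 = log(p2) + ls2,
          h3 = log(p1) + log(p2) + logdiffexp(ls1 + ls2, lsb),
          h4 = log(p12) + lsb)
  pp <- exp(lh - logsumexp(lh))
  data.frame(pp_h0 = pp[["h0"]], pp_h1 = pp[["h1"]], pp_h2 = pp[["h2"]],
             pp_h3 = pp[["h3"]], pp_h4 = pp[["h4"]],
             conditional_pp = conditional_pp(pp[["h3"]], pp[["h4"]]),
             n_variants = n, p1 = p1, p2 = p2, p12 = p12)
}

#' Probability of colocalization conditional on both traits being causal
#'
#' `PP.H4 / (PP.H3 + PP.H4)`: among configurations where both traits have a
#' causal variant in the region, the posterior share in which it is shared.
#'
#' @param pp_h3,pp_h4 posterior probabilities, or a one-row [coloc_abf()]
#'   result passed as `pp_h3` with `pp_h4` missing.
#' @return numeric in `[0, 1]`, or `NA` when `pp_h3 + pp_h4 == 0`.
#' @export
conditional_pp <- function(pp_h3, pp_h4) {
  if (missing(pp_h4) && is.data.frame(pp_h3)) {
    pp_h4 <- pp_h3$pp_h4
    pp_h3 <- pp_h3$pp_h3
  }
  denom <- pp_h3 + pp_h4
  ifelse(denom > 0, pp_h4 / denom, NA_real_)
}
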