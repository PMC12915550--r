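# Two-sample Mendelian randomization estimators over harmonized pairs, and
# false-discovery-rate control for the proteome-wide scan.
#
# All estimates are on the log-odds scale of the binary outcome per unit of
# the exposure (pQTL betas are reported per SD of protein level, so odds
# ratios read "per SD"). P-values for Wald and IVW use the two-sided normal
# reference, the summary-statistic convention; MR-Egger uses the t reference
# with k - 2 degrees of freedom as is standard for that regression.

#' @noRd
mr_result <- function(trait_id = NA_character_, method, estimate = NA_real_,
                      se = NA_real_, pval = NA_real_, n_snp = NA_integer_,
                      egger_intercept = NA_real_, egger_intercept_p = NA_real_,
                      status = "ok", reason = NA_character_) {
  ok <- identical(status, "ok")
  data.frame(trait_id = trait_id, method = method,
             n_snp = as.integer(n_snp),
             estimate = estimate, se = se, pval = pval,
             p_adj = NA_real_,
             or_point = if (ok) exp(estimate) else NA_real_,
             or_lo95 = if (ok) exp(estimate - 1.959963984540054 * se) else NA_real_,
             or_hi95 = if (ok) exp(estimate + 1.959963984540054 * se) else NA_real_,
             egger_intercept = egger_intercept,
             egger_intercept_p = egger_intercept_p,
             status = status, reason = reason,
             stringsAsFactors = FALSE)
}

#' @noRd
check_pairs <- function(pairs) {
  pairs <- usable_pairs(pairs)
  if (nrow(pairs) == 0L) stop("no usable harmonized pairs", call. = FALSE)
  if (any(pairs$beta_exp == 0)) {
    stop("degenerate instrument: exposure beta of exactly 0", call. = FALSE)
  }
  pairs
}

#' Wald ratio estimate from a single instrument
#'
#' Causal estimate `beta_out / beta_exp`. The standard error uses the
#' two-term first-order delta method,
#' `sqrt(se_out^2/beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)`,
#' which is conservative relative to `se_out/|beta_exp|` when instrument
#' strength is moderate; set `first_order_only = TRUE` for the one-term
#' version.
#'
#' @param pair one harmonized pair (one-row data.frame from
#'   [harmonize_tables()]).
#' @param trait_id label carried into the result.
#' @param first_order_only drop the exposure-uncertainty term.
#' @return one-row MR result data.frame (`estimate`, `se`, `pval`,
#'   `or_point`, `or_lo95`, `or_hi95`, ...).
#' @export
wald_ratio <- function(pair, trait_id = NA_character_, first_order_only = FALSE) {
  pair <- check_pairs(pair)
  stopifnot(nrow(pair) == 1L)
  bx <- pair$beta_exp; by <- pair$beta_out
  sx <- pair$se_exp; sy <- pair$se_out
  est <- by / bx
  v <- sy^2 / bx^2
  if (!first_order_only) v <- v + by^2 * sx^2 / bx^4
  se <- sqrt(v)
  mr_result(trait_id, "wald", est, se, 2 * stats::pnorm(-abs(est / se)),
            n_snp = 1L)
}

#' Inverse-variance-weighted estimate
#'
#' Weighted average of per-instrument Wald ratios with weights
#' `beta_exp^2 / se_out^2` (equivalently, weighted least squares of
#' `beta_out` on `beta_exp` through the origin). With `"fixed"` effects the
#' standard error is `sqrt(1/sum(w))`; with `"multiplicative_random"` it is
#' scaled by `sqrt(max(1, Q/(k-1)))` where Q is Cochran's heterogeneity
#' statistic of the ratios. `"auto"` (default) uses fixed effects for a
#' single instrument and multiplicative random effects otherwise.
#'
#' @param pairs harmonized pairs.
#' @param effects_model `"auto"`, `"fixed"` or `"multiplicative_random"`.
#' @param trait_id label carried into the result.
#' @return one-row MR result data.frame.
#' @export
ivw <- function(pairs, effects_model = c("auto", "fixed", "multiplicative_random"),
                trait_id = NA_character_) {
  effects_model <- match.arg(effects_model)
  pairs <- check_pairs(pairs)
  k <- nrow(pairs)
  if (effects_model == "auto") {
    effects_model <- if (k == 1L) "fixed" else "multiplicative_random"
  }
  r <- pairs$beta_out / pairs$beta_exp
  w <- pairs$beta_exp^2 / pairs$se_out^2
  est <- sum(w * r) / sum(w)
  se <- sqrt(1 / sum(w))
  if (effects_model == "multiplicative_random") {
    if (k < 2L) stop("multiplicative random effects needs at least 2 instruments",
                     call. = FALSE)
    q <- sum(w * (r - est)^2)
    se <- se * sqrt(max(1, q / (k - 1)))
  }
  method <- if (effects_model == "fixed") "ivw_fe" else "ivw_mre"
  mr_result(trait_id, method, est, se, 2 * stats::pnorm(-abs(est / se)),
            n_snp = k)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome betas on exposure betas with a free
#' intercept (weights `1/se_out^2`), after orienting all exposure betas
#' nonnegative. The slope is the causal estimate; the intercept estimates
#' average directional pleiotropy. Standard errors use the multiplicative
#' random-effects scaling `max(1, sigma_resid)` and the t reference with
#' `k - 2` degrees of freedom. With fewer than 3 instruments the model is not
#' identified and a structured `not_estimable` result is returned, mirroring
#' how sparse-instrument exposures are reported rather than erroring.
#'
#' @inheritParams ivw
#' @return one-row MR result data.frame (`egger_intercept`,
#'   `egger_intercept_p` populated; `status = "not_estimable"` with a reason
#'   when k < 3).
#' @export
egger <- function(pairs, trait_id = NA_character_) {
  pairs <- usable_pairs(pairs)
  k <- nrow(pairs)
  if (k < 3L) {
    return(mr_result(trait_id, "egger", n_snp = k, status = "not_estimable",
                     reason = "insufficient instruments"))
  }
  pairs <- check_pairs(pairs)
  s <- sign(pairs$beta_exp)
  bx <- abs(pairs$beta_exp)
  by <- pairs$beta_out * s
  w <- 1 / pairs$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  cf <- summary(fit)$coefficients
  scale <- max(1, summary(fit)$sigma) / summary(fit)$sigma
  if (!is.finite(scale)) scale <- 1  # noiseless (exact-fit) degenerate input
  se_slope <- cf["bx", "Std. Error"] * scale
  se_int <- cf["(Intercept)", "Std. Error"] * scale
  est <- cf["bx", "Estimate"]
  int <- cf["(Intercept)", "Estimate"]
  p_slope <- 2 * stats::pt(-abs(est / se_slope), df = k - 2)
  p_int <- 2 * stats::pt(-abs(int / se_int), df = k - 2)
  mr_result(trait_id, "egger", est, se_slope, p_slope, n_snp = k,
            egger_intercept = int, egger_intercept_p = p_int)
}

# Weighted median of ratios: the value where the cumulative standardized
# weight (centered, Bowden-style) crosses 0.5, linearly interpolated.
#' @noRd
weighted_median_point <- function(r, w) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord] / sum(w)
  cs <- cumsum(w) - w / 2
  if (cs[1] >= 0.5) return(r[1])
  if (cs[length(cs)] <= 0.5) return(r[length(cs)])
  i <- max(which(cs < 0.5))
  r[i] + (r[i + 1] - r[i]) * (0.5 - cs[i]) / (cs[i + 1] - cs[i])
}

#' Weighted median estimate
#'
#' Orders the per-instrument Wald ratios and takes the ratio at which the
#' cumulative standardized inverse-variance weight crosses 0.5 (linear
#' interpolation between bracketing ratios); consistent when at least half
#' the weight comes from valid instruments. The standard error is a
#' parametric bootstrap: exposure and outcome betas are resampled from their
#' normal sampling distributions and the estimate recomputed.
#'
#' @inheritParams ivw
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed optional seed for the bootstrap (local RNG; the caller's
#'   stream is untouched).
#' @return one-row MR result data.frame (`not_estimable` when k < 3).
#' @export
weighted_median <- function(pairs, n_boot = 2000, seed = NULL,
                            trait_id = NA_character_) {
  pairs <- usable_pairs(pairs)
  k <- nrow(pairs)
  if (k < 3L) {
    return(mr_result(trait_id, "weighted_median", n_snp = k,
                     status = "not_estimable",
                     reason = "insufficient instruments"))
  }
  pairs <- check_pairs(pairs)
  r <- pairs$beta_out / pairs$beta_exp
  w <- pairs$beta_exp^2 / pairs$se_out^2
  est <- weighted_median_point(r, w)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(k, pairs$beta_exp, pairs$se_exp)
      by <- stats::rnorm(k, pairs$beta_out, pairs$se_out)
      ok <- bx != 0
      weighted_median_point(by[ok] / bx[ok], bx[ok]^2 / pairs$se_out[ok]^2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  mr_result(trait_id, "weighted_median", est, se,
            2 * stats::pnorm(-abs(est / se)), n_snp = k)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment across a scan (wraps [stats::p.adjust()] after
#' validating the input domain). Significance at adjusted p < 0.05 defines
#' the scan's discovery set.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Run all requested MR estimators for one harmonized instrument set
#'
#' Routes by instrument count: one pair gives the Wald ratio, two or more
#' give IVW (auto effects model); Egger and weighted median are attempted
#' whenever requested and report `not_estimable` below 3 instruments. The
#' first row (Wald or IVW) is the primary estimate used for FDR control.
#'
#' @param pairs harmonized pairs for one trait.
#' @param trait_id label.
#' @param methods subset of `c("primary", "egger", "weighted_median")`.
#' @param n_boot,seed weighted-median bootstrap controls.
#' @return data.frame of MR results, one row per method.
#' @export
mr_all_methods <- function(pairs, trait_id = NA_character_,
                           methods = c("primary", "egger", "weighted_median"),
                           n_boot = 2000, seed = NULL) {
  pairs <- usable_pairs(pairs)
  k <- nrow(pairs)
  rows <- list()
  if ("primary" %in% methods) {
    rows$primary <- if (k == 1L) wald_ratio(pairs, trait_id)
    else ivw(pairs, trait_id = trait_id)
  }
  if ("egger" %in% methods) rows$egger <- egger(pairs, trait_id)
  if ("weighted_median" %in% methods) {
    rows$wm <- weighted_median(pairs, n_boot = n_boot, seed = seed,
                               trait_id = trait_id)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
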