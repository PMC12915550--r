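# Independent brute-force oracles. Each one re-derives a quantity from its
# definition by direct enumeration or naive arithmetic, never by calling the
# implementation under test.

# Colocalization by direct enumeration over all single-causal-variant
# configurations: trait 1 causal at j in {none, 1..n}, trait 2 at k.
oracle_coloc <- function(lbf1, lbf2, p1, p2, p12) {
  n <- length(lbf1)
  bf1 <- exp(lbf1); bf2 <- exp(lbf2)
  s <- c(h0 = 1, h1 = 0, h2 = 0, h3 = 0, h4 = 0)
  for (j in seq_len(n)) s["h1"] <- s["h1"] + p1 * bf1[j]
  for (k in seq_len(n)) s["h2"] <- s["h2"] + p2 * bf2[k]
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (j == k) s["h4"] <- s["h4"] + p12 * bf1[j] * bf2[j]
      else s["h3"] <- s["h3"] + p1 * p2 * bf1[j] * bf2[k]
    }
  }
  unname(s / sum(s))
}

# Wakefield Bayes factor by numerical integration of the marginal
# likelihood ratio: BF = ∫ N(beta; b, se^2) N(b; 0, w) db / N(beta; 0, se^2)
oracle_labf_quadrature <- function(beta, se, w) {
  marg <- stats::integrate(function(b) {
    stats::dnorm(beta, b, se) * stats::dnorm(b, 0, sqrt(w))
  }, -Inf, Inf, rel.tol = 1e-12)$value
  log(marg) - stats::dnorm(beta, 0, se, log = TRUE)
}

# Allele-orientation oracle: enumerate the candidate representations of the
# outcome record (identity / swap, each with or without strand flip) and
# return the outcome beta expressed per the exposure's effect allele, or NA
# when the orientation is ambiguous (palindromes) or irreconcilable.
rc <- function(a) {
  vapply(strsplit(chartr("ACGT", "TGCA", a), ""),
         function(x) paste(rev(x), collapse = ""), character(1))
}
oracle_orient <- function(ea_e, oa_e, ea_o, oa_o, beta_o) {
  if (ea_e == rc(oa_e)) return(NA_real_)  # palindrome: letters cannot resolve
  candidates <- list(
    list(ea = ea_o, oa = oa_o, flip = FALSE),
    list(ea = oa_o, oa = ea_o, flip = TRUE),
    list(ea = rc(ea_o), oa = rc(oa_o), flip = FALSE),
    list(ea = rc(oa_o), oa = rc(ea_o), flip = TRUE)
  )
  for (cand in candidates) {
    if (cand$ea == ea_e && cand$oa == oa_e) {
      return(if (cand$flip) -beta_o else beta_o)
    }
  }
  NA_real_
}

# Quadratic-time Benjamini-Hochberg from its step-up definition:
# adj(i) = min over ranks j >= rank(i) of m * p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# IVW as weighted least squares of beta_out on beta_exp through the origin.
oracle_ivw_wls <- function(bx, by, sy) {
  fit <- stats::lm(by ~ 0 + bx, weights = 1 / sy^2)
  s <- summary(fit)
  k <- length(bx)
  se_fe <- s$coefficients[1, 2] / s$sigma
  list(estimate = unname(stats::coef(fit)[1]),
       se_fixed = unname(se_fe),
       se_mre = unname(se_fe * max(1, s$sigma)))
}

# Greedy clumping re-run as an explicit loop over p-sorted candidates.
oracle_clump <- function(ids, pvals, ld, r2_max) {
  ord <- order(pvals)
  kept <- character(0)
  for (id in ids[ord]) {
    if (all(ld[id, kept]^2 <= r2_max)) kept <- c(kept, id)
  }
  kept
}

# Build harmonized-pair data.frames directly for estimator tests.
make_pairs <- function(bx, by, sx = rep(0.01, length(bx)),
                       sy = rep(0.05, length(bx))) {
  data.frame(variant_id = paste0("v", seq_along(bx)),
             effect_allele = "A", other_allele = "G",
             beta_exp = bx, se_exp = sx, eaf_exp = 0.3,
             beta_out = by, se_out = sy, eaf_out = 0.3,
             action = "kept_same", reason = NA_character_,
             stringsAsFactors = FALSE)
}
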