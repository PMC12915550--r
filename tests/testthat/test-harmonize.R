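# Allele harmonization: orientation cases, palindrome policy, involution.

rec <- function(id = "rs1", ea, oa, beta = 0.1, se = 0.02, eaf = NA_real_) {
  list(variant_id = id, effect_allele = ea, other_allele = oa,
       beta = beta, se = se, eaf = eaf)
}

test_that("swapped outcome alleles flip beta and complement eaf", {
  pair <- align_pair(rec(ea = "A", oa = "G", beta = 0.10),
                     rec(ea = "G", oa = "A", beta = 0.05, eaf = 0.30))
  expect_equal(pair$action, "flipped")
  expect_equal(pair$beta_out, -0.05)
  expect_equal(pair$eaf_out, 0.70)
})

test_that("strand flips are corrected with and without an allele swap", {
  same <- align_pair(rec(ea = "A", oa = "G"),
                     rec(ea = "T", oa = "C", beta = 0.05))
  expect_equal(same$action, "strand_corrected")
  expect_equal(same$beta_out, 0.05)
  both <- align_pair(rec(ea = "A", oa = "G"),
                     rec(ea = "C", oa = "T", beta = 0.05))
  expect_equal(both$action, "strand_corrected")
  expect_equal(both$beta_out, -0.05)
})

test_that("palindromic variants follow the policy and eaf window", {
  ambiguous <- align_pair(rec(ea = "A", oa = "T", eaf = 0.50),
                          rec(ea = "A", oa = "T", beta = 0.05, eaf = 0.50),
                          palindrome_policy = "infer_by_eaf", eaf_window = 0.08)
  expect_equal(ambiguous$action, "dropped_palindromic")
  expect_equal(ambiguous$reason, "ambiguous_eaf")
  expect_true(is.na(ambiguous$beta_out))

  dropped <- align_pair(rec(ea = "A", oa = "T", eaf = 0.10),
                        rec(ea = "A", oa = "T", beta = 0.05, eaf = 0.12),
                        palindrome_policy = "drop")
  expect_equal(dropped$action, "dropped_palindromic")

  missing <- align_pair(rec(ea = "A", oa = "T", eaf = NA_real_),
                        rec(ea = "A", oa = "T", beta = 0.05, eaf = 0.12))
  expect_equal(missing$reason, "missing_eaf")

  concordant <- align_pair(rec(ea = "A", oa = "T", eaf = 0.10),
                           rec(ea = "A", oa = "T", beta = 0.05, eaf = 0.12))
  expect_equal(concordant$action, "kept_same")
  expect_equal(concordant$beta_out, 0.05)

  discordant <- align_pair(rec(ea = "A", oa = "T", eaf = 0.10),
                           rec(ea = "A", oa = "T", beta = 0.05, eaf = 0.88))
  expect_equal(discordant$action, "strand_corrected")
  expect_equal(discordant$beta_out, -0.05)
  expect_equal(discordant$eaf_out, 0.12)
})

test_that("indels match by exact string or swap only; mismatches drop", {
  swap <- align_pair(rec(ea = "AT", oa = "A"),
                     rec(ea = "A", oa = "AT", beta = 0.05, eaf = 0.3))
  expect_equal(swap$action, "flipped")
  expect_equal(swap$beta_out, -0.05)
  mismatch <- align_pair(rec(ea = "AT", oa = "A"),
                         rec(ea = "TA", oa = "T", beta = 0.05))
  expect_equal(mismatch$action, "dropped_mismatch")
  snp_mismatch <- align_pair(rec(ea = "A", oa = "G"),
                             rec(ea = "A", oa = "C", beta = 0.05))
  expect_equal(snp_mismatch$action, "dropped_mismatch")
})

test_that("mismatched variant ids are a programming error", {
  expect_error(align_pair(rec(id = "rs1", ea = "A", oa = "G"),
                          rec(id = "rs2", ea = "A", oa = "G")),
               "different variants")
})

test_that("harmonized betas agree with the orientation-enumeration oracle", {
  study <- simulate_mr_study(100, beta_true = 0.2, seed = 404)
  pairs <- harmonize_tables(study$exposure, study$outcome)
  expect_equal(nrow(pairs), 100L)
  expect_true(all(pairs$action %in%
                    c("kept_same", "flipped", "strand_corrected")))
  out <- as.data.frame(study$outcome)
  exp <- as.data.frame(study$exposure)
  want <- vapply(seq_len(nrow(pairs)), function(i) {
    j <- match(pairs$variant_id[i], out$variant_id)
    k <- match(pairs$variant_id[i], exp$variant_id)
    oracle_orient(exp$effect_allele[k], exp$other_allele[k],
                  out$effect_allele[j], out$other_allele[j], out$beta[j])
  }, numeric(1))
  expect_equal(pairs$beta_out, want)
})

test_that("harmonization is an involution and every pair gets one action", {
  study <- simulate_mr_study(50, beta_true = 0.1, seed = 17)
  pairs <- harmonize_tables(study$exposure, study$outcome)
  expect_equal(nrow(pairs), 50L)
  expect_true(all(table(pairs$variant_id) == 1L))
  kept <- usable_pairs(pairs)
  # rebuild the outcome in the exposure's orientation and harmonize again
  out2 <- trait_table(
    data.frame(variant_id = kept$variant_id, chrom = "1",
               pos = seq_along(kept$variant_id),
               effect_allele = kept$effect_allele,
               other_allele = kept$other_allele,
               eaf = kept$eaf_out, beta = kept$beta_out, se = kept$se_out),
    trait_id = "outcome", trait_type = "outcome")
  again <- harmonize_tables(study$exposure, out2)
  again <- again[match(kept$variant_id, again$variant_id), ]
  expect_true(all(again$action == "kept_same"))
  expect_equal(again$beta_out, kept$beta_out)
  expect_equal(again$eaf_out, kept$eaf_out)
})

test_that("flipping the outcome file leaves MR estimates unchanged", {
  study <- simulate_mr_study(10, beta_true = 0.3, seed = 99)
  out <- as.data.frame(study$outcome)
  flipped <- transform(out, effect_allele = other_allele,
                       other_allele = effect_allele,
                       beta = -beta, eaf = 1 - eaf)
  out_f <- trait_table(flipped, trait_id = "outcome", trait_type = "outcome")
  p1 <- usable_pairs(harmonize_tables(study$exposure, study$outcome))
  p2 <- usable_pairs(harmonize_tables(study$exposure, out_f))
  expect_equal(ivw(p1)$estimate, ivw(p2)$estimate)
  expect_equal(ivw(p1)$se, ivw(p2)$se)
})

test_that("variants absent from the outcome are tallied unavailable", {
  study <- simulate_mr_study(5, seed = 3)
  out_small <- trait_table(as.data.frame(study$outcome)[1:3, ],
                           trait_id = "outcome", trait_type = "outcome")
  pairs <- harmonize_tables(study$exposure, out_small)
  expect_equal(nrow(pairs), 3L)
  expect_equal(unname(attr(pairs, "tally")["unavailable"]), 2L)
})
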