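# Synthetic-data generators: structure, determinism, calibration.

test_that("AR1 LD matrix has the closed form and is positive definite", {
  expect_equal(simulate_ld(3, 0), diag(3))
  R <- simulate_ld(3, 0.9)
  expect_equal(R[1, 2], 0.9)
  expect_equal(R[1, 3], 0.81)
  expect_equal(R, t(R))
  expect_error(simulate_ld(3, 1), "\\[0, 1\\)")
  set.seed(6)
  for (rho in runif(5, 0, 0.99)) {
    ev <- eigen(simulate_ld(30, rho), symmetric = TRUE, only.values = TRUE)
    expect_gt(min(ev$values), 0)
  }
})

test_that("scenario invariants are enforced", {
  expect_error(sim_scenario("H4", causal_index_1 = 2, causal_index_2 = 3),
               "inconsistent")
  expect_error(sim_scenario("H3", causal_index_1 = 2, causal_index_2 = 2),
               "inconsistent")
  expect_error(sim_scenario("H0", causal_index_1 = 2), "inconsistent")
  expect_error(sim_scenario("H4", n_variants = 10, causal_index_1 = 11,
                            causal_index_2 = 11), "out of range")
})

test_that("region pairs are seeded, self-consistent and satisfy the analytic
          causal z", {
  sc <- sim_scenario("H4", n_variants = 200, causal_index_1 = 100,
                     causal_index_2 = 100, seed = 77)
  a <- simulate_region_pair(sc)
  b <- simulate_region_pair(sc)
  expect_identical(a$region1$beta, b$region1$beta)  # bit-identical at seed
  expect_true(all(a$region1$se > 0))
  expect_equal(nrow(a$region1), 200L)
  # mean causal z over replicates matches effect / sampling sd
  zs <- vapply(1:40, function(i) {
    sc_i <- sim_scenario("H4", n_variants = 50, causal_index_1 = 25,
                         causal_index_2 = 25, seed = 500 + i)
    rp <- simulate_region_pair(sc_i)
    rp$region1$beta[25] / rp$region1$se[25]
  }, numeric(1))
  expect_equal(mean(zs), 0.15 * sqrt(2 * 20000 * 0.275 * 0.725),
               tolerance = 0.25)
})

test_that("null regions rarely show large z", {
  frac_quiet <- vapply(1:60, function(i) {
    sc <- sim_scenario("H0", n_variants = 60, seed = 900 + i)
    rp <- simulate_region_pair(sc)
    max(abs(c(rp$region1$beta / rp$region1$se,
              rp$region2$beta / rp$region2$se))) < 4
  }, logical(1))
  expect_gte(mean(frac_quiet), 0.9)
})

test_that("MR studies hit the target F band and route through harmonization
          untouched", {
  st <- simulate_mr_study(50, beta_true = 0.2, seed = 33)
  f <- f_statistic(st$exposure$beta, st$exposure$se)
  expect_gt(mean(f), 60)   # noisy observed F around the 80-120 target band
  expect_lt(mean(f), 160)
  pairs <- harmonize_tables(st$exposure, st$outcome)
  expect_equal(nrow(usable_pairs(pairs)), 50L)  # generator self-consistency
  expect_true(all(st$exposure$pos >= st$locus$start &
                    st$exposure$pos <= st$locus$end))
  st2 <- simulate_mr_study(50, beta_true = 0.2, seed = 33)
  expect_identical(st2$exposure$beta, st$exposure$beta)
})

test_that("single-instrument studies route to Wald with sensitivity methods
          not estimable", {
  st <- simulate_mr_study(1, beta_true = 0.3, seed = 8)
  pairs <- usable_pairs(harmonize_tables(st$exposure, st$outcome))
  res <- mr_all_methods(pairs, n_boot = 10)
  expect_equal(res$method[1], "wald")
  expect_equal(res$status, c("ok", "not_estimable", "not_estimable"))
})

test_that("proteomics intensities carry the requested shifts and masks", {
  sim <- simulate_proteomics(n_case = 30, n_control = 30, n_proteins = 10,
                             effect_map = c(ECM1 = 0.633),
                             missing_proteins = c("SPON1", "AFAP1"),
                             sigma = 0.2, seed = 11)
  expect_equal(dim(sim$intensities), c(10L, 60L))
  expect_true(all(is.na(sim$intensities["SPON1", ])))
  lfc <- mean(log2(sim$intensities["ECM1", sim$groups == "case"])) -
    mean(log2(sim$intensities["ECM1", sim$groups == "control"]))
  expect_equal(lfc, 0.633, tolerance = 0.2)
  sim2 <- simulate_proteomics(n_case = 30, n_control = 30, n_proteins = 10,
                              effect_map = c(ECM1 = 0.633),
                              missing_proteins = c("SPON1", "AFAP1"),
                              sigma = 0.2, seed = 11)
  expect_identical(sim$intensities, sim2$intensities)
})

test_that("scan study fixtures wire exposures, loci, LD and outcome
          coherently", {
  study <- simulate_scan_study(n_traits = 6, k_instruments = 2,
                               n_causal = 2, seed = 21)
  expect_named(study$exposures, c("platform_A", "platform_B"))
  for (pl in names(study$exposures)) {
    for (tab in study$exposures[[pl]]) {
      tid <- attr(tab, "trait_id")
      expect_true(tid %in% study$loci$gene_id)
      expect_true(all(tab$variant_id %in% rownames(study$ld[[tid]])))
      expect_true(all(tab$variant_id %in% study$outcome$variant_id))
    }
  }
  expect_equal(sum(study$truth$beta_true != 0), 2L)
})
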