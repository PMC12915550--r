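# MR estimators: Wald ratio, IVW, Egger, weighted median, BH adjustment.

test_that("Wald ratio has the stated limits and guards degenerate input", {
  p <- make_pairs(1, 0.5, sx = 1e-12, sy = 0.1)
  r <- wald_ratio(p)
  expect_equal(r$estimate, 0.5)
  expect_equal(r$se, 0.1, tolerance = 1e-6)
  null <- wald_ratio(make_pairs(0.2, 0))
  expect_equal(null$estimate, 0)
  expect_equal(null$or_point, 1)
  expect_error(wald_ratio(make_pairs(0, 0.1)), "degenerate")
})

test_that("Wald delta-method se matches Monte-Carlo error propagation", {
  r <- wald_ratio(make_pairs(0.2, 0.1, sx = 0.02, sy = 0.05))
  set.seed(1)
  n <- 1e6
  draws <- rnorm(n, 0.1, 0.05) / rnorm(n, 0.2, 0.02)
  expect_equal(r$se, sd(draws), tolerance = 0.02)
  expect_equal(r$or_point, exp(r$estimate))
  expect_lt(r$or_lo95, r$or_point)
  expect_gt(r$or_hi95, r$or_point)
})

test_that("IVW reduces to the Wald ratio at k = 1 and averages equal weights", {
  p1 <- make_pairs(0.2, 0.06, sx = 0.02, sy = 0.05)
  expect_equal(ivw(p1, "fixed")[, c("estimate", "se", "pval")],
               wald_ratio(p1, first_order_only = TRUE)[, c("estimate", "se", "pval")])
  p2 <- make_pairs(c(1, 1), c(0.2, 0.4), sy = c(0.1, 0.1))
  expect_equal(ivw(p2, "fixed")$estimate, 0.3)
})

test_that("IVW equals the WLS-through-origin oracle to 1e-10", {
  set.seed(21)
  bx <- rnorm(10, 0.2, 0.05)
  by <- 0.3 * bx + rnorm(10, 0, 0.04)
  sy <- runif(10, 0.02, 0.08)
  pairs <- make_pairs(bx, by, sy = sy)
  want <- oracle_ivw_wls(bx, by, sy)
  expect_equal(ivw(pairs, "fixed")$estimate, want$estimate, tolerance = 1e-10)
  expect_equal(ivw(pairs, "fixed")$se, want$se_fixed, tolerance = 1e-10)
  expect_equal(ivw(pairs, "multiplicative_random")$se, want$se_mre,
               tolerance = 1e-10)
})

test_that("IVW is invariant to ordering and joint sign flips", {
  set.seed(22)
  bx <- rnorm(8, 0.2, 0.05); by <- 0.3 * bx + rnorm(8, 0, 0.03)
  pairs <- make_pairs(bx, by, sy = runif(8, 0.02, 0.08))
  ref <- ivw(pairs)
  expect_equal(ivw(pairs[sample(8), ])$estimate, ref$estimate)
  flip <- pairs
  flip$beta_exp[1:3] <- -flip$beta_exp[1:3]
  flip$beta_out[1:3] <- -flip$beta_out[1:3]
  expect_equal(ivw(flip)$estimate, ref$estimate)
  expect_equal(ivw(flip)$se, ref$se)
})

test_that("Egger fits noiseless pairs exactly and reports sparse sets", {
  set.seed(23)
  bx <- runif(5, 0.1, 0.3)
  pairs <- make_pairs(bx, 0.4 * bx, sy = rep(0.05, 5))
  fit <- egger(pairs)
  expect_equal(fit$estimate, 0.4, tolerance = 1e-10)
  expect_equal(fit$egger_intercept, 0, tolerance = 1e-10)

  sparse <- egger(make_pairs(c(0.2, 0.3), c(0.1, 0.1)))
  expect_equal(sparse$status, "not_estimable")
  expect_match(sparse$reason, "insufficient instruments")
  expect_true(is.na(sparse$estimate))
})

test_that("weighted median reduces to the ordinary median with equal weights
          and follows concentrated weight", {
  eq <- make_pairs(c(1, 1, 1), c(0.1, 0.2, 0.9), sy = c(1, 1, 1))
  expect_equal(weighted_median(eq, n_boot = 50, seed = 1)$estimate, 0.2)
  conc <- make_pairs(c(1, 1, 1), c(0.1, 0.2, 0.9), sy = c(1, 1, 1e-4))
  expect_equal(weighted_median(conc, n_boot = 50, seed = 1)$estimate, 0.9,
               tolerance = 1e-3)
  expect_equal(weighted_median(eq[1:2, ], n_boot = 10)$status, "not_estimable")
})

test_that("weighted-median bootstrap se converges to the re-estimation sd", {
  set.seed(31)
  bx <- rnorm(10, 0.25, 0.04)
  by <- 0.3 * bx + rnorm(10, 0, 0.03)
  pairs <- make_pairs(bx, by, sx = rep(0.01, 10), sy = rep(0.04, 10))
  est <- weighted_median(pairs, n_boot = 2000, seed = 7)
  # independent large-sample re-estimation of the same parametric bootstrap
  redraws <- replicate(50000, {
    bxs <- rnorm(10, pairs$beta_exp, pairs$se_exp)
    bys <- rnorm(10, pairs$beta_out, pairs$se_out)
    r <- bys / bxs
    w <- bxs^2 / pairs$se_out^2
    ord <- order(r)
    r <- r[ord]; w <- w[ord] / sum(w)
    cs <- cumsum(w) - w / 2
    if (cs[1] >= 0.5) r[1]
    else if (cs[10] <= 0.5) r[10]
    else {
      i <- max(which(cs < 0.5))
      r[i] + (r[i + 1] - r[i]) * (0.5 - cs[i]) / (cs[i + 1] - cs[i])
    }
  })
  expect_equal(est$se, sd(redraws), tolerance = 0.05)
})

test_that("BH adjustment matches the hand-computed step-up example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("mr_all_methods routes by instrument count", {
  one <- make_pairs(0.2, 0.1)
  res1 <- mr_all_methods(one, trait_id = "T")
  expect_equal(res1$method, c("wald", "egger", "weighted_median"))
  expect_equal(res1$status, c("ok", "not_estimable", "not_estimable"))
  set.seed(8)
  five <- make_pairs(rnorm(5, 0.2, 0.02), rnorm(5, 0.06, 0.02))
  res5 <- mr_all_methods(five, trait_id = "T", n_boot = 50, seed = 2)
  expect_equal(res5$method, c("ivw_mre", "egger", "weighted_median"))
  expect_true(all(res5$status == "ok"))
  expect_true(all(res5$n_snp == 5L))
})
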