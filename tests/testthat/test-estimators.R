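test_that("Wald ratio arithmetic, SEs and the null case are exact", {
  est <- mr_wald_ratio(0.5, 0.01, 0.25, 0.02)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.04)
  expect_equal(est$odds_ratio, exp(0.5))
  null <- mr_wald_ratio(0.5, 0.01, 0, 0.02)
  expect_equal(null$beta, 0)
  expect_equal(null$odds_ratio, 1)
  so <- mr_wald_ratio(0.5, 0.01, 0.25, 0.02, second_order = TRUE)
  expect_equal(so$se, sqrt(0.02^2 / 0.5^2 + 0.25^2 * 0.01^2 / 0.5^4))
  expect_error(mr_wald_ratio(0, 0.01, 0.1, 0.02), "undefined ratio")
})

test_that("IVW pools ratios by inverse variance, variants agree on the point", {
  # consensus: all ratios equal
  h <- make_hset(c(0.1, 0.2, 0.4), 0.01, c(0.03, 0.06, 0.12), 0.02)
  expect_equal(mr_ivw(h)$beta, 0.3)
  expect_equal(mr_ivw(h, "fixed")$beta, 0.3)
  # two equal-weight instruments: symmetric mean
  h2 <- make_hset(c(1, 1), 0.01, c(0.2, 0.4), c(0.05, 0.05))
  expect_equal(mr_ivw(h2)$beta, 0.3)
  # single instrument delegates to the Wald ratio
  h1 <- make_hset(0.5, 0.01, 0.25, 0.02)
  expect_equal(mr_ivw(h1)$beta, 0.5)
  expect_identical(mr_ivw(h1)$method, "wald_ratio")
  expect_error(mr_ivw(make_hset(numeric(0), numeric(0), numeric(0), numeric(0))),
               "empty")
})

test_that("fixed and multiplicative-random IVW differ only in the SE", {
  for (s in 1:10) {
    h <- scenario_hset(n_snps = 15, seed = 500 + s,
                       invalid_fraction = 0.2, pleiotropy_mean = 0.05,
                       pleiotropy_sd = 0.05)
    f <- mr_ivw(h, "fixed")
    m <- mr_ivw(h, "multiplicative_random")
    expect_identical(f$beta, m$beta)
    q <- attr(f, "cochran_q"); dfree <- attr(f, "df")
    if (q > dfree) expect_gt(m$se, f$se) else expect_equal(m$se, f$se)
  }
})

test_that("negating all exposure betas negates the IVW estimate", {
  h <- scenario_hset(n_snps = 25, seed = 77)
  h_neg <- h
  h_neg$beta_exp <- -h_neg$beta_exp
  expect_equal(mr_ivw(h_neg)$beta, -mr_ivw(h)$beta)
})

test_that("median estimators match hand-derived values", {
  h <- make_hset(c(1, 1, 1), 0.01, c(0.1, 0.3, 0.9), c(0.05, 0.05, 0.05))
  expect_equal(mr_simple_median(h, nboot = 0)$beta, 0.3)
  # equal weights reduce the weighted median to the simple median
  expect_equal(mr_weighted_median(h, nboot = 0)$beta, 0.3)
  # consensus ratios: bootstrap SE is small and the estimate exact
  hc <- make_hset(rep(1, 5), 0.001, rep(0.25, 5), 0.001)
  est <- mr_simple_median(hc, nboot = 200, seed = 1)
  expect_equal(est$beta, 0.25)
  expect_lt(est$se, 0.01)
  expect_error(mr_simple_median(make_hset(1, 0.01, 0.1, 0.02)),
               "insufficient instruments")
})

test_that("weighted median interpolates the cumulative-weight rule", {
  # ratios {0, 1} with normalized weights {0.9, 0.1}: cumulative midpoints
  # at 0.45 and 0.95, so the 0.5 crossing interpolates to 0.1
  expect_equal(weighted_median(c(0, 1), c(0.9, 0.1)), 0.1)
  # via the estimator: se_out chosen so the first-order weights are 0.9/0.1
  h <- make_hset(c(1, 1), 0.001, c(0, 1), c(1 / 3, 1))
  est <- mr_weighted_median(rbind(h, h[2, ]), nboot = 0)
  # three instruments needed; duplicate the light one: weights 9:1:1
  w <- c(9, 1, 1) / 11
  p <- cumsum(w) - w / 2
  expect_equal(est$beta, approx(p, c(0, 1, 1), xout = 0.5)$y)
})

test_that("Egger regression recovers exact linear structures", {
  bx <- c(0.05, 0.08, 0.12, 0.2)
  h <- make_hset(bx, 0.01, 0.3 * bx, 0.02)
  e <- mr_egger(h)
  expect_equal(e$beta[e$method == "egger_slope"], 0.3)
  expect_equal(e$beta[e$method == "egger_intercept"], 0, tolerance = 1e-12)
  h2 <- make_hset(bx, 0.01, 0.3 * bx + 0.05, 0.02)
  e2 <- mr_egger(h2)
  expect_equal(e2$beta[e2$method == "egger_slope"], 0.3)
  expect_equal(e2$beta[e2$method == "egger_intercept"], 0.05)
  expect_error(mr_egger(make_hset(rep(0.1, 4), 0.01, rnorm(4), 0.02)),
               "collinearity")
})

test_that("Egger orients instruments to non-negative exposure effects", {
  bx <- c(0.05, -0.08, 0.12, -0.2)
  h <- make_hset(bx, 0.01, 0.3 * bx + sign(bx) * 0.05, 0.02)
  e <- mr_egger(h)
  expect_equal(e$beta[e$method == "egger_slope"], 0.3)
  expect_equal(e$beta[e$method == "egger_intercept"], 0.05)
})

test_that("heterogeneity diagnostics follow the Q/I2 identities", {
  # identical ratios: Q = 0, I2 = 0
  h <- make_hset(c(0.1, 0.2, 0.4), 0.01, c(0.03, 0.06, 0.12), 0.02)
  d <- mr_diagnostics(h)
  expect_equal(d$cochran_q, 0, tolerance = 1e-20)
  expect_equal(d$i_squared, 0)
  expect_equal(d$df, 2)
  expect_true(d$unimportant_heterogeneity)
  # Q p-value matches the chi-squared reference
  h2 <- scenario_hset(n_snps = 10, seed = 11)
  d2 <- mr_diagnostics(h2)
  expect_equal(d2$q_pval, pchisq(d2$cochran_q, d2$df, lower.tail = FALSE))
  expect_equal(d2$i_squared, i_squared(d2$cochran_q, d2$df))
})

test_that("mean F statistics are exact and warn on weak instruments", {
  expect_equal(mr_mean_f(make_hset(0.1, 0.01, 0, 0.02)), 100)
  expect_equal(mr_mean_f(make_hset(c(0.05, 0.07), c(0.01, 0.01), 0, 0.02)),
               mean(c(25, 49)))
  expect_warning(mr_mean_f(make_hset(0.02, 0.01, 0, 0.02)), "weak instruments")
})

test_that("instruments selected at 5e-8 all exceed the F ~ 29.7 bound", {
  pair <- generate_gwas_pair(mr_scenario(n_snps = 100, seed = 12))
  sel <- select_instruments(pair$exposure, 5e-8)
  f <- (sel$beta / sel$se)^2
  expect_true(all(f > qchisq(5e-8, 1, lower.tail = FALSE) - 1e-9))
  expect_gt(min(f), 29.7)
})

test_that("scatter export yields per-SNP points plus one line per method", {
  h <- scenario_hset(n_snps = 3, seed = 13)
  est <- rbind(mr_ivw(h), mr_egger(h))
  tab <- export_scatter_data(h, est)
  expect_equal(sum(tab$row_type == "point"), 3)
  expect_equal(sum(tab$row_type == "line"), 2) # ivw + egger slope
  ivw_line <- tab[tab$row_type == "line" & tab$method == "ivw_mre", ]
  expect_equal(ivw_line$intercept, 0)
  egger_line <- tab[tab$row_type == "line" & tab$method == "egger_slope", ]
  expect_false(egger_line$intercept == 0)
  expect_equal(sum(export_scatter_data(h)$row_type == "line"), 0)
})
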