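test_that("standard errors follow the allele-frequency/sample-size formula", {
  # the generator's SE law pinned at f = 0.5, n = 10000
  sc <- mr_scenario(n_snps = 200, n_exposure = 10000, n_outcome = 10000,
                    eaf_range = c(0.4999, 0.5001), seed = 61)
  pair <- generate_gwas_pair(sc)
  expect_equal(mean(pair$exposure$se), 1 / sqrt(5000), tolerance = 1e-4)
})

test_that("generation is reproducible from the recorded seed", {
  a <- generate_gwas_pair(mr_scenario(seed = 62))
  b <- generate_gwas_pair(mr_scenario(seed = 62))
  expect_identical(as.data.frame(a$exposure), as.data.frame(b$exposure))
  expect_identical(as.data.frame(a$outcome), as.data.frame(b$outcome))
  expect_identical(a$truth, b$truth)
  c2 <- generate_gwas_pair(mr_scenario(seed = 63))
  expect_false(identical(a$exposure$beta, c2$exposure$beta))
})

test_that("the invalid-instrument count and pleiotropy law are honored", {
  sc <- mr_scenario(n_snps = 50, invalid_fraction = 0.4,
                    pleiotropy_mean = 0.1, pleiotropy_sd = 0.01, seed = 64)
  tr <- generate_gwas_pair(sc)$truth
  expect_equal(sum(!tr$valid), round(0.4 * 50))
  expect_true(all(tr$alpha[tr$valid] == 0))
  expect_true(all(tr$alpha[!tr$valid] != 0))
  expect_error(mr_scenario(invalid_fraction = 1), "invalid_fraction")
})

test_that("true per-SNP F statistics respect the configured range", {
  sc <- mr_scenario(n_snps = 300, f_range = c(30, 300), seed = 65)
  pair <- generate_gwas_pair(sc)
  f_true <- (pair$truth$gamma * sqrt(2 * pair$truth$eaf *
               (1 - pair$truth$eaf) * sc$n_exposure))^2
  expect_true(all(f_true >= 30 & f_true <= 300))
  # selection at genome-wide significance retains most instruments
  sel <- select_instruments(pair$exposure)
  expect_gt(nrow(sel) / nrow(pair$exposure), 0.8)
})

test_that("confounding inflation scales outcome chi-squared multiplicatively", {
  base <- mr_scenario(n_snps = 2000, beta_causal = 0, seed = 66)
  infl <- mr_scenario(n_snps = 2000, beta_causal = 0, seed = 66,
                      confounding_inflation = 1.5)
  chi_base <- (generate_gwas_pair(base)$outcome$beta /
                 generate_gwas_pair(base)$outcome$se)^2
  chi_infl <- (generate_gwas_pair(infl)$outcome$beta /
                 generate_gwas_pair(infl)$outcome$se)^2
  expect_equal(chi_infl, 1.5 * chi_base, tolerance = 1e-12)
})

test_that("the block LD generator drives clumping as designed", {
  sc <- mr_scenario(n_snps = 30, seed = 67)
  pair <- generate_gwas_pair(sc)
  # block_size 1: everything independent, clumping keeps all significant SNPs
  ld1 <- generate_ld_reference(sc, block_size = 1, within_block_r2 = 0)
  sel <- select_instruments(pair$exposure)
  expect_equal(nrow(clump_instruments(sel, ld1)), nrow(sel))
  # blocks of 5 at r2 = 0.5 with threshold 0.001: one survivor per block
  ld5 <- generate_ld_reference(sc, block_size = 5, within_block_r2 = 0.5)
  all30 <- sumstats_table(as.data.frame(pair$exposure))
  clumped <- clump_instruments(all30, ld5, r2_threshold = 0.001)
  expect_equal(nrow(clumped), 6)
  blocks <- (match(clumped$variant_id, pair$exposure$variant_id) - 1) %/% 5
  expect_equal(sort(blocks), 0:5)
  # symmetry of generated pairs
  expect_equal(ld_r2(ld5, "rs000001", "rs000002"),
               ld_r2(ld5, "rs000002", "rs000001"))
})

test_that("LDSC input generators match their stated expectations", {
  null <- generate_ldsc_input(20000, h2 = 0, n = 50000, intercept_true = 1,
                              seed = 68)
  expect_equal(mean(null$chi2), 1, tolerance = 0.05)
  tr <- attr(null, "truth")
  expect_equal(tr$h2, 0)
  pr <- generate_ldsc_pair(20000, 0.2, 0.2, rg = 1, n1 = 5e4, n2 = 5e4,
                           seed = 69)
  expect_equal(cor(pr$z1, pr$z2), 1, tolerance = 0.05)
})
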