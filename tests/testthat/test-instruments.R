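test_that("instrument selection applies a strict p-value threshold", {
  df <- toy_sumstats_df()
  df$pval <- c(4.9e-8, 5e-8, 1e-3)
  tab <- sumstats_table(df)
  sel <- select_instruments(tab, p_threshold = 5e-8)
  expect_identical(sel$variant_id, "rs1")
  df$pval <- rep(0.5, 3)
  expect_warning(sel0 <- select_instruments(sumstats_table(df)), "no variants")
  expect_equal(nrow(sel0), 0)
})

test_that("greedy clumping follows the p-value order and r2 threshold", {
  df <- data.frame(variant_id = c("SNP1", "SNP2", "SNP3"),
                   effect_allele = "A", other_allele = "G",
                   beta = 0.1, se = 0.01,
                   pval = c(1e-10, 1e-9, 1e-8), stringsAsFactors = FALSE)
  tab <- sumstats_table(df)
  ld <- ld_reference(data.frame(
    id_a = c("SNP1", "SNP1", "SNP2"), id_b = c("SNP2", "SNP3", "SNP3"),
    r2 = c(0.5, 0.0001, 0)))
  out <- clump_instruments(tab, ld, r2_threshold = 0.001)
  expect_identical(sort(out$variant_id), c("SNP1", "SNP3"))
})

test_that("independent candidates are all retained and absences are audited", {
  df <- toy_sumstats_df()
  tab <- sumstats_table(df)
  ld <- ld_reference(data.frame(id_a = "rs1", id_b = "rs2", r2 = 0))
  out <- clump_instruments(tab, ld)
  expect_equal(nrow(out), 3)
  expect_equal(attr(out, "clump_audit")$n_not_in_ld_reference, 1) # rs3
})

test_that("clumping ties break lexicographically and ignore row order", {
  df <- data.frame(variant_id = c("rsB", "rsA"),
                   effect_allele = "A", other_allele = "G",
                   beta = 0.1, se = 0.01, pval = c(1e-10, 1e-10),
                   stringsAsFactors = FALSE)
  ld <- ld_reference(data.frame(id_a = "rsA", id_b = "rsB", r2 = 0.9))
  out1 <- clump_instruments(sumstats_table(df), ld)
  out2 <- clump_instruments(sumstats_table(df[2:1, ]), ld)
  expect_identical(out1$variant_id, "rsA")
  expect_identical(out2$variant_id, "rsA")
})

make_pair_tables <- function(exp_alleles, out_alleles, beta_out = 0.2,
                             eaf_exp = 0.3, eaf_out = 0.3) {
  exp <- sumstats_table(data.frame(
    variant_id = "rs1", effect_allele = exp_alleles[1],
    other_allele = exp_alleles[2], eaf = eaf_exp,
    beta = 0.1, se = 0.01, pval = 1e-10, stringsAsFactors = FALSE))
  out <- sumstats_table(data.frame(
    variant_id = "rs1", effect_allele = out_alleles[1],
    other_allele = out_alleles[2], eaf = eaf_out,
    beta = beta_out, se = 0.02, pval = 0.01, stringsAsFactors = FALSE))
  list(exp = exp, out = out)
}

test_that("harmonization keeps, flips, complements and drops correctly", {
  # identical orientation -> kept, beta unchanged
  p <- make_pair_tables(c("A", "G"), c("A", "G"))
  h <- harmonize(p$exp, p$out)
  expect_identical(h$action, "kept")
  expect_equal(h$beta_out, 0.2)
  # swapped orientation -> flipped, beta negated, eaf complemented
  p <- make_pair_tables(c("A", "G"), c("G", "A"), eaf_out = 0.7)
  h <- harmonize(p$exp, p$out)
  expect_identical(h$action, "flipped")
  expect_equal(h$beta_out, -0.2)
  expect_equal(h$eaf_out, 0.3)
  # opposite strand, same orientation after complement -> kept
  p <- make_pair_tables(c("A", "G"), c("T", "C"))
  h <- harmonize(p$exp, p$out)
  expect_identical(h$action, "kept")
  expect_equal(h$beta_out, 0.2)
  # irreconcilable alleles -> dropped with reason, never kept
  p <- make_pair_tables(c("A", "G"), c("A", "C"))
  h <- harmonize(p$exp, p$out)
  expect_equal(nrow(h), 0)
  expect_identical(attr(h, "dropped")$action, "dropped_incompatible")
  # absent from outcome -> dropped_missing
  p <- make_pair_tables(c("A", "G"), c("A", "G"))
  out2 <- p$out
  out2$variant_id <- "rs_other"
  h <- harmonize(p$exp, out2)
  expect_identical(attr(h, "dropped")$action, "dropped_missing")
})

test_that("palindromic variants follow the policy", {
  # frequency near 0.5 is uninformative -> dropped under infer_by_eaf
  p <- make_pair_tables(c("A", "T"), c("A", "T"), eaf_exp = 0.5, eaf_out = 0.5)
  h <- harmonize(p$exp, p$out, palindromic_policy = "infer_by_eaf")
  expect_identical(attr(h, "dropped")$action, "dropped_palindromic")
  # informative concordant frequencies -> kept
  p <- make_pair_tables(c("A", "T"), c("A", "T"), eaf_exp = 0.2, eaf_out = 0.25)
  h <- harmonize(p$exp, p$out)
  expect_identical(h$action, "kept")
  expect_equal(h$beta_out, 0.2)
  # discordant frequencies signal a strand flip -> beta negated
  p <- make_pair_tables(c("A", "T"), c("A", "T"), eaf_exp = 0.2, eaf_out = 0.8)
  h <- harmonize(p$exp, p$out)
  expect_identical(h$action, "flipped")
  expect_equal(h$beta_out, -0.2)
  # drop policy removes all palindromic variants
  p <- make_pair_tables(c("C", "G"), c("C", "G"), eaf_exp = 0.2, eaf_out = 0.2)
  h <- harmonize(p$exp, p$out, palindromic_policy = "drop")
  expect_identical(attr(h, "dropped")$action, "dropped_palindromic")
  # missing frequency falls back to drop
  p <- make_pair_tables(c("A", "T"), c("A", "T"), eaf_exp = NA, eaf_out = 0.2)
  h <- harmonize(p$exp, p$out)
  expect_equal(nrow(h), 0)
})

test_that("double-flipping outcome alleles leaves estimator inputs unchanged", {
  pair <- generate_gwas_pair(mr_scenario(n_snps = 20, seed = 42))
  h1 <- harmonize(pair$exposure, pair$outcome)
  flipped <- as.data.frame(pair$outcome)
  tmp <- flipped$effect_allele
  flipped$effect_allele <- flipped$other_allele
  flipped$other_allele <- tmp
  flipped$beta <- -flipped$beta
  flipped$eaf <- 1 - flipped$eaf
  h2 <- harmonize(pair$exposure, sumstats_table(flipped))
  cols <- c("variant_id", "beta_exp", "se_exp", "beta_out", "se_out")
  expect_equal(h1[cols], h2[cols])
})

test_that("harmonization is idempotent", {
  pair <- generate_gwas_pair(mr_scenario(n_snps = 20, seed = 43))
  h1 <- harmonize(pair$exposure, pair$outcome)
  # rebuild an outcome table already on the exposure allele frame
  out2 <- as.data.frame(pair$exposure)
  out2$beta <- h1$beta_out[match(out2$variant_id, h1$variant_id)]
  out2$se <- h1$se_out[match(out2$variant_id, h1$variant_id)]
  out2$eaf <- h1$eaf_out[match(out2$variant_id, h1$variant_id)]
  out2$pval <- 0.5
  h2 <- harmonize(pair$exposure, sumstats_table(out2))
  expect_true(all(h2$action == "kept"))
  cols <- c("variant_id", "beta_exp", "beta_out", "se_out")
  expect_equal(h1[cols], h2[cols])
})
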