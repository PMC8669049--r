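#!/usr/bin/env Rscript
# Simulate the study's summary-level inputs: three sleep-trait-like
# exposures (instrument counts mirroring genome-wide-significant panels:
# 49, 42 and 41 SNPs), one binary outcome per exposure panel on the
# log-odds scale, and a block LD reference for clumping.  Everything is
# written as plain TSV under results/study/data/.

library(mrkit)

outdir <- "results/study/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

scenarios <- list(
  insomnia = mr_scenario(n_snps = 49, beta_causal = 0.16, seed = 2101,
                         invalid_fraction = 0.1, pleiotropy_mean = 0.02,
                         pleiotropy_sd = 0.05),
  napping  = mr_scenario(n_snps = 42, beta_causal = 0.0, seed = 2102),
  snoring  = mr_scenario(n_snps = 41, beta_causal = 0.0, seed = 2103,
                         invalid_fraction = 0.2, pleiotropy_mean = 0,
                         pleiotropy_sd = 0.08))

truths <- list()
for (nm in names(scenarios)) {
  pair <- generate_gwas_pair(scenarios[[nm]])
  write_sumstats(pair$exposure, file.path(outdir, paste0(nm, ".tsv")))
  write_sumstats(pair$outcome, file.path(outdir, paste0("ibd_", nm, ".tsv")))
  truths[[nm]] <- pair$truth
  cat(sprintf("%-9s %2d instruments, true log-OR %.2f, %d invalid\n",
              nm, nrow(pair$exposure), scenarios[[nm]]$beta_causal,
              sum(!pair$truth$valid)))
}

# one LD reference covering the shared variant ids (blocks of 1 = fully
# independent panels, as clumped instrument sets are)
ld <- generate_ld_reference(scenarios$insomnia, block_size = 1,
                            within_block_r2 = 0)
ids <- sprintf("rs%06d", 1:49)
utils::write.table(data.frame(id_a = ids, id_b = ids, r2 = 1),
                   file.path(outdir, "ld.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

truth_tab <- do.call(rbind, Map(cbind, trait = names(truths), truths))
utils::write.table(truth_tab, file.path(outdir, "truth.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("inputs written to", outdir, "\n")
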