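# in-code fixtures shared across the suite

# a small well-formed sumstats data.frame (3 SNPs)
toy_sumstats_df <- function() {
  data.frame(
    variant_id = c("rs1", "rs2", "rs3"),
    chrom = c("1", "2", "3"), pos = c(1000, 2000, 3000),
    effect_allele = c("A", "C", "G"), other_allele = c("G", "T", "A"),
    eaf = c(0.3, 0.6, NA), beta = c(0.10, -0.05, 0.20),
    se = c(0.01, 0.02, 0.03), pval = c(1e-20, 1e-9, 1e-12),
    n = c(10000, 10000, NA), stringsAsFactors = FALSE)
}

toy_sumstats <- function(...) sumstats_table(toy_sumstats_df(), ...)

write_toy_file <- function(df = toy_sumstats_df(), path = tempfile(fileext = ".tsv")) {
  names(df) <- unname(default_column_map()[names(df)])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

# a hand-built harmonized set from explicit effect vectors
make_hset <- function(beta_exp, se_exp, beta_out, se_out) {
  structure(data.frame(
    variant_id = sprintf("s%d", seq_along(beta_exp)),
    beta_exp = beta_exp, se_exp = se_exp,
    beta_out = beta_out, se_out = se_out,
    action = rep("kept", length(beta_exp)), stringsAsFactors = FALSE),
    class = c("harmonized_set", "data.frame"))
}

# harmonized set drawn from a synthetic scenario
scenario_hset <- function(...) {
  pair <- generate_gwas_pair(mr_scenario(...))
  harmonize(pair$exposure, pair$outcome)
}
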