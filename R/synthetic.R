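# Synthetic GWAS summary statistics with recorded ground truth.
#
# Structural model per SNP j with exposure effect gamma_j and direct
# (pleiotropic) outcome effect alpha_j:
#   se_exp_j  = 1 / sqrt(2 f_j (1 - f_j) n_exposure)
#   se_out_j  analogous with n_outcome
#   beta_exp_j ~ Normal(gamma_j, se_exp_j^2)
#   beta_out_j ~ Normal(beta_causal * gamma_j + alpha_j, se_out_j^2)
# Valid instruments have alpha_j = 0; exactly round(invalid_fraction *
# n_snps) instruments are invalid.  A confounding multiplier > 1 inflates
# outcome chi-squared statistics (z scaled by its square root), emulating
# uncorrected stratification.  Binary outcomes are handled directly on the
# log-odds scale (beta = ln OR).

#' Define a synthetic MR scenario
#'
#' Defaults describe a well-powered two-sample design: 50 independent
#' instruments with per-SNP F uniform in 30-300 (a genome-wide-significant
#' panel), 50,000 samples per trait, allele frequencies uniform on
#' (0.05, 0.95), no pleiotropy and no confounding inflation.
#'
#' @param n_snps number of instruments.
#' @param beta_causal true causal effect (log-odds per exposure unit).
#' @param f_range per-SNP F statistic range for the true exposure effects
#'   (drawn uniformly; `gamma_j = sqrt(F_j) * se_exp_j`).
#' @param pleiotropy_mean,pleiotropy_sd normal law for the direct effects
#'   `alpha_j` of invalid instruments.
#' @param invalid_fraction fraction of instruments with `alpha_j != 0`, in
#'   \[0, 1).
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param eaf_range support of the uniform effect-allele-frequency law.
#' @param confounding_inflation multiplier >= 1 on outcome chi-squared.
#' @param seed RNG seed recorded with the scenario.
#' @return an `mr_scenario` list.
#' @export
mr_scenario <- function(n_snps = 50, beta_causal = 0.2,
                        f_range = c(30, 300),
                        pleiotropy_mean = 0, pleiotropy_sd = 0,
                        invalid_fraction = 0,
                        n_exposure = 50000, n_outcome = 50000,
                        eaf_range = c(0.05, 0.95),
                        confounding_inflation = 1, seed = 1) {
  stopifnot(n_snps >= 1, invalid_fraction >= 0, confounding_inflation >= 1,
            n_exposure > 0, n_outcome > 0,
            eaf_range[1] > 0, eaf_range[2] < 1, f_range[1] > 0)
  if (invalid_fraction >= 1) stop("invalid_fraction must be < 1")
  structure(list(n_snps = as.integer(n_snps), beta_causal = beta_causal,
                 f_range = f_range, pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 invalid_fraction = invalid_fraction,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 eaf_range = eaf_range,
                 confounding_inflation = confounding_inflation,
                 seed = as.integer(seed)),
            class = "mr_scenario")
}

# non-palindromic ordered allele pairs; the generator emits both tables on
# the same strand and orientation, so harmonization keeps every variant
NONPALINDROMIC_PAIRS <- matrix(c("A","C", "A","G", "C","A", "C","T",
                                 "G","A", "G","T", "T","C", "T","G"),
                               ncol = 2, byrow = TRUE)

#' Generate a paired exposure/outcome summary-statistics set
#'
#' @param scenario an [mr_scenario()].
#' @return list with elements `exposure` and `outcome` (`sumstats` tables)
#'   and `truth` (per-SNP latent values: `gamma`, `alpha`, `valid`, plus
#'   the scenario).  Re-running with the same scenario reproduces the
#'   tables exactly.
#' @export
generate_gwas_pair <- function(scenario) {
  stopifnot(inherits(scenario, "mr_scenario"))
  s <- scenario
  with_seed(s$seed, {
    n <- s$n_snps
    f <- stats::runif(n, s$eaf_range[1], s$eaf_range[2])
    se_exp <- 1 / sqrt(2 * f * (1 - f) * s$n_exposure)
    se_out <- 1 / sqrt(2 * f * (1 - f) * s$n_outcome)
    f_stat <- stats::runif(n, s$f_range[1], s$f_range[2])
    gamma <- sqrt(f_stat) * se_exp
    n_invalid <- round(s$invalid_fraction * n)
    invalid <- if (n_invalid > 0) sample.int(n, n_invalid) else integer(0)
    alpha <- rep(0, n)
    alpha[invalid] <- stats::rnorm(n_invalid, s$pleiotropy_mean, s$pleiotropy_sd)

    beta_exp <- stats::rnorm(n, gamma, se_exp)
    beta_out <- stats::rnorm(n, s$beta_causal * gamma + alpha, se_out)
    if (s$confounding_inflation > 1) {
      beta_out <- beta_out * sqrt(s$confounding_inflation)
    }
    pair_idx <- sample.int(nrow(NONPALINDROMIC_PAIRS), n, replace = TRUE)
    ids <- sprintf("rs%06d", seq_len(n))
    base <- data.frame(variant_id = ids,
                       chrom = as.character(rep_len(1:22, n)),
                       pos = seq_len(n) * 10000L,
                       effect_allele = NONPALINDROMIC_PAIRS[pair_idx, 1],
                       other_allele = NONPALINDROMIC_PAIRS[pair_idx, 2],
                       eaf = f, stringsAsFactors = FALSE)
    pfun <- function(b, se) pmax(2 * stats::pnorm(-abs(b / se)), 1e-320)

    exposure <- base
    exposure$beta <- beta_exp
    exposure$se <- se_exp
    exposure$pval <- pfun(beta_exp, se_exp)
    exposure$n <- s$n_exposure
    outcome <- base
    outcome$beta <- beta_out
    outcome$se <- se_out
    outcome$pval <- pfun(beta_out, se_out)
    outcome$n <- s$n_outcome

    list(exposure = sumstats_table(exposure, trait_name = "exposure",
                                   trait_type = "continuous",
                                   source = "synthetic"),
         outcome = sumstats_table(outcome, trait_name = "outcome",
                                  trait_type = "binary",
                                  source = "synthetic"),
         truth = structure(data.frame(variant_id = ids, eaf = f,
                                      gamma = gamma, alpha = alpha,
                                      valid = alpha == 0,
                                      stringsAsFactors = FALSE),
                           scenario = s))
  })
}

#' Generate a block-structured LD reference
#'
#' Partitions the scenario's SNPs into consecutive blocks; within-block
#' pairs share a single r2, cross-block pairs are independent (absent, i.e.
#' r2 = 0).
#'
#' @param scenario an [mr_scenario()] (only `n_snps` is used).
#' @param block_size SNPs per block (>= 1).
#' @param within_block_r2 pairwise r2 inside a block.
#' @return an `ld_reference`.
#' @export
generate_ld_reference <- function(scenario, block_size, within_block_r2) {
  stopifnot(inherits(scenario, "mr_scenario"), block_size >= 1)
  n <- scenario$n_snps
  ids <- sprintf("rs%06d", seq_len(n))
  blk <- (seq_len(n) - 1) %/% block_size
  pairs <- NULL
  if (block_size > 1) {
    pairs <- do.call(rbind, lapply(split(ids, blk), function(g) {
      if (length(g) < 2) return(NULL)
      cmb <- utils::combn(g, 2)
      data.frame(id_a = cmb[1, ], id_b = cmb[2, ], r2 = within_block_r2,
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(pairs) || nrow(pairs) == 0) {
    # diagonal-only reference: record ids so clumping sees them
    pairs <- data.frame(id_a = ids, id_b = ids, r2 = 1)
  }
  ld_reference(pairs)
}

#' Generate single-trait LDSC input with known truth
#'
#' LD scores are uniform on (1, 150); z statistics are drawn normal with
#' variance `intercept_true + (n * h2 / M) * l_j`, so
#' `E[chi2_j]` follows the LD-score-regression expectation exactly.
#'
#' @param m_snps number of SNPs (also M, the reference size).
#' @param h2 true SNP heritability in \[0, 1).
#' @param n GWAS sample size.
#' @param intercept_true true intercept (1 = no confounding).
#' @param seed RNG seed.
#' @return data.frame (`variant_id`, `ld_score`, `z`, `chi2`, `n`) with the
#'   truth recorded in attributes.
#' @export
generate_ldsc_input <- function(m_snps, h2, n, intercept_true = 1, seed = 1) {
  stopifnot(h2 >= 0, h2 < 1, m_snps >= 1)
  with_seed(seed, {
    l <- stats::runif(m_snps, 1, 150)
    v <- intercept_true + (n * h2 / m_snps) * l
    z <- stats::rnorm(m_snps, 0, sqrt(v))
    structure(data.frame(variant_id = sprintf("rs%06d", seq_len(m_snps)),
                         ld_score = l, z = z, chi2 = z^2, n = n,
                         stringsAsFactors = FALSE),
              truth = list(h2 = h2, n = n, intercept = intercept_true,
                           M = m_snps, seed = seed))
  })
}

#' Generate paired-trait LDSC input with known genetic correlation
#'
#' Per SNP, (z1, z2) are bivariate normal with variances
#' `1 + n_i h2_i l / M` and covariance `rg sqrt(n1 n2 h2_1 h2_2) l / M`
#' (no sample overlap, so the cross-trait intercept is 0).
#'
#' @param m_snps number of SNPs (also M).
#' @param h2_1,h2_2 true heritabilities.
#' @param rg true genetic correlation in \[-1, 1\].
#' @param n1,n2 sample sizes.
#' @param seed RNG seed.
#' @return data.frame (`variant_id`, `ld_score`, `z1`, `z2`, `n1`, `n2`)
#'   with truth attributes.
#' @export
generate_ldsc_pair <- function(m_snps, h2_1, h2_2, rg, n1, n2, seed = 1) {
  stopifnot(abs(rg) <= 1, h2_1 >= 0, h2_2 >= 0)
  with_seed(seed, {
    l <- stats::runif(m_snps, 1, 150)
    v1 <- 1 + (n1 * h2_1 / m_snps) * l
    v2 <- 1 + (n2 * h2_2 / m_snps) * l
    cv <- rg * sqrt(n1 * n2 * h2_1 * h2_2) * l / m_snps
    u1 <- stats::rnorm(m_snps)
    u2 <- stats::rnorm(m_snps)
    z1 <- sqrt(v1) * u1
    z2 <- (cv / sqrt(v1)) * u1 + sqrt(pmax(v2 - cv^2 / v1, 0)) * u2
    structure(data.frame(variant_id = sprintf("rs%06d", seq_len(m_snps)),
                         ld_score = l, z1 = z1, z2 = z2, n1 = n1, n2 = n2,
                         stringsAsFactors = FALSE),
              truth = list(h2_1 = h2_1, h2_2 = h2_2, rg = rg,
                           n1 = n1, n2 = n2, M = m_snps, seed = seed))
  })
}
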