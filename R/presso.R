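# MR-PRESSO: pleiotropy residual-sum-of-squares global test, per-SNP
# outlier test, and distortion test.
#
# The observed RSS uses leave-one-out IVW predictions; the null
# distribution is built by parametric simulation of exposure and outcome
# betas under the no-pleiotropy model, with the same leave-one-out
# machinery applied to every simulated dataset.  The add-one p-value rule
# makes the minimum attainable p equal to 1/(1 + n_sim).

# leave-one-out zero-intercept IVW slopes for columns of BE/BO matrices
# (n x k), weights w (length n); returns an n x k matrix of beta_(-j)
loo_ivw_matrix <- function(BE, BO, w) {
  sxy <- colSums(w * BE * BO)
  sxx <- colSums(w * BE * BE)
  num <- sweep(-(w * BE * BO), 2, sxy, "+")
  den <- sweep(-(w * BE * BE), 2, sxx, "+")
  num / den
}

#' MR-PRESSO global pleiotropy test
#'
#' @param set harmonized instrument set (>= 4 SNPs).
#' @param n_sim parametric simulations for the null RSS distribution
#'   (default 1000).
#' @param seed simulation seed; drawn and recorded when `NULL`.
#' @return an `mr_presso` object with the global fields
#'   (`rss_observed`, `global_pval`, per-SNP residual machinery for the
#'   outlier stage, `n_sim`, `seed`).
#' @export
presso_global <- function(set, n_sim = 1000, seed = NULL) {
  df <- as_instrument_frame(set)
  n <- nrow(df)
  if (n < 4) stop("insufficient instruments: MR-PRESSO needs >= 4 SNPs")
  seed <- seed %||% sample.int(.Machine$integer.max, 1)
  w <- 1 / df$se_out^2
  be <- df$beta_exp
  bo <- df$beta_out

  b_loo <- drop(loo_ivw_matrix(cbind(be), cbind(bo), w))
  d_obs <- w * (bo - b_loo * be)^2
  rss_obs <- sum(d_obs)

  sims <- with_seed(seed, {
    BE <- matrix(stats::rnorm(n * n_sim, be, df$se_exp), n, n_sim)
    BO <- matrix(stats::rnorm(n * n_sim, b_loo * be, df$se_out), n, n_sim)
    BL <- loo_ivw_matrix(BE, BO, w)
    w * (BO - BL * BE)^2
  })
  rss_sim <- colSums(sims)
  structure(list(rss_observed = rss_obs,
                 global_pval = (1 + sum(rss_sim >= rss_obs)) / (1 + n_sim),
                 d_observed = stats::setNames(d_obs, df$variant_id),
                 d_sim = sims,
                 n_sim = n_sim, seed = seed,
                 estimate_raw = mr_ivw(df)),
            class = "mr_presso")
}

#' MR-PRESSO outlier and distortion tests
#'
#' Per-SNP p-values compare each instrument's observed leave-one-out
#' weighted residual with its simulated null distribution; outliers are
#' instruments whose Bonferroni-adjusted p (over `n_snps`) falls below
#' `alpha`.  When outliers are found, the outlier-corrected IVW estimate is
#' computed on the retained set and the distortion test compares the
#' raw-vs-corrected shift against a null of removing equally many randomly
#' chosen instruments.
#'
#' @param set the same harmonized instrument set passed to
#'   [presso_global()].
#' @param global the result of [presso_global()].
#' @param alpha outlier significance level (Bonferroni-adjusted); default
#'   0.05.
#' @param n_distortion random-removal draws for the distortion null
#'   (default 1000).
#' @return the completed `mr_presso` object: `per_snp_pvals`, `outliers`,
#'   `estimate_outlier_corrected` (NULL when no outliers),
#'   `distortion_pval` (NA when no outliers).
#' @export
presso_outliers <- function(set, global, alpha = 0.05, n_distortion = 1000) {
  stopifnot(inherits(global, "mr_presso"))
  df <- as_instrument_frame(set)
  n <- nrow(df)
  d_obs <- global$d_observed
  p_snp <- (1 + rowSums(global$d_sim >= d_obs)) / (1 + global$n_sim)
  names(p_snp) <- df$variant_id
  out_ids <- df$variant_id[pmin(1, p_snp * n) < alpha]

  res <- global
  res$per_snp_pvals <- p_snp
  res$outliers <- out_ids
  res$estimate_outlier_corrected <- NULL
  res$distortion_pval <- NA_real_
  res$d_sim <- NULL

  if (length(out_ids) == 0) return(res)
  if (length(out_ids) >= n - 1) {
    warning("MR-PRESSO flagged (nearly) all instruments as outliers; ",
            "refusing outlier correction", call. = FALSE)
    res$all_outliers <- TRUE
    return(res)
  }
  keep <- !(df$variant_id %in% out_ids)
  res$estimate_outlier_corrected <- mr_ivw(df[keep, , drop = FALSE])

  # distortion null: remove random subsets of the same size
  m <- length(out_ids)
  b_raw <- res$estimate_raw$beta
  b_corr <- res$estimate_outlier_corrected$beta
  d_stat <- abs(b_raw - b_corr)
  # closed-form leave-subset IVW: subtract the dropped SNPs' terms from the
  # zero-intercept weighted-regression sums
  w <- 1 / df$se_out^2
  wxy <- w * df$beta_exp * df$beta_out
  wxx <- w * df$beta_exp^2
  d_null <- with_seed(global$seed + 1L, {
    idx <- replicate(n_distortion, sample.int(n, m))
    idx <- matrix(idx, nrow = m)
    num <- sum(wxy) - colSums(matrix(wxy[idx], nrow = m))
    den <- sum(wxx) - colSums(matrix(wxx[idx], nrow = m))
    abs(b_raw - num / den)
  })
  res$distortion_pval <- (1 + sum(d_null >= d_stat)) / (1 + n_distortion)
  res
}

#' Run the full MR-PRESSO analysis
#'
#' Convenience wrapper: [presso_global()] followed by [presso_outliers()].
#' Identical `(set, n_sim, seed)` give identical results.
#'
#' @inheritParams presso_global
#' @inheritParams presso_outliers
#' @return a completed `mr_presso` object.
#' @export
mr_presso <- function(set, n_sim = 1000, seed = NULL, alpha = 0.05,
                      n_distortion = 1000) {
  g <- presso_global(set, n_sim = n_sim, seed = seed)
  presso_outliers(set, g, alpha = alpha, n_distortion = n_distortion)
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO (n_sim = %d, seed = %d)\n", x$n_sim, x$seed))
  cat(sprintf("  global RSS = %.4g, global p = %.4g\n",
              x$rss_observed, x$global_pval))
  if (!is.null(x$outliers)) {
    cat(sprintf("  outliers: %s\n",
                if (length(x$outliers)) paste(x$outliers, collapse = ", ")
                else "none"))
    if (!is.null(x$estimate_outlier_corrected)) {
      cat(sprintf("  corrected IVW beta = %.4g (raw %.4g), distortion p = %.4g\n",
                  x$estimate_outlier_corrected$beta, x$estimate_raw$beta,
                  x$distortion_pval))
    }
  }
  invisible(x)
}
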