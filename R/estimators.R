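# Single-exposure MR estimators and instrument diagnostics.
#
# All estimators consume a harmonized instrument set (or any data.frame
# with columns beta_exp, se_exp, beta_out, se_out) and return `mr_estimate`
# rows on the log-odds scale with the odds-ratio transform attached
# (beta = ln OR).

# one estimate row; normal CIs with the fixed 1.959964 multiplier unless a
# t reference (df) is supplied
new_mr_estimate <- function(method, beta, se, n_snps, t_df = NULL) {
  if (is.na(se) || se == 0) {
    ci_low <- ci_high <- beta
    pval <- NA_real_
  } else if (is.null(t_df)) {
    ci_low <- beta - Z95 * se
    ci_high <- beta + Z95 * se
    pval <- 2 * stats::pnorm(-abs(beta / se))
  } else {
    q <- stats::qt(0.975, df = t_df)
    ci_low <- beta - q * se
    ci_high <- beta + q * se
    pval <- 2 * stats::pt(-abs(beta / se), df = t_df)
  }
  structure(data.frame(method = method, beta = beta, se = se,
                       ci_low = ci_low, ci_high = ci_high, pval = pval,
                       odds_ratio = exp(beta), or_ci_low = exp(ci_low),
                       or_ci_high = exp(ci_high), n_snps = as.integer(n_snps),
                       stringsAsFactors = FALSE),
            class = c("mr_estimate", "data.frame"))
}

as_instrument_frame <- function(set) {
  df <- as.data.frame(set)
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  if (!all(need %in% names(df))) {
    stop("instrument set must carry columns ", paste(need, collapse = ", "))
  }
  if (any(df$se_exp <= 0) || any(df$se_out <= 0)) stop("standard errors must be positive")
  df
}

# per-SNP Wald ratios and their first-order inverse-variance weights
wald_components <- function(df) {
  if (any(df$beta_exp == 0)) stop("undefined ratio: beta_exp = 0 for some instrument")
  list(ratio = df$beta_out / df$beta_exp,
       se = abs(df$se_out / df$beta_exp))
}

#' Wald ratio for a single instrument
#'
#' The per-SNP causal estimate: SNP-outcome effect divided by SNP-exposure
#' effect.  The default SE is the first-order delta method
#' `|se_out / beta_exp|`; `second_order = TRUE` adds the
#' `beta_out^2 se_exp^2 / beta_exp^4` term.
#'
#' @param beta_exp,se_exp,beta_out,se_out per-SNP effects and SEs.
#' @param second_order include the second-order delta-method term.
#' @return an `mr_estimate` row with method `"wald_ratio"`.
#' @export
mr_wald_ratio <- function(beta_exp, se_exp, beta_out, se_out,
                          second_order = FALSE) {
  if (beta_exp == 0) stop("undefined ratio: beta_exp = 0")
  beta <- beta_out / beta_exp
  v <- se_out^2 / beta_exp^2
  if (second_order) v <- v + beta_out^2 * se_exp^2 / beta_exp^4
  new_mr_estimate("wald_ratio", beta, sqrt(v), 1L)
}

#' Inverse-variance-weighted estimate
#'
#' Pools the per-SNP Wald ratios with first-order inverse-variance weights;
#' equivalently, the zero-intercept regression of outcome betas on exposure
#' betas weighted by `1/se_out^2`.  The fixed-effect SE is
#' `(sum w)^(-1/2)`; the multiplicative-random-effects variant (default)
#' inflates it by `max(1, sqrt(Q/df))`.  Point estimates of the two
#' variants are identical.  A single instrument delegates to the Wald
#' ratio.
#'
#' @param set harmonized instrument set.
#' @param variant `"multiplicative_random"` (default) or `"fixed"`.
#' @return an `mr_estimate` row; Cochran's Q and df are attached as
#'   attributes `cochran_q`, `df`.
#' @export
mr_ivw <- function(set, variant = c("multiplicative_random", "fixed")) {
  variant <- match.arg(variant)
  df <- as_instrument_frame(set)
  n <- nrow(df)
  if (n == 0) stop("empty instrument set")
  if (n == 1) {
    return(mr_wald_ratio(df$beta_exp, df$se_exp, df$beta_out, df$se_out))
  }
  wc <- wald_components(df)
  w <- 1 / wc$se^2
  beta <- sum(w * wc$ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  q <- sum(w * (wc$ratio - beta)^2)
  se <- if (variant == "fixed") se_fixed
        else se_fixed * max(1, sqrt(q / (n - 1)))
  method <- if (variant == "fixed") "ivw_fixed" else "ivw_mre"
  est <- new_mr_estimate(method, beta, se, n)
  attr(est, "cochran_q") <- q
  attr(est, "df") <- n - 1L
  est
}

# parametric bootstrap SE: resample per-SNP betas from their sampling
# distributions and recompute the statistic; returns c(se, seed)
bootstrap_se <- function(df, stat, nboot, seed) {
  if (nboot == 0) return(list(se = NA_real_, seed = NA_integer_))
  seed <- seed %||% sample.int(.Machine$integer.max, 1)
  se <- with_seed(seed, {
    n <- nrow(df)
    be <- matrix(stats::rnorm(n * nboot, df$beta_exp, df$se_exp), n, nboot)
    bo <- matrix(stats::rnorm(n * nboot, df$beta_out, df$se_out), n, nboot)
    stats::sd(vapply(seq_len(nboot),
                     function(k) stat(be[, k], bo[, k], df), 0))
  })
  list(se = se, seed = seed)
}

median_estimate <- function(set, weighted, nboot, seed, method) {
  df <- as_instrument_frame(set)
  if (nrow(df) < 3) stop("insufficient instruments: median methods need >= 3 SNPs")
  stat <- function(be, bo, d) {
    if (any(be == 0)) be[be == 0] <- .Machine$double.eps
    r <- bo / be
    w <- if (weighted) (be / d$se_out)^2 else rep(1, length(r))
    weighted_median(r, w)
  }
  beta <- stat(df$beta_exp, df$beta_out, df)
  bs <- bootstrap_se(df, stat, nboot, seed)
  est <- new_mr_estimate(method, beta, bs$se, nrow(df))
  attr(est, "bootstrap") <- list(nboot = nboot, seed = bs$seed)
  est
}

#' Simple-median estimate
#'
#' The median of the per-SNP Wald ratios (interpolated, via
#' [weighted_median()] with equal weights); consistent when at least half
#' the instruments are valid.  SE by parametric bootstrap.
#'
#' @param set harmonized instrument set (>= 3 SNPs).
#' @param nboot bootstrap replicates (default 1000; 0 skips the SE).
#' @param seed bootstrap seed; drawn and recorded when `NULL`.
#' @return an `mr_estimate` row; the bootstrap seed is attached as an
#'   attribute.
#' @export
mr_simple_median <- function(set, nboot = 1000, seed = NULL) {
  median_estimate(set, weighted = FALSE, nboot, seed, "simple_median")
}

#' Weighted-median estimate
#'
#' Orders the Wald ratios, normalizes the first-order inverse-variance
#' weights to sum 1, and takes the ratio at cumulative weight 0.5 with
#' linear interpolation; consistent when less than half the total weight
#' comes from invalid instruments.  SE by parametric bootstrap.
#'
#' @inheritParams mr_simple_median
#' @return an `mr_estimate` row.
#' @export
mr_weighted_median <- function(set, nboot = 1000, seed = NULL) {
  median_estimate(set, weighted = TRUE, nboot, seed, "weighted_median")
}

#' MR-Egger regression
#'
#' Weighted linear regression with a free intercept of outcome betas on
#' exposure betas (weights `1/se_out^2`), after orienting every instrument
#' so its exposure beta is non-negative.  The slope is the
#' pleiotropy-adjusted causal estimate; the intercept estimates average
#' directional pleiotropy.  SEs use multiplicative residual scaling
#' `max(1, sigma)` and t-based intervals with `n - 2` df.
#'
#' @param set harmonized instrument set (>= 3 SNPs).
#' @return a two-row `mr_estimate` frame: methods `"egger_slope"` and
#'   `"egger_intercept"`.
#' @export
mr_egger <- function(set) {
  df <- as_instrument_frame(set)
  n <- nrow(df)
  if (n < 3) stop("insufficient instruments: MR-Egger needs >= 3 SNPs")
  s <- ifelse(df$beta_exp < 0, -1, 1)
  bx <- s * df$beta_exp
  by <- s * df$beta_out
  if (stats::var(bx) == 0) stop("collinearity error: all exposure betas identical")
  w <- 1 / df$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  cf <- stats::coef(fit)
  sigma <- summary(fit)$sigma
  # unscaled (X'WX)^-1 diag, then multiplicative overdispersion >= 1
  se_un <- sqrt(diag(stats::vcov(fit))) / sigma
  se <- se_un * max(1, sigma)
  if (!is.finite(sigma) || sigma == 0) se <- c(0, 0)
  out <- rbind(new_mr_estimate("egger_slope", unname(cf[2]), se[2], n,
                               t_df = n - 2),
               new_mr_estimate("egger_intercept", unname(cf[1]), se[1], n,
                               t_df = n - 2))
  structure(out, class = c("mr_estimate", "data.frame"))
}

#' I-squared from Cochran's Q
#'
#' `I2 = max(0, (Q - df)/Q) * 100`, the percentage of variation in the
#' per-SNP ratios attributable to heterogeneity.
#'
#' @param q Cochran's Q statistic.
#' @param df degrees of freedom (instruments minus one).
#' @return I-squared in percent, in \[0, 100\].
#' @export
i_squared <- function(q, df) {
  ifelse(q <= 0, 0, pmax(0, (q - df) / q) * 100)
}

#' Heterogeneity and instrument-strength diagnostics
#'
#' Cochran's Q of the per-SNP Wald ratios around the IVW estimate
#' (`Q = sum w (ratio - beta_ivw)^2`), its chi-squared p-value on
#' `n_snps - 1` df, I-squared, and the mean per-SNP F statistic
#' `(beta_exp/se_exp)^2`.  I-squared below 40% is flagged as unimportant
#' heterogeneity.
#'
#' @param set harmonized instrument set (>= 2 SNPs).
#' @return a one-row data.frame: `cochran_q`, `df`, `q_pval`, `i_squared`,
#'   `unimportant_heterogeneity`, `mean_f`.
#' @export
mr_diagnostics <- function(set) {
  df <- as_instrument_frame(set)
  if (nrow(df) < 2) stop("heterogeneity needs >= 2 instruments")
  ivw <- mr_ivw(df, variant = "fixed")
  q <- attr(ivw, "cochran_q")
  dfree <- nrow(df) - 1L
  i2 <- i_squared(q, dfree)
  data.frame(cochran_q = q, df = dfree,
             q_pval = stats::pchisq(q, dfree, lower.tail = FALSE),
             i_squared = i2,
             unimportant_heterogeneity = i2 < 40,
             mean_f = mr_mean_f(df))
}

#' Mean F statistic of an instrument set
#'
#' Per-SNP `F = (beta_exp/se_exp)^2`, averaged; a mean below 10 triggers a
#' weak-instrument warning.
#'
#' @param set harmonized instrument set or sumstats-like frame with
#'   `beta_exp`/`se_exp` (or `beta`/`se`) columns.
#' @return mean F (scalar).
#' @export
mr_mean_f <- function(set) {
  df <- as.data.frame(set)
  if (all(c("beta_exp", "se_exp") %in% names(df))) {
    f <- (df$beta_exp / df$se_exp)^2
  } else if (all(c("beta", "se") %in% names(df))) {
    f <- (df$beta / df$se)^2
  } else {
    stop("need beta_exp/se_exp (or beta/se) columns")
  }
  if (length(f) == 0) stop("empty instrument set")
  mf <- mean(f)
  if (mf < 10) warning("weak instruments: mean F = ", format(mf, digits = 3),
                       " < 10", call. = FALSE)
  mf
}

#' Scatter-plot data export
#'
#' Per-SNP rows of exposure/outcome effects with 95% error-bar half-widths,
#' plus one fitted-line row per supplied estimate (zero intercept for
#' IVW/median methods; slope and intercept for MR-Egger).  Intended for
#' external plotting.
#'
#' @param set harmonized instrument set.
#' @param estimates optional `mr_estimate` frame (rows are methods).
#' @return data.frame with `row_type` `"point"` or `"line"`.
#' @export
export_scatter_data <- function(set, estimates = NULL) {
  df <- as_instrument_frame(set)
  pts <- data.frame(row_type = "point", variant_id = df$variant_id,
                    beta_exp = df$beta_exp, se_exp = df$se_exp,
                    beta_out = df$beta_out, se_out = df$se_out,
                    xbar = Z95 * df$se_exp, ybar = Z95 * df$se_out,
                    method = NA_character_, intercept = NA_real_,
                    slope = NA_real_, stringsAsFactors = FALSE)
  if (is.null(estimates) || nrow(estimates) == 0) return(pts)
  est <- as.data.frame(estimates)
  lines <- NULL
  egger_i <- est$beta[est$method == "egger_intercept"]
  for (k in seq_len(nrow(est))) {
    m <- est$method[k]
    if (m == "egger_intercept") next
    ic <- if (m == "egger_slope" && length(egger_i)) egger_i[1] else 0
    lines <- rbind(lines,
                   data.frame(row_type = "line", variant_id = NA_character_,
                              beta_exp = NA_real_, se_exp = NA_real_,
                              beta_out = NA_real_, se_out = NA_real_,
                              xbar = NA_real_, ybar = NA_real_,
                              method = m, intercept = ic,
                              slope = est$beta[k], stringsAsFactors = FALSE))
  }
  rbind(pts, lines)
}
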