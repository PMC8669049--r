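# LD-score regression: single-trait intercept/heritability and cross-trait
# genetic correlation, with block-jackknife standard errors.
#
# Single-trait model: E[chi2_j] = intercept + (n * h2 / M) * l_j, where l_j
# is SNP j's LD score and M the number of SNPs in the reference.  An
# intercept above 1 signals inflation not attributable to polygenicity
# (confounding / stratification).  Cross-trait model: E[z1_j * z2_j] =
# intercept_x + (sqrt(n1 n2) * gcov / M) * l_j; rg = gcov / sqrt(h2_1 h2_2).
#
# This is a didactic desk-scale implementation: weights come from a
# two-step fit (1 / (2 * predicted^2)), jackknife blocks are contiguous in
# input order, and genome-scale performance is out of scope.

ldsc_weights <- function(chi2, l) {
  fit0 <- wls_line(l, chi2, rep(1, length(l)))
  pred <- pmax(fit0["intercept"] + fit0["slope"] * l, 0.1)
  1 / (2 * pred^2)
}

# block sums for weighted simple regression; returns list(total, by_block)
# each a matrix with columns (s0, sx, sy, sxx, sxy)
block_sums <- function(x, y, w, block) {
  m <- cbind(s0 = w, sx = w * x, sy = w * y, sxx = w * x^2, sxy = w * x * y)
  by_block <- rowsum(m, block)
  list(total = colSums(m), by_block = by_block)
}

line_from_sums <- function(s) {
  den <- s["s0"] * s["sxx"] - s["sx"]^2
  slope <- (s["s0"] * s["sxy"] - s["sx"] * s["sy"]) / den
  c(intercept = unname((s["sy"] - slope * s["sx"]) / s["s0"]),
    slope = unname(slope))
}

make_blocks <- function(m, n_blocks) {
  n_blocks <- min(n_blocks, m)
  sort(rep_len(seq_len(n_blocks), m))
}

jackknife_se <- function(theta) {
  b <- length(theta)
  sqrt((b - 1) / b * sum((theta - mean(theta))^2))
}

#' LD-score regression intercept and heritability
#'
#' Weighted regression of per-SNP chi-squared statistics on LD scores.  The
#' intercept estimates inflation from confounding/stratification (1 under
#' the null); the slope times `M / n` estimates SNP heritability.  SEs come
#' from a delete-one block jackknife over contiguous blocks.  An intercept
#' above `flag_threshold` raises the confounding flag.
#'
#' @param input data.frame with columns `ld_score`, `n`, and `chi2` (or `z`,
#'   squared internally); >= 200 rows.
#' @param M number of SNPs in the LD reference (defaults to `nrow(input)`).
#' @param n_blocks jackknife blocks; default 200.
#' @param flag_threshold intercept level flagged as possible confounding
#'   bias; default 1.3.
#' @return an `ldsc_result` list: `intercept`, `intercept_se`, `slope`,
#'   `slope_se`, `h2`, `h2_se`, `confounding_flag`, `n_blocks`, `m_snps`.
#' @export
ldsc_intercept <- function(input, M = nrow(input), n_blocks = 200,
                           flag_threshold = 1.3) {
  df <- as.data.frame(input)
  if (!"chi2" %in% names(df)) {
    if (!"z" %in% names(df)) stop("need a chi2 or z column")
    df$chi2 <- df$z^2
  }
  if (nrow(df) < 200) stop("LDSC needs at least 200 SNPs with LD scores")
  l <- df$ld_score
  if (any(l < 0)) stop("LD scores must be non-negative")
  if (stats::var(l) == 0) stop("unidentifiable slope: constant LD scores")
  n_mean <- mean(df$n)
  w <- ldsc_weights(df$chi2, l)
  block <- make_blocks(nrow(df), n_blocks)
  bs <- block_sums(l, df$chi2, w, block)
  full <- line_from_sums(bs$total)
  reps <- t(apply(bs$by_block, 1, function(b) line_from_sums(bs$total - b)))
  h2_of <- function(slope) slope * M / n_mean
  res <- list(intercept = full["intercept"],
              intercept_se = jackknife_se(reps[, "intercept"]),
              slope = full["slope"],
              slope_se = jackknife_se(reps[, "slope"]),
              h2 = h2_of(full["slope"]),
              h2_se = jackknife_se(h2_of(reps[, "slope"])),
              confounding_flag = unname(full["intercept"] > flag_threshold),
              n_blocks = nrow(reps), m_snps = nrow(df), M = M)
  res[c("intercept", "slope", "h2")] <- lapply(
    res[c("intercept", "slope", "h2")], unname)
  structure(res, class = "ldsc_result")
}

#' Cross-trait LD-score regression (genetic correlation)
#'
#' Single-trait regressions give each trait's heritability; the regression
#' of `z1 * z2` on LD scores gives the genetic covariance term, and
#' `rg = gcov / sqrt(h2_1 * h2_2)`.  The jackknife recomputes the full
#' pipeline per deleted block (fixed weights), so the rg SE propagates the
#' uncertainty of all three regressions.  rg is clamped to \[-1, 1\] with a
#' warning.
#'
#' @param input data.frame with columns `ld_score`, `z1`, `z2`, `n1`, `n2`;
#'   >= 200 rows.
#' @param M number of SNPs in the LD reference (defaults to `nrow(input)`).
#' @param n_blocks jackknife blocks; default 200.
#' @return an `ldsc_result` list: `rg`, `rg_se`, `gcov`, per-trait `h2_1`,
#'   `h2_2`, intercepts, `n_blocks`.
#' @export
ldsc_rg <- function(input, M = nrow(input), n_blocks = 200) {
  df <- as.data.frame(input)
  need <- c("ld_score", "z1", "z2", "n1", "n2")
  if (!all(need %in% names(df))) {
    stop("need columns ", paste(need, collapse = ", "))
  }
  if (nrow(df) < 200) stop("LDSC needs at least 200 SNPs with LD scores")
  l <- df$ld_score
  if (stats::var(l) == 0) stop("unidentifiable slope: constant LD scores")
  chi1 <- df$z1^2; chi2 <- df$z2^2; z12 <- df$z1 * df$z2
  n1 <- mean(df$n1); n2 <- mean(df$n2)
  w1 <- ldsc_weights(chi1, l)
  w2 <- ldsc_weights(chi2, l)
  fit0_1 <- wls_line(l, chi1, rep(1, length(l)))
  fit0_2 <- wls_line(l, chi2, rep(1, length(l)))
  p1 <- pmax(fit0_1["intercept"] + fit0_1["slope"] * l, 0.1)
  p2 <- pmax(fit0_2["intercept"] + fit0_2["slope"] * l, 0.1)
  w12 <- 1 / (p1 * p2)

  block <- make_blocks(nrow(df), n_blocks)
  bs1 <- block_sums(l, chi1, w1, block)
  bs2 <- block_sums(l, chi2, w2, block)
  bsx <- block_sums(l, z12, w12, block)

  rg_from <- function(s1, s2, sx) {
    h2_1 <- line_from_sums(s1)["slope"] * M / n1
    h2_2 <- line_from_sums(s2)["slope"] * M / n2
    gcov <- line_from_sums(sx)["slope"] * M / sqrt(n1 * n2)
    c(h2_1 = unname(h2_1), h2_2 = unname(h2_2), gcov = unname(gcov),
      rg = unname(gcov / sqrt(pmax(h2_1, 1e-12) * pmax(h2_2, 1e-12))))
  }
  full <- rg_from(bs1$total, bs2$total, bsx$total)
  if (full["h2_1"] <= 0 || full["h2_2"] <= 0) {
    stop("rg undefined: non-positive heritability estimate for a trait")
  }
  nb <- nrow(bs1$by_block)
  reps <- t(vapply(seq_len(nb), function(b) {
    rg_from(bs1$total - bs1$by_block[b, ],
            bs2$total - bs2$by_block[b, ],
            bsx$total - bsx$by_block[b, ])
  }, numeric(4)))
  rg <- unname(full["rg"])
  if (abs(rg) > 1) {
    warning("genetic correlation clamped to [-1, 1] (was ",
            format(rg, digits = 4), ")", call. = FALSE)
    rg <- sign(rg)
  }
  structure(list(rg = rg, rg_se = jackknife_se(reps[, "rg"]),
                 gcov = unname(full["gcov"]),
                 h2_1 = unname(full["h2_1"]), h2_2 = unname(full["h2_2"]),
                 intercept_1 = unname(line_from_sums(bs1$total)["intercept"]),
                 intercept_2 = unname(line_from_sums(bs2$total)["intercept"]),
                 n_blocks = nb, m_snps = nrow(df), M = M),
            class = "ldsc_result")
}

#' @export
print.ldsc_result <- function(x, ...) {
  if (!is.null(x$rg)) {
    cat(sprintf("LDSC genetic correlation: rg = %.4f (SE %.4f), h2 = %.4f / %.4f\n",
                x$rg, x$rg_se, x$h2_1, x$h2_2))
  } else {
    cat(sprintf("LDSC: intercept = %.4f (SE %.4f), h2 = %.4f (SE %.4f)%s\n",
                x$intercept, x$intercept_se, x$h2, x$h2_se,
                if (isTRUE(x$confounding_flag)) "  [confounding flag]" else ""))
  }
  invisible(x)
}
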