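# Multivariable MR: conditional causal effects of several correlated
# exposures on one outcome from jointly harmonized summary statistics.

#' Jointly harmonize several exposures and one outcome
#'
#' Instrument pooling: each exposure's genome-wide-significant variants are
#' selected, their union is clumped jointly (ordering by the minimum
#' p-value across exposures), and every retained variant must be present in
#' all exposure tables and the outcome table; effects are aligned onto the
#' first exposure's effect-allele frame with the same strand/swap rules as
#' [harmonize()] (palindromic variants are dropped).
#'
#' @param exposures named list of `sumstats` tables (K >= 2).
#' @param outcome a `sumstats` table.
#' @param ld an `ld_reference`.
#' @param p_threshold instrument-selection threshold; default 5e-8.
#' @param r2_threshold clumping threshold; default 0.001.
#' @return an `mvmr_input` data.frame with per-SNP columns
#'   `beta_exp.<name>`, `se_exp.<name>` for each exposure plus `beta_out`,
#'   `se_out`; exposure names are in `attr(x, "exposures")`.
#' @export
mvmr_harmonize <- function(exposures, outcome, ld,
                           p_threshold = 5e-8, r2_threshold = 0.001) {
  stopifnot(is.list(exposures), length(exposures) >= 2,
            !is.null(names(exposures)))
  sel <- lapply(exposures, select_instruments, p_threshold = p_threshold)
  pool_ids <- unique(unlist(lapply(sel, function(s) s$variant_id)))
  if (length(pool_ids) == 0) stop("no instruments reach the threshold for any exposure")

  # joint clump: order the union by the best p across exposures
  minp <- vapply(pool_ids, function(v) {
    min(vapply(exposures, function(e) {
      i <- match(v, e$variant_id)
      if (is.na(i)) Inf else e$pval[i]
    }, 0))
  }, 0)
  first <- exposures[[1]]
  frame_idx <- match(pool_ids, first$variant_id)
  pool <- data.frame(variant_id = pool_ids,
                     effect_allele = first$effect_allele[frame_idx],
                     other_allele = first$other_allele[frame_idx],
                     beta = rep(0, length(pool_ids)), se = 1, pval = minp,
                     stringsAsFactors = FALSE)
  pool <- pool[!is.na(pool$effect_allele), , drop = FALSE]
  pool_tab <- sumstats_table(pool, trait_name = "mvmr_pool")
  clumped <- clump_instruments(pool_tab, ld, r2_threshold = r2_threshold)

  ids <- clumped$variant_id
  K <- length(exposures)
  bx <- sx <- matrix(NA_real_, length(ids), K,
                     dimnames = list(ids, names(exposures)))
  keep <- rep(TRUE, length(ids))
  ref <- clumped[, c("variant_id", "effect_allele", "other_allele")]
  align <- function(tab, v, ea, oa) {
    i <- match(v, tab$variant_id)
    if (is.na(i)) return(NULL)
    if (is_palindromic(ea, oa)) return(NULL)
    m <- match_alleles(ea, oa, tab$effect_allele[i], tab$other_allele[i])
    if (is.na(m)) return(NULL)
    c(beta = if (m == "swapped") -tab$beta[i] else tab$beta[i],
      se = tab$se[i])
  }
  b_out <- s_out <- rep(NA_real_, length(ids))
  for (r in seq_along(ids)) {
    v <- ref$variant_id[r]; ea <- ref$effect_allele[r]; oa <- ref$other_allele[r]
    for (k in seq_len(K)) {
      a <- align(exposures[[k]], v, ea, oa)
      if (is.null(a)) { keep[r] <- FALSE; break }
      bx[r, k] <- a["beta"]; sx[r, k] <- a["se"]
    }
    if (!keep[r]) next
    a <- align(outcome, v, ea, oa)
    if (is.null(a)) { keep[r] <- FALSE; next }
    b_out[r] <- a["beta"]; s_out[r] <- a["se"]
  }

  out <- data.frame(variant_id = ids[keep], stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    out[[paste0("beta_exp.", names(exposures)[k])]] <- bx[keep, k]
    out[[paste0("se_exp.", names(exposures)[k])]] <- sx[keep, k]
  }
  out$beta_out <- b_out[keep]
  out$se_out <- s_out[keep]
  if (nrow(out) <= K) stop("too few jointly harmonized instruments (need > K)")
  structure(out, class = c("mvmr_input", "data.frame"),
            exposures = names(exposures),
            audit = list(n_pool = length(pool_ids),
                         n_clumped = length(ids),
                         n_retained = nrow(out)))
}

#' Multivariable IVW estimate
#'
#' Weighted least squares of outcome betas on the K exposure-beta columns
#' with no intercept and weights `1/se_out^2`.  SEs come from the weighted
#' regression covariance with multiplicative overdispersion scaling
#' `max(1, Q/df)` (mirroring the univariable multiplicative-random-effects
#' choice); with K = 1 the result equals the univariable IVW exactly.
#'
#' @param input an `mvmr_input`, or any data.frame with `beta_exp.*`,
#'   `se_exp.*`, `beta_out`, `se_out` columns.
#' @return an `mr_estimate` frame with one row per exposure (column
#'   `exposure`).
#' @export
mvmr_ivw <- function(input) {
  df <- as.data.frame(input)
  bx_cols <- grep("^beta_exp", names(df), value = TRUE)
  K <- length(bx_cols)
  exposures <- attr(input, "exposures") %||% sub("^beta_exp\\.?", "", bx_cols)
  if (K == 1 && exposures[1] == "") exposures <- "exposure"
  X <- as.matrix(df[bx_cols])
  y <- df$beta_out
  w <- 1 / df$se_out^2
  n <- nrow(X)
  if (n <= K) stop("need more instruments than exposures")
  xtwx <- crossprod(X, w * X)
  r <- qr(xtwx)$rank
  if (r < K) {
    stop("collinearity error: rank-deficient exposure design (",
         paste(exposures, collapse = ", "), ")")
  }
  beta <- drop(solve(xtwx, crossprod(X, w * y)))
  q <- sum(w * (y - drop(X %*% beta))^2)
  phi <- max(1, q / (n - K))
  se <- sqrt(diag(solve(xtwx)) * phi)
  rows <- do.call(rbind, lapply(seq_len(K), function(k) {
    new_mr_estimate("mvmr_ivw", unname(beta[k]), unname(se[k]), n)
  }))
  rows <- cbind(exposure = exposures, rows)
  attr(rows, "cochran_q") <- q
  attr(rows, "df") <- n - K
  structure(rows, class = c("mr_estimate", "data.frame"))
}
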