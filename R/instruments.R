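# Instrument selection, LD clumping and allele harmonization.

#' Select genome-wide-significant instruments
#'
#' Retains variants whose exposure p-value is strictly below the threshold
#' (`p < threshold`, the conventional relevance criterion).
#'
#' @param exposure a `sumstats` table.
#' @param p_threshold significance threshold; default `5e-8`.
#' @return a `sumstats` table of the retained records (possibly empty, with
#'   a warning).
#' @export
select_instruments <- function(exposure, p_threshold = 5e-8) {
  stopifnot(inherits(exposure, "sumstats"))
  if (any(is.na(exposure$pval))) stop("p-values must be present for selection")
  keep <- exposure$pval < p_threshold
  out <- exposure[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) {
    warning("no variants reach p < ", format(p_threshold),
            " for ", attr(exposure, "trait_name"), call. = FALSE)
  }
  attr(out, "p_threshold") <- p_threshold
  out
}

#' Greedy LD clumping
#'
#' Orders candidates by ascending p-value (ties broken by lexicographic
#' variant id, so the result is invariant to input row order), retains the
#' best variant, discards every candidate with r2 above the threshold
#' against any retained variant, and repeats.  Variants absent from the LD
#' reference are treated as independent (r2 = 0) and counted in the audit.
#'
#' @param candidates a `sumstats` table (non-empty).
#' @param ld an `ld_reference`.
#' @param r2_threshold maximum pairwise r2 among retained instruments;
#'   default `0.001`.
#' @return the clumped `sumstats` table; `attr(x, "clump_audit")` records
#'   counts of retained/discarded/unmatched variants.
#' @export
clump_instruments <- function(candidates, ld, r2_threshold = 0.001) {
  stopifnot(inherits(candidates, "sumstats"), inherits(ld, "ld_reference"))
  if (nrow(candidates) == 0) stop("no candidate instruments to clump")
  ord <- order(candidates$pval, candidates$variant_id)
  cand <- candidates[ord, , drop = FALSE]
  n_unmatched <- sum(!ld_has_variant(ld, cand$variant_id))
  retained <- character(0)
  for (i in seq_len(nrow(cand))) {
    v <- cand$variant_id[i]
    if (length(retained) == 0 || all(ld_r2(ld, v, retained) <= r2_threshold)) {
      retained <- c(retained, v)
    }
  }
  out <- candidates[match(retained, candidates$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "p_threshold") <- attr(candidates, "p_threshold")
  attr(out, "r2_threshold") <- r2_threshold
  attr(out, "clump_audit") <- list(n_in = nrow(candidates),
                                   n_retained = nrow(out),
                                   n_discarded = nrow(candidates) - nrow(out),
                                   n_not_in_ld_reference = n_unmatched)
  out
}

# orientation of one outcome record against the exposure allele frame:
# list(match = "same" | "swapped" | NA)
match_alleles <- function(e_ea, e_oa, o_ea, o_oa) {
  if (e_ea == o_ea && e_oa == o_oa) return("same")
  if (e_ea == o_oa && e_oa == o_ea) return("swapped")
  # try the complementary strand
  c_ea <- complement_alleles(o_ea)
  c_oa <- complement_alleles(o_oa)
  if (e_ea == c_ea && e_oa == c_oa) return("same")
  if (e_ea == c_oa && e_oa == c_ea) return("swapped")
  NA_character_
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns each exposure instrument's outcome association onto the exposure
#' effect allele.  Identical allele pairs are kept as-is; swapped pairs have
#' the outcome beta negated and frequency complemented; strand flips are
#' resolved by complementing before matching.  Palindromic variants (A/T,
#' C/G) are ambiguous: under `infer_by_eaf` the allele frequencies on both
#' sides decide the orientation, and the variant is dropped when either
#' frequency is missing or within `eaf_tolerance` of 0.5; under `drop` they
#' are always removed.  Irreconcilable allele pairs are dropped with reason,
#' never silently kept.
#'
#' @param exposure_instruments a `sumstats` table of selected instruments.
#' @param outcome a `sumstats` table for the outcome trait.
#' @param palindromic_policy `"infer_by_eaf"` (default) or `"drop"`.
#' @param eaf_tolerance palindromic frequencies within this distance of 0.5
#'   are considered uninformative; default 0.08.
#' @return a `harmonized_set` data.frame with columns `variant_id`,
#'   `beta_exp`, `se_exp`, `pval_exp`, `eaf_exp`, `beta_out`, `se_out`,
#'   `action` (`"kept"` or `"flipped"`); dropped records (with reasons) are
#'   attached as `attr(x, "dropped")`.
#' @export
harmonize <- function(exposure_instruments, outcome,
                      palindromic_policy = c("infer_by_eaf", "drop"),
                      eaf_tolerance = 0.08) {
  palindromic_policy <- match.arg(palindromic_policy)
  exp <- as.data.frame(exposure_instruments)
  out <- as.data.frame(outcome)
  idx <- match(exp$variant_id, out$variant_id)

  n <- nrow(exp)
  action <- character(n)
  beta_out <- se_out <- eaf_out <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    j <- idx[i]
    if (is.na(j)) {
      action[i] <- "dropped_missing"
      next
    }
    e_ea <- exp$effect_allele[i]; e_oa <- exp$other_allele[i]
    o_ea <- out$effect_allele[j]; o_oa <- out$other_allele[j]
    b <- out$beta[j]; f <- out$eaf[j]
    se_out[i] <- out$se[j]

    if (is_palindromic(e_ea, e_oa)) {
      if (palindromic_policy == "drop") {
        action[i] <- "dropped_palindromic"
        next
      }
      # nominal alignment first, then let frequencies fix the strand
      m <- if (e_ea == o_ea && e_oa == o_oa) "same"
           else if (e_ea == o_oa && e_oa == o_ea) "swapped"
           else NA_character_
      if (is.na(m)) { action[i] <- "dropped_incompatible"; next }
      if (m == "swapped") { b <- -b; f <- if (is.na(f)) NA else 1 - f }
      fe <- exp$eaf[i]
      if (is.na(fe) || is.na(f) ||
          abs(fe - 0.5) <= eaf_tolerance || abs(f - 0.5) <= eaf_tolerance) {
        action[i] <- "dropped_palindromic"
        next
      }
      if ((fe < 0.5) != (f < 0.5)) { b <- -b; f <- 1 - f; m <- "swapped" }
      flipped <- !isTRUE(all.equal(b, out$beta[j]))
      action[i] <- if (flipped) "flipped" else "kept"
      beta_out[i] <- b; eaf_out[i] <- f
      next
    }

    m <- match_alleles(e_ea, e_oa, o_ea, o_oa)
    if (is.na(m)) {
      action[i] <- "dropped_incompatible"
      next
    }
    if (m == "swapped") {
      action[i] <- "flipped"
      beta_out[i] <- -b
      eaf_out[i] <- if (is.na(f)) NA_real_ else 1 - f
    } else {
      action[i] <- "kept"
      beta_out[i] <- b
      eaf_out[i] <- f
    }
  }

  rec <- data.frame(variant_id = exp$variant_id,
                    effect_allele = exp$effect_allele,
                    other_allele = exp$other_allele,
                    beta_exp = exp$beta, se_exp = exp$se,
                    pval_exp = exp$pval, eaf_exp = exp$eaf,
                    beta_out = beta_out, se_out = se_out,
                    eaf_out = eaf_out, action = action,
                    stringsAsFactors = FALSE)
  kept <- rec[rec$action %in% c("kept", "flipped"), , drop = FALSE]
  rownames(kept) <- NULL
  dropped <- rec[!(rec$action %in% c("kept", "flipped")),
                 c("variant_id", "action"), drop = FALSE]
  rownames(dropped) <- NULL
  structure(kept,
            class = c("harmonized_set", "data.frame"),
            exposure_name = attr(exposure_instruments, "trait_name"),
            outcome_name = attr(outcome, "trait_name"),
            p_threshold = attr(exposure_instruments, "p_threshold"),
            dropped = dropped)
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized instruments: %s -> %s, %d variants (%d dropped)\n",
              attr(x, "exposure_name") %||% "exposure",
              attr(x, "outcome_name") %||% "outcome",
              nrow(x), nrow(attr(x, "dropped") %||% data.frame())))
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}
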