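# Full-study orchestration: select -> clump -> harmonize -> estimate ->
# diagnostics -> MR-PRESSO for every exposure-outcome pair, with per-stage
# row audits, deterministic per-pair seeds split from one root seed, and
# TSV outputs (estimates, diagnostics, scatter data, a combined forest
# table mirroring a forest plot's content, and a plain-text run log).

pipeline_defaults <- function() {
  list(p_threshold = 5e-8, r2_threshold = 0.001,
       palindromic = "infer_by_eaf",
       methods = c("ivw", "simple_median", "weighted_median", "egger"),
       ivw_variant = "multiplicative_random",
       nboot = 1000, presso = TRUE, presso_nsim = 1000,
       seed = 1, outdir = "results/pipeline")
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(pipeline_defaults(), config)
  for (f in c("exposures", "outcomes", "ld")) {
    if (is.null(cfg[[f]])) stop("run config must name '", f, "'")
  }
  for (p in c(unlist(cfg$exposures), unlist(cfg$outcomes), cfg$ld)) {
    if (!file.exists(p)) stop("configured path does not exist: ", p)
  }
  cfg
}

estimate_pair <- function(hset, methods, ivw_variant, nboot, seed) {
  rows <- list()
  for (m in methods) {
    est <- switch(m,
      ivw = mr_ivw(hset, variant = ivw_variant),
      simple_median = mr_simple_median(hset, nboot = nboot, seed = seed),
      weighted_median = mr_weighted_median(hset, nboot = nboot, seed = seed + 1L),
      egger = mr_egger(hset),
      stop("unknown method: ", m))
    rows[[m]] <- est
  }
  do.call(rbind, rows)
}

#' Run the full MR workflow for every exposure-outcome pair
#'
#' Executes instrument selection, LD clumping, harmonization, all requested
#' estimators, heterogeneity/instrument-strength diagnostics and (when at
#' least 4 instruments remain) MR-PRESSO for each pair, writing one TSV per
#' table plus a combined forest-data table and a run log under
#' `config$outdir`.  A stage failure halts that pair only; the returned
#' report lists per-pair status and `attr(report, "ok")` is FALSE when any
#' pair failed or was skipped.
#'
#' All randomness (median bootstraps, PRESSO simulations) descends
#' deterministically from the single root seed, split per pair and stage,
#' so an identical config reproduces identical outputs.
#'
#' @param config a named list or path to a YAML file with entries
#'   `exposures` (named list of sumstats paths), `outcomes` (named list),
#'   `ld` (LD-reference path) and optional overrides of the defaults
#'   (`p_threshold` 5e-8, `r2_threshold` 0.001, `palindromic`
#'   "infer_by_eaf", `methods`, `ivw_variant`, `nboot`, `presso`,
#'   `presso_nsim`, `seed`, `outdir`).
#' @return invisibly, a list of per-pair reports (status, stage audit,
#'   estimates, diagnostics).
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  ld <- read_ld_reference(cfg$ld)
  outcomes <- lapply(names(cfg$outcomes), function(nm) {
    read_sumstats(cfg$outcomes[[nm]], trait_name = nm, trait_type = "binary")
  })
  names(outcomes) <- names(cfg$outcomes)

  log_lines <- c(sprintf("mrkit run: %s", format(Sys.time())),
                 sprintf("root seed: %d", cfg$seed),
                 sprintf("p_threshold=%g r2_threshold=%g palindromic=%s",
                         cfg$p_threshold, cfg$r2_threshold, cfg$palindromic))
  report <- list()
  forest <- NULL
  pair_i <- 0L

  for (en in names(cfg$exposures)) {
    exposure <- read_sumstats(cfg$exposures[[en]], trait_name = en)
    for (on in names(outcomes)) {
      pair_i <- pair_i + 1L
      pair_seed <- cfg$seed * 1000L + pair_i * 10L
      pair_id <- paste0(en, "__", on)
      res <- tryCatch({
        sel <- select_instruments(exposure, p_threshold = cfg$p_threshold)
        if (nrow(sel) == 0) stop("no genome-wide-significant instruments")
        clumped <- clump_instruments(sel, ld, r2_threshold = cfg$r2_threshold)
        hset <- harmonize(clumped, outcomes[[on]],
                          palindromic_policy = cfg$palindromic)
        if (nrow(hset) < 2) stop("fewer than 2 harmonized instruments")
        audit <- data.frame(
          stage = c("input", "selected", "clumped", "harmonized"),
          n = c(nrow(exposure), nrow(sel), nrow(clumped), nrow(hset)))
        est <- estimate_pair(hset, cfg$methods, cfg$ivw_variant,
                             cfg$nboot, pair_seed)
        diag <- mr_diagnostics(hset)
        presso <- NULL
        if (isTRUE(cfg$presso) && nrow(hset) >= 4) {
          presso <- mr_presso(hset, n_sim = cfg$presso_nsim,
                              seed = pair_seed + 5L)
        }
        pfx <- file.path(cfg$outdir, pair_id)
        utils::write.table(cbind(exposure = en, outcome = on, est),
                           paste0(pfx, "_estimates.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(cbind(exposure = en, outcome = on, diag),
                           paste0(pfx, "_diagnostics.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(export_scatter_data(hset, est),
                           paste0(pfx, "_scatter.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        if (!is.null(presso)) {
          ptab <- data.frame(exposure = en, outcome = on,
                             rss_observed = presso$rss_observed,
                             global_pval = presso$global_pval,
                             n_outliers = length(presso$outliers),
                             outliers = paste(presso$outliers, collapse = ","),
                             distortion_pval = presso$distortion_pval,
                             n_sim = presso$n_sim, seed = presso$seed)
          utils::write.table(ptab, paste0(pfx, "_presso.tsv"), sep = "\t",
                             quote = FALSE, row.names = FALSE)
        }
        forest <- rbind(forest, cbind(exposure = en, outcome = on,
                                       est[, c("method", "odds_ratio",
                                               "or_ci_low", "or_ci_high",
                                               "pval", "n_snps")]))
        log_lines <- c(log_lines,
                       sprintf("[%s] ok: %s", pair_id,
                               paste(sprintf("%s=%d", audit$stage, audit$n),
                                     collapse = " ")))
        list(status = "ok", audit = audit, estimates = est,
             diagnostics = diag, presso = presso)
      }, error = function(e) {
        log_lines <<- c(log_lines,
                        sprintf("[%s] FAILED: %s", pair_id, conditionMessage(e)))
        list(status = "failed", reason = conditionMessage(e))
      })
      report[[pair_id]] <- res
    }
  }
  if (!is.null(forest)) {
    utils::write.table(forest, file.path(cfg$outdir, "forest_data.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(log_lines, file.path(cfg$outdir, "run_log.txt"))
  ok <- all(vapply(report, function(r) r$status == "ok", TRUE))
  attr(report, "ok") <- ok
  attr(report, "forest") <- forest
  if (!ok) warning("one or more exposure-outcome pairs failed; see run_log.txt",
                   call. = FALSE)
  invisible(report)
}
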