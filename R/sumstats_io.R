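# GWAS summary-statistics tables: reading, validation, writing.
#
# A sumstats table is a data.frame with the standard columns
#   variant_id, chrom, pos, effect_allele, other_allele, eaf, beta, se,
#   pval, n
# plus attributes trait_name, trait_type, ancestry, source and an audit
# record of rows dropped at validation.  Coordinates are 1-based.  Missing
# eaf and n are permitted (frequency-free sources omit them); operations
# that need them fail loudly rather than impute.

STANDARD_FIELDS <- c("variant_id", "chrom", "pos", "effect_allele",
                     "other_allele", "eaf", "beta", "se", "pval", "n")
MANDATORY_FIELDS <- c("variant_id", "effect_allele", "other_allele",
                      "beta", "se", "pval")

#' Default column map for summary-statistics files
#'
#' Maps each standard field to the column header used on disk.  Sources with
#' other dialects supply their own map to [read_sumstats()].
#'
#' @return named character vector, names = standard fields, values = file
#'   column headers.
#' @export
default_column_map <- function() {
  c(variant_id = "snp", chrom = "chr", pos = "pos",
    effect_allele = "ea", other_allele = "oa", eaf = "eaf",
    beta = "beta", se = "se", pval = "p", n = "n")
}

#' Construct a validated summary-statistics table
#'
#' Validates every row against the per-variant invariants (distinct single
#' ACGT alleles, se > 0, p in (0,1], eaf in (0,1) when present, unique
#' variant ids), drops failing rows, and records the drops in an audit
#' attribute with `rows_in = rows_kept + rows_dropped`.
#'
#' @param df data.frame carrying the standard fields (missing optional
#'   fields are filled with NA).
#' @param trait_name,trait_type,ancestry,source trait metadata;
#'   `trait_type` is `"continuous"` or `"binary"` (binary betas are
#'   log-odds, beta = ln OR).
#' @return a `sumstats` data.frame; `attr(x, "audit")` holds the row
#'   accounting.
#' @export
sumstats_table <- function(df, trait_name = "trait",
                           trait_type = c("continuous", "binary"),
                           ancestry = NA_character_, source = NA_character_) {
  trait_type <- match.arg(trait_type)
  for (f in setdiff(STANDARD_FIELDS, names(df))) {
    if (f %in% MANDATORY_FIELDS) {
      stop("configuration error: mandatory field '", f, "' absent", call. = FALSE)
    }
    df[[f]] <- NA
  }
  df <- df[STANDARD_FIELDS]
  df$variant_id <- as.character(df$variant_id)
  df$chrom <- as.character(df$chrom)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (f in c("pos", "eaf", "beta", "se", "pval", "n")) {
    df[[f]] <- suppressWarnings(as.numeric(df[[f]]))
  }

  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- FALSE
    reason[bad & is.na(reason)] <<- why
  }
  flag(is.na(df$variant_id) | df$variant_id == "", "missing variant id")
  flag(!(df$effect_allele %in% c("A", "C", "G", "T")) |
         !(df$other_allele %in% c("A", "C", "G", "T")),
       "non-SNP or missing alleles")
  flag(df$effect_allele == df$other_allele, "degenerate alleles")
  flag(is.na(df$beta), "missing beta")
  flag(is.na(df$se) | df$se <= 0, "non-positive or missing se")
  flag(is.na(df$pval) | df$pval <= 0 | df$pval > 1, "p-value outside (0,1]")
  flag(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "eaf outside (0,1)")
  flag(!is.na(df$n) & df$n <= 0, "non-positive n")
  flag(duplicated(df$variant_id), "duplicate variant id")

  kept <- df[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  dropped <- table(reason[!is.na(reason)])
  structure(kept,
            class = c("sumstats", "data.frame"),
            trait_name = trait_name, trait_type = trait_type,
            ancestry = ancestry, source = source,
            audit = list(rows_in = nrow(df), rows_kept = nrow(kept),
                         rows_dropped = nrow(df) - nrow(kept),
                         reasons = dropped))
}

#' Read a GWAS summary-statistics file
#'
#' Tab-separated text, UTF-8, one header line, `NA` for missing values.
#' Column headers are resolved through `column_map`; rows violating the
#' per-variant invariants are dropped and counted in the audit attribute.
#'
#' @param path file path.
#' @param column_map named character vector mapping standard fields to the
#'   file's column headers; see [default_column_map()].
#' @inheritParams sumstats_table
#' @return a `sumstats` table.
#' @export
read_sumstats <- function(path, column_map = default_column_map(),
                          trait_name = "trait",
                          trait_type = c("continuous", "binary"),
                          ancestry = NA_character_, source = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = "NA",
                           check.names = FALSE)
  missing_cols <- setdiff(unname(column_map[MANDATORY_FIELDS]), names(raw))
  if (length(missing_cols)) {
    stop("configuration error: mandatory column(s) ",
         paste(missing_cols, collapse = ", "), " not found in ", path,
         call. = FALSE)
  }
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in names(column_map)) {
    if (column_map[[f]] %in% names(raw)) df[[f]] <- raw[[column_map[[f]]]]
  }
  tab <- sumstats_table(df, trait_name = trait_name, trait_type = trait_type,
                        ancestry = ancestry, source = source)
  if (nrow(tab) == 0) {
    stop("empty input: no valid summary-statistics rows in ", path,
         call. = FALSE)
  }
  tab
}

#' Write a summary-statistics table
#'
#' Writes tab-separated text using the headers in `column_map`; numerics are
#' printed with 17 significant digits so that a read-back reproduces the
#' table field-for-field.  Missing values are written as `NA`.
#'
#' @param table a `sumstats` table.
#' @param path output path.
#' @param column_map see [default_column_map()].
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path, column_map = default_column_map()) {
  out <- as.data.frame(table)[STANDARD_FIELDS]
  for (f in c("pos", "eaf", "beta", "se", "pval", "n")) {
    v <- out[[f]]
    out[[f]] <- ifelse(is.na(v), "NA", formatC(v, digits = 17, format = "g"))
  }
  names(out) <- unname(column_map[STANDARD_FIELDS])
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) {
    stop("cannot write ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d variants\n",
              attr(x, "trait_name"), attr(x, "trait_type"), nrow(x)))
  audit <- attr(x, "audit")
  if (!is.null(audit) && audit$rows_dropped > 0) {
    cat(sprintf("  %d of %d input rows dropped at validation\n",
                audit$rows_dropped, audit$rows_in))
  }
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}
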