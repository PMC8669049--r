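# Pairwise-r2 LD reference used by clumping.
#
# Stored as a hash over unordered variant pairs; absent pairs are r2 = 0 by
# contract and r2(a, a) = 1.

ld_key <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}

#' Build an LD reference from a pair table
#'
#' @param pairs data.frame with columns `id_a`, `id_b`, `r2` (any names;
#'   first three columns are used).  r2 outside \[0, 1\] is rejected.
#' @return an `ld_reference` object with symmetric lookup.
#' @export
ld_reference <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 3) stop("LD reference needs three columns (id_a, id_b, r2)")
  id_a <- as.character(pairs[[1]])
  id_b <- as.character(pairs[[2]])
  r2 <- as.numeric(pairs[[3]])
  if (any(is.na(r2)) || any(r2 < 0) || any(r2 > 1)) {
    stop("validation error: r2 values must lie in [0, 1]", call. = FALSE)
  }
  h <- new.env(hash = TRUE, parent = emptyenv())
  ids <- new.env(hash = TRUE, parent = emptyenv())
  keys <- ld_key(id_a, id_b)
  for (i in seq_along(keys)) {
    assign(keys[i], r2[i], envir = h)
    assign(id_a[i], TRUE, envir = ids)
    assign(id_b[i], TRUE, envir = ids)
  }
  structure(list(index = h, ids = ids, n_pairs = length(keys)),
            class = "ld_reference")
}

#' Read an LD reference from a tab-separated file
#'
#' Expected layout: header plus columns (id_a, id_b, r2).
#'
#' @param path file path.
#' @return an `ld_reference`.
#' @export
read_ld_reference <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ld_reference(utils::read.delim(path, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE))
}

#' Pairwise r2 lookup
#'
#' Symmetric; `r2(a, a)` is 1 and absent pairs are 0.
#'
#' @param ld an `ld_reference`.
#' @param a,b variant ids (vectors are recycled).
#' @return numeric vector of r2 values.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_reference"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- unlist(mget(ld_key(a, b), envir = ld$index, ifnotfound = 0),
                use.names = FALSE)
  out[a == b] <- 1
  out
}

# TRUE for variants present anywhere in the reference
ld_has_variant <- function(ld, ids) {
  vapply(as.character(ids), function(v) {
    exists(v, envir = ld$ids, inherits = FALSE)
  }, logical(1), USE.NAMES = FALSE)
}
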