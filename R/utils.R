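# shared internals

# 95% normal multiplier used for all normal-approximation intervals
Z95 <- 1.959964

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `code` under a temporary RNG state seeded with `seed`;
# NULL seed leaves the session RNG untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

complement_alleles <- function(x) chartr("ACGT", "TGCA", toupper(x))

is_palindromic <- function(a1, a2) complement_alleles(a1) == a2

#' Interpolated weighted median
#'
#' The estimate at cumulative normalized weight 0.5: order the values
#' ascending, place value `i` at cumulative weight `(sum(w[1:i]) - w[i]/2) /
#' sum(w)`, and linearly interpolate to 0.5.  With equal weights and an odd
#' count this is the sample median; with an even count it is the midpoint of
#' the two central values.
#'
#' @param x numeric values.
#' @param w positive weights, recycled to `length(x)`.
#' @return the interpolated weighted median (scalar).
#' @export
weighted_median <- function(x, w = rep(1, length(x))) {
  stopifnot(length(x) >= 1, all(w > 0))
  w <- rep_len(w, length(x))
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  p <- (cumsum(w) - 0.5 * w) / sum(w)
  if (0.5 <= p[1]) return(x[1])
  if (0.5 >= p[length(p)]) return(x[length(x)])
  stats::approx(p, x, xout = 0.5, ties = "ordered", rule = 2)$y
}

# weighted simple linear regression through precomputed sums;
# returns c(intercept, slope)
wls_line <- function(x, y, w) {
  s0 <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x * x); sxy <- sum(w * x * y)
  den <- s0 * sxx - sx^2
  if (den <= 0) stop("unidentifiable slope: no variation in the predictor")
  slope <- (s0 * sxy - sx * sy) / den
  intercept <- (sy - slope * sx) / s0
  c(intercept = intercept, slope = slope)
}
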