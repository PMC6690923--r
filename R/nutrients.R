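#' Nutrient triples
#'
#' Most quantities in this package come in threes: one value for N, one for P,
#' one for K. A nutrient triple is a named numeric vector with names
#' `c("N", "P", "K")`. `nutrient_triple()` builds one, `as_triple()` coerces
#' and validates one.
#'
#' @param n,p,k Single finite numeric values for nitrogen, phosphorus and
#'   potassium, in a shared unit (kg/ha for uptakes, g/kg for concentrations,
#'   kg/kg for efficiencies and indices, kg/t for reciprocal efficiencies).
#' @return A named numeric vector of length 3 with names `N`, `P`, `K`.
#' @examples
#' nutrient_triple(241.0, 1069.2, 170.6)
#' @export
nutrient_triple <- function(n, p, k) {
  as_triple(c(N = n, P = p, K = k))
}

#' @rdname nutrient_triple
#' @param x A numeric vector of length 3, optionally named `N`, `P`, `K` in
#'   any order.
#' @param nonnegative Require all components to be `>= 0` (the default;
#'   masses, concentrations and efficiencies cannot be negative).
#' @export
as_triple <- function(x, nonnegative = TRUE) {
  if (!is.numeric(x) || length(x) != 3L)
    stop("a nutrient triple must be a numeric vector of length 3", call. = FALSE)
  if (!is.null(names(x))) {
    if (!setequal(names(x), c("N", "P", "K")))
      stop("nutrient triple names must be 'N', 'P', 'K'", call. = FALSE)
    x <- x[c("N", "P", "K")]
  } else {
    names(x) <- c("N", "P", "K")
  }
  if (any(!is.finite(x)))
    stop("nutrient triple components must all be finite", call. = FALSE)
  if (nonnegative && any(x < 0))
    stop("nutrient triple components must be non-negative", call. = FALSE)
  x
}

NUTRIENTS <- c("N", "P", "K")

#' Interpolated percentiles
#'
#' Single percentile estimator shared by the summary tables and the envelope
#' calibration: linear interpolation between order statistics
#' (`stats::quantile()` type 7, the convention spreadsheet software uses).
#' Centralized so the two modules can never drift apart.
#'
#' @param x Numeric vector, `NA`s dropped.
#' @param probs Percentiles in `[0, 100]`.
#' @return Numeric vector of the same length as `probs`.
#' @examples
#' pctile(seq(100, 1000, by = 100), c(2.5, 97.5))
#' @export
pctile <- function(x, probs) {
  stopifnot(all(probs >= 0 & probs <= 100))
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("no non-missing values to take percentiles of", call. = FALSE)
  unname(stats::quantile(x, probs / 100, type = 7, names = FALSE))
}
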