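## Model validation metrics: RMSE, normalized RMSE, mean error, and the
## paired comparison test between simulated and measured uptake.

.check_pairs <- function(simulated, measured) {
  if (length(simulated) != length(measured))
    stop("simulated and measured series must be paired (equal length)",
         call. = FALSE)
  if (length(simulated) < 1L) stop("need at least one pair", call. = FALSE)
  if (anyNA(simulated) || anyNA(measured))
    stop("missing values in paired series", call. = FALSE)
}

#' Root mean square error
#'
#' `sqrt(mean((s - m)^2))` over pairs of simulated (`s`) and measured (`m`)
#' values, in the unit of the inputs (kg/ha for uptake).
#'
#' @param simulated,measured Paired numeric vectors.
#' @return A single number.
#' @export
rmse <- function(simulated, measured) {
  .check_pairs(simulated, measured)
  sqrt(mean((simulated - measured)^2))
}

#' Normalized root mean square error
#'
#' [rmse()] divided by the mean of the measured series; dimensionless, so
#' comparable across nutrients. Reported as a fraction.
#'
#' @inheritParams rmse
#' @return A single number (fraction).
#' @export
nrmse <- function(simulated, measured) {
  .check_pairs(simulated, measured)
  mbar <- mean(measured)
  if (mbar <= 0) stop("mean of measured series must be positive", call. = FALSE)
  rmse(simulated, measured) / mbar
}

#' Mean error
#'
#' `mean(s - m)`; negative values mean the model under-simulates.
#'
#' @inheritParams rmse
#' @return A single number, same unit as the inputs.
#' @export
mean_error <- function(simulated, measured) {
  .check_pairs(simulated, measured)
  mean(simulated - measured)
}

#' Compare simulated and measured means
#'
#' Two-sided Student's t test of the simulated-measured difference. The
#' default is the paired test (the validation design observes both values on
#' the same field); set `paired = FALSE` for the two-sample variant.
#'
#' @inheritParams rmse
#' @param alpha Significance level for the `significant` flag.
#' @param paired Paired (default) or two-sample test.
#' @return A list with `t_statistic`, `df`, `p_value`, `alpha` and
#'   `significant`. A model that validates shows a non-significant
#'   difference. Errors on the degenerate case of identically-constant
#'   nonzero differences (infinite t).
#' @export
compare_means <- function(simulated, measured, alpha = 0.05, paired = TRUE) {
  .check_pairs(simulated, measured)
  if (length(simulated) < 2L) stop("need at least two pairs", call. = FALSE)
  diffs <- simulated - measured
  if (paired && stats::var(diffs) == 0) {
    if (mean(diffs) == 0)
      return(list(t_statistic = 0, df = length(diffs) - 1L, p_value = 1,
                  alpha = alpha, significant = FALSE))
    stop("zero variance of differences with nonzero mean: t undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(simulated, measured, paired = paired)
  list(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, alpha = alpha,
       significant = tt$p.value < alpha)
}

#' Per-nutrient validation statistics
#'
#' Computes n, RMSE, nRMSE, mean error and the paired comparison test for
#' each nutrient of a paired simulated/measured uptake table.
#'
#' @param pairs A data frame with columns `nutrient` (values `N`, `P`, `K`),
#'   `simulated` and `measured` (kg/ha), such as returned by
#'   [generate_validation_pairs()].
#' @param alpha,paired Passed to [compare_means()].
#' @return A `data.frame` with one row per nutrient: `nutrient`, `n`, `rmse`,
#'   `nrmse`, `me`, `t_statistic`, `p_value`, `significant`.
#' @export
validation_stats <- function(pairs, alpha = 0.05, paired = TRUE) {
  stopifnot(all(c("nutrient", "simulated", "measured") %in% names(pairs)))
  rows <- lapply(intersect(NUTRIENTS, unique(pairs$nutrient)), function(nu) {
    s <- pairs$simulated[pairs$nutrient == nu]
    m <- pairs$measured[pairs$nutrient == nu]
    tt <- compare_means(s, m, alpha = alpha, paired = paired)
    data.frame(nutrient = nu, n = length(s), rmse = rmse(s, m),
               nrmse = nrmse(s, m), me = mean_error(s, m),
               t_statistic = tt$t_statistic, p_value = tt$p_value,
               significant = tt$significant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
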