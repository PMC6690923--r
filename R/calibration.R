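## Envelope calibration: harvest-index data selection and percentile-based
## maximum-accumulation / maximum-dilution constants.

PERCENTILE_SETS <- list(I = c(2.5, 97.5), II = c(5.0, 95.0), III = c(7.5, 92.5))

#' Calibration specification
#'
#' @param hi_min Harvest-index retention threshold, kg/kg. Plots with
#'   `harvest_index < hi_min` are assumed stressed by factors other than
#'   N/P/K supply and are excluded; the threshold is inclusive (`>= hi_min`
#'   retained). Default 0.4.
#' @param set Percentile set: `"I"` (2.5/97.5), `"II"` (5/95) or `"III"`
#'   (7.5/92.5). The lower percentile of the internal-efficiency distribution
#'   becomes the maximum-accumulation constant `a`, the upper one the
#'   maximum-dilution constant `d`.
#' @param basis `"plant"` for whole-plant uptake IEs or `"root"` for
#'   fleshy-root removal IEs.
#' @param min_n Minimum number of IE values per nutrient; percentiles of tiny
#'   samples are meaningless. Safeguard only, default 20.
#' @return A list of class `calibration_spec`.
#' @export
calibration_spec <- function(hi_min = 0.4, set = c("I", "II", "III"),
                             basis = c("plant", "root"), min_n = 20) {
  set <- match.arg(set)
  basis <- match.arg(basis)
  stopifnot(is.numeric(hi_min), length(hi_min) == 1L, hi_min >= 0, hi_min < 1)
  pr <- PERCENTILE_SETS[[set]]
  stopifnot(pr[1] >= 0, pr[1] < pr[2], pr[2] <= 100)
  structure(list(hi_min = hi_min, set = set, percentiles = pr,
                 basis = basis, min_n = min_n),
            class = "calibration_spec")
}

#' Envelope constants
#'
#' Container for the per-nutrient maximum-accumulation (`a`) and
#' maximum-dilution (`d`) internal efficiencies that define the QUEFTS yield
#' envelope, with provenance. `a` is the IE of a plant hoarding the nutrient
#' (lower boundary of yield per unit uptake), `d` of a plant stretching it
#' maximally (upper boundary); `a < d` for every nutrient.
#'
#' @param a,d Nutrient triples of envelope IEs, kg fleshy root per kg
#'   nutrient (see [nutrient_triple()]).
#' @param basis `"plant"` or `"root"` (removal).
#' @param set Percentile-set label, or any provenance label for injected
#'   constants.
#' @param n Number of IE values per nutrient used in calibration (NA for
#'   injected constants).
#' @param hi_min Harvest-index threshold applied (NA for injected constants).
#' @return An object of class `envelope_constants` with elements `a`, `d`,
#'   `d_over_a`, `basis`, `set`, `n`, `hi_min`.
#' @examples
#' # published set-I constants for radish in China
#' envelope_constants(a = c(N = 241.0, P = 1069.2, K = 170.6),
#'                    d = c(N = 844.6, P = 4480.0, K = 878.7))
#' @export
envelope_constants <- function(a, d, basis = "plant", set = "injected",
                               n = rep(NA_integer_, 3), hi_min = NA_real_) {
  a <- as_triple(a)
  d <- as_triple(d)
  if (any(a <= 0)) stop("maximum-accumulation constants must be positive", call. = FALSE)
  if (any(a >= d))
    stop("degenerate envelope: a >= d for ", paste(NUTRIENTS[a >= d], collapse = ", "),
         call. = FALSE)
  structure(list(a = a, d = d, d_over_a = d / a, basis = basis, set = set,
                 n = stats::setNames(as.integer(n), NUTRIENTS), hi_min = hi_min),
            class = "envelope_constants")
}

#' @export
print.envelope_constants <- function(x, ...) {
  cat(sprintf("QUEFTS envelope constants (basis: %s, set: %s", x$basis, x$set))
  if (!is.na(x$hi_min)) cat(sprintf(", HI >= %g", x$hi_min))
  cat(")\n")
  m <- rbind(a = x$a, d = x$d, `d/a` = x$d_over_a)
  print(round(m, 2))
  if (!all(is.na(x$n))) cat("n:", paste(x$n, collapse = "/"), "\n")
  invisible(x)
}

#' Select records for calibration
#'
#' Applies the harvest-index quality filter and drops records whose internal
#' efficiencies are undefined on the requested basis. A plot with low harvest
#' index is taken to have been limited by stresses other than nutrient
#' supply, so it carries no information about the attainable IE range. The
#' threshold is inclusive: `harvest_index >= hi_min` is retained.
#'
#' @param derived A [derive_trials()] data frame.
#' @param spec A [calibration_spec()].
#' @return A list with `records` (the retained rows) and `exclusions`, a data
#'   frame counting removals by reason (`hi_below_min`, `hi_missing`,
#'   `ie_undefined`).
#' @export
filter_records <- function(derived, spec = calibration_spec()) {
  stopifnot(inherits(spec, "calibration_spec"))
  df <- as.data.frame(derived)
  ie_cols <- paste0("ie_", if (spec$basis == "plant") "plant" else "root",
                    "_", tolower(NUTRIENTS))
  hi_missing <- is.na(df$harvest_index)
  hi_low <- !hi_missing & df$harvest_index < spec$hi_min
  ie_bad <- !hi_missing & !hi_low &
    Reduce(`|`, lapply(ie_cols, function(cl) !is.finite(df[[cl]])))
  keep <- !(hi_missing | hi_low | ie_bad)
  # hi_min = 0 still requires a defined HI only if the filter is active
  if (spec$hi_min == 0) {
    keep <- !ie_bad & !Reduce(`|`, lapply(ie_cols, function(cl) is.na(df[[cl]])))
    hi_missing <- hi_low <- rep(FALSE, nrow(df))
    ie_bad <- !keep
  }
  exclusions <- data.frame(
    reason = c("hi_below_min", "hi_missing", "ie_undefined"),
    n = c(sum(hi_low), sum(hi_missing), sum(ie_bad)),
    stringsAsFactors = FALSE
  )
  if (!any(keep))
    stop("all records excluded; calibration impossible", call. = FALSE)
  list(records = df[keep, , drop = FALSE], exclusions = exclusions)
}

#' Envelope constants from internal-efficiency values
#'
#' Takes the lower and upper percentiles of each nutrient's IE distribution
#' (interpolated between order statistics, see [pctile()]) as the
#' maximum-accumulation and maximum-dilution constants. Nutrients are treated
#' independently.
#'
#' @param ie A list or data frame with numeric elements `N`, `P`, `K` of IE
#'   values (kg fleshy root per kg nutrient); `NA`s are dropped.
#' @param spec A [calibration_spec()]; supplies the percentile pair and
#'   provenance fields.
#' @return An [envelope_constants()] object. Errors if any nutrient has fewer
#'   than `spec$min_n` values or a degenerate spread (`a >= d`).
#' @examples
#' ie <- list(N = seq(100, 1000, by = 100),
#'            P = seq(800, 4400, by = 400),
#'            K = seq(150, 960, by = 90))
#' envelope_from_ies(ie, calibration_spec(min_n = 10))
#' @export
envelope_from_ies <- function(ie, spec = calibration_spec()) {
  stopifnot(inherits(spec, "calibration_spec"))
  vals <- lapply(NUTRIENTS, function(nu) {
    x <- ie[[nu]]
    x <- x[!is.na(x)]
    if (length(x) < spec$min_n)
      stop(sprintf("only %d IE values for %s; need at least %d",
                   length(x), nu, spec$min_n), call. = FALSE)
    x
  })
  a <- vapply(vals, pctile, numeric(1), probs = spec$percentiles[1])
  d <- vapply(vals, pctile, numeric(1), probs = spec$percentiles[2])
  names(a) <- names(d) <- NUTRIENTS
  envelope_constants(a, d, basis = spec$basis, set = spec$set,
                     n = vapply(vals, length, integer(1)), hi_min = spec$hi_min)
}

.ie_list <- function(records, basis) {
  pre <- if (basis == "plant") "ie_plant_" else "ie_root_"
  stats::setNames(lapply(tolower(NUTRIENTS), function(nu) records[[paste0(pre, nu)]]),
                  NUTRIENTS)
}

#' Calibrate envelope constants from derived trial records
#'
#' Convenience wrapper: [filter_records()] then [envelope_from_ies()].
#'
#' @inheritParams filter_records
#' @return An [envelope_constants()] object with an `exclusions` attribute.
#' @export
calibrate_envelope <- function(derived, spec = calibration_spec()) {
  flt <- filter_records(derived, spec)
  env <- envelope_from_ies(.ie_list(flt$records, spec$basis), spec)
  attr(env, "exclusions") <- flt$exclusions
  env
}

#' Percentile-set sensitivity analysis
#'
#' Calibrates envelope constants for the three percentile sets I (2.5/97.5),
#' II (5/95) and III (7.5/92.5) on the same records. By construction of order
#' statistics the envelopes nest: `a_I <= a_II <= a_III < d_III <= d_II <=
#' d_I`.
#'
#' @inheritParams filter_records
#' @param basis,hi_min,min_n Passed to [calibration_spec()].
#' @return A named list of three [envelope_constants()] objects.
#' @export
sensitivity_sets <- function(derived, basis = "plant", hi_min = 0.4, min_n = 20) {
  out <- lapply(names(PERCENTILE_SETS), function(s)
    calibrate_envelope(derived, calibration_spec(hi_min = hi_min, set = s,
                                                 basis = basis, min_n = min_n)))
  names(out) <- names(PERCENTILE_SETS)
  out
}

#' Write / read envelope constants as JSON
#'
#' @param constants An [envelope_constants()] object.
#' @param path JSON file path.
#' @return `write_constants()` returns `path` invisibly; `read_constants()`
#'   returns the reconstructed [envelope_constants()].
#' @export
write_constants <- function(constants, path) {
  stopifnot(inherits(constants, "envelope_constants"))
  jsonlite::write_json(
    list(a = as.list(constants$a), d = as.list(constants$d),
         basis = constants$basis, set = constants$set,
         n = as.list(constants$n), hi_min = constants$hi_min),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_constants
#' @export
read_constants <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_count <- function(v) {
    out <- vapply(NUTRIENTS, function(nu) {
      z <- v[[nu]]
      if (is.null(z) || length(z) == 0 || is.na(z)) NA_integer_ else as.integer(z)
    }, integer(1))
    out
  }
  envelope_constants(unlist(x$a), unlist(x$d), basis = x$basis, set = x$set,
                     n = if (is.null(x$n)) rep(NA_integer_, 3) else as_count(x$n),
                     hi_min = if (is.null(x$hi_min) || length(x$hi_min) == 0)
                       NA_real_ else x$hi_min)
}
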