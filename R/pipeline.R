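## End-to-end analysis pipeline: ingest or synthesize trials, calibrate the
## envelope, generate requirement curves on both bases, validate, and write a
## reproducible output bundle with a run manifest.

#' Pipeline configuration
#'
#' @param out_dir Output directory for the bundle.
#' @param trials_csv Path to a trial-table CSV; `NULL` generates a synthetic
#'   database instead.
#' @param synth A [synth_config()] used when `trials_csv` is `NULL`.
#' @param constants Optional [envelope_constants()] injected directly,
#'   skipping calibration (e.g. the published set-I values); calibration from
#'   the data still runs for the root-removal basis and the report.
#' @param set,hi_min Calibration choices, see [calibration_spec()].
#' @param potential_yield,yield_step Engine choices, see [quefts_config()].
#' @param n_validation_fields,validation_noise_sd Validation-stage data, see
#'   [generate_validation_pairs()].
#' @param seed Integer seed for the stochastic stages.
#' @param quiet Suppress stage messages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("queftsnpk_run_"),
                            trials_csv = NULL,
                            synth = synth_config(n_trials = 1000, seed = seed),
                            constants = NULL,
                            set = "I", hi_min = 0.4,
                            potential_yield = 120000, yield_step = 6000,
                            n_validation_fields = 63, validation_noise_sd = 15,
                            seed = 1, quiet = FALSE) {
  structure(list(out_dir = out_dir, trials_csv = trials_csv, synth = synth,
                 constants = constants, set = set, hi_min = hi_min,
                 potential_yield = potential_yield, yield_step = yield_step,
                 n_validation_fields = n_validation_fields,
                 validation_noise_sd = validation_noise_sd,
                 seed = seed, quiet = quiet),
            class = "pipeline_config")
}

# published reference values the report compares against: linear-part
# requirements per 1000 kg fleshy root on the plant-uptake and root-removal
# bases for radish in China
.reference_rie <- list(plant = c(N = 2.15, P = 0.45, K = 2.58),
                       root = c(N = 1.34, P = 0.30, K = 1.93))

#' Run the full analysis pipeline
#'
#' Stages, in order: (a) ingest or synthesize the trial database and derive
#' per-plot quantities; (b) select records and calibrate the envelope
#' constants on the plant-uptake and root-removal bases (or inject supplied
#' constants for the plant basis); (c) simulate the balanced uptake and
#' removal requirement curves; then validate simulated against (generated)
#' measured uptake. Writes the summary tables, constants JSON, curve CSVs,
#' validation statistics, a human-readable report and a run manifest into
#' `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `trials`, `derived`, `summary`,
#'   `constants` (per basis), `curves` (per basis), `validation`, `manifest`
#'   and `files`.
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(synth = synth_config(n_trials = 300,
#'                                                          seed = 7),
#'                                     seed = 7, quiet = TRUE))
#' attr(res$curves$plant, "linear_rie")
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  say <- function(...) if (!config$quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  out <- function(name) {
    p <- file.path(config$out_dir, name)
    files <<- c(files, p)
    p
  }

  say("stage a: data (%s)", if (is.null(config$trials_csv)) "synthetic" else
      config$trials_csv)
  trials <- stage("data", {
    if (is.null(config$trials_csv)) generate_database(config$synth)
    else read_trials(config$trials_csv)
  })
  derived <- stage("derive", derive_trials(trials))
  smry <- stage("summary", summarize_trials(derived))
  utils::write.csv(smry, out("summary.csv"), row.names = FALSE)

  say("stage b: calibration (set %s, HI >= %g)", config$set, config$hi_min)
  constants <- stage("calibration", {
    plant <- if (!is.null(config$constants)) config$constants
             else calibrate_envelope(derived, calibration_spec(
               hi_min = config$hi_min, set = config$set, basis = "plant"))
    root <- calibrate_envelope(derived, calibration_spec(
      hi_min = config$hi_min, set = config$set, basis = "root"))
    list(plant = plant, root = root)
  })
  write_constants(constants$plant, out("constants_plant.json"))
  write_constants(constants$root, out("constants_root.json"))

  say("stage c: requirement curves (Ymax %g kg/ha)", config$potential_yield)
  qc <- quefts_config(config$potential_yield, config$yield_step)
  curves <- stage("curves", lapply(constants, uptake_curve,
                                   ymax = config$potential_yield, config = qc))
  for (basis in names(curves))
    utils::write.csv(curves[[basis]], out(sprintf("curve_%s.csv", basis)),
                     row.names = FALSE)

  say("stage d: validation (%d fields)", config$n_validation_fields)
  pairs <- stage("validation", generate_validation_pairs(
    n_fields = config$n_validation_fields, constants = constants$plant,
    ymax = config$potential_yield, noise_sd = config$validation_noise_sd,
    seed = config$seed))
  vstats <- validation_stats(pairs)
  utils::write.csv(vstats, out("validation.csv"), row.names = FALSE)

  report <- .pipeline_report(constants, curves, vstats)
  writeLines(report, out("report.txt"))

  manifest <- list(
    package = "queftsnpk",
    version = as.character(utils::packageVersion("queftsnpk")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = list(trials_csv = config$trials_csv, set = config$set,
                  hi_min = config$hi_min,
                  potential_yield = config$potential_yield,
                  yield_step = config$yield_step,
                  n_trials = if (is.null(config$trials_csv))
                    config$synth$n_trials else NA,
                  n_validation_fields = config$n_validation_fields,
                  validation_noise_sd = config$validation_noise_sd,
                  constants_injected = !is.null(config$constants)),
    input_sha = if (!is.null(config$trials_csv))
      unname(tools::md5sum(config$trials_csv)) else NA,
    outputs = basename(files)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  say("done: %d files in %s", length(files), config$out_dir)
  invisible(list(trials = trials, derived = derived, summary = smry,
                 constants = constants, curves = curves, validation = vstats,
                 pairs = pairs, manifest = manifest, files = files))
}

.pipeline_report <- function(constants, curves, vstats) {
  fmt_rie <- function(x) paste(sprintf("%.2f", x), collapse = " / ")
  lines <- c("queftsnpk pipeline report", strrep("=", 60), "")
  for (basis in c("plant", "root")) {
    lr <- attr(curves[[basis]], "linear_rie")
    ref <- .reference_rie[[basis]]
    lines <- c(lines,
      sprintf("%s basis (set %s):", basis, constants[[basis]]$set),
      sprintf("  a (max accumulation): %s kg/kg",
              paste(sprintf("%.1f", constants[[basis]]$a), collapse = " / ")),
      sprintf("  d (max dilution):     %s kg/kg",
              paste(sprintf("%.1f", constants[[basis]]$d), collapse = " / ")),
      sprintf("  linear-part N/P/K per 1000 kg fleshy root: %s kg", fmt_rie(lr)),
      sprintf("  published radish reference:                %s kg", fmt_rie(ref)),
      "")
  }
  lines <- c(lines, "validation (simulated vs measured plant uptake):",
             utils::capture.output(print(vstats, row.names = FALSE)))
  lines
}
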