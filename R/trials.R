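## Trial-table data model: canonical columns, CSV I/O, per-plot derivation,
## and descriptive summaries.

# canonical column names of a trial table; yields and dry matter in t/ha,
# concentrations in g/kg dry matter
.trial_meta_cols <- c("record_id", "province", "year", "season", "treatment")
.trial_num_cols <- c(
  "root_fresh_yield_t_ha", "leaf_fresh_yield_t_ha",
  "root_dm_t_ha", "leaf_dm_t_ha",
  "root_n_g_kg", "root_p_g_kg", "root_k_g_kg",
  "leaf_n_g_kg", "leaf_p_g_kg", "leaf_k_g_kg"
)
# columns that may be missing for a usable (root-basis-only) record
.trial_optional_cols <- c(
  "leaf_fresh_yield_t_ha", "leaf_dm_t_ha",
  "leaf_n_g_kg", "leaf_p_g_kg", "leaf_k_g_kg"
)

#' Canonical trial-table columns
#'
#' @return Character vector of the canonical column names of an on-farm trial
#'   table: plot identifiers and site metadata, fresh yields and organ dry
#'   matter in t/ha, and organ nutrient concentrations in g/kg dry matter.
#' @export
trial_columns <- function() c(.trial_meta_cols, .trial_num_cols)

.check_trial_rows <- function(df, conc_max = 200) {
  reasons <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) {
    bad <- which(bad & is.na(reasons))
    reasons[bad] <<- why
  }
  flag(!is.finite(df$root_fresh_yield_t_ha) | df$root_fresh_yield_t_ha <= 0,
       "root_fresh_yield_t_ha must be > 0")
  flag(!is.finite(df$root_dm_t_ha) | df$root_dm_t_ha <= 0,
       "root_dm_t_ha must be > 0")
  flag(is.finite(df$root_dm_t_ha) & is.finite(df$root_fresh_yield_t_ha) &
         df$root_dm_t_ha > df$root_fresh_yield_t_ha,
       "root dry matter exceeds fresh yield")
  flag(is.finite(df$leaf_dm_t_ha) & df$leaf_dm_t_ha < 0,
       "leaf_dm_t_ha must be >= 0")
  for (col in grep("_[npk]_g_kg$", names(df), value = TRUE)) {
    flag(is.finite(df[[col]]) & (df[[col]] <= 0 | df[[col]] >= conc_max),
         sprintf("%s outside (0, %g) g/kg", col, conc_max))
  }
  # mandatory concentrations for the root organ
  for (col in c("root_n_g_kg", "root_p_g_kg", "root_k_g_kg"))
    flag(is.na(df[[col]]), sprintf("missing %s", col))
  reasons
}

#' Read an on-farm trial table from CSV
#'
#' Parses a UTF-8 CSV with a header row into a validated trial table. Columns
#' are matched by name, so their order is irrelevant. Rows violating the
#' plot-level invariants (positive yields, dry matter not exceeding fresh
#' mass, concentrations within a sanity bound) are rejected and reported, not
#' silently repaired; empty optional cells become `NA`, never zero.
#'
#' @param path Path to a CSV file.
#' @param col_map Optional named character vector translating file headers to
#'   canonical names, e.g. `c(yield = "root_fresh_yield_t_ha")` for a file
#'   whose yield column is called `yield`. See [trial_columns()].
#' @param conc_max Upper sanity bound for concentrations, g/kg dry matter.
#' @return A `data.frame` of class `trial_table` with the canonical columns;
#'   rejected rows are attached as `attr(x, "rejected")`, a data frame with
#'   the file row number and the reason.
#' @seealso [write_trials()], [derive_trials()]
#' @export
read_trials <- function(path, col_map = NULL, conc_max = 200) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    hit <- match(names(col_map), names(raw))
    if (anyNA(hit))
      stop("col_map names absent from file: ",
           paste(names(col_map)[is.na(hit)], collapse = ", "), call. = FALSE)
    names(raw)[hit] <- unname(col_map)
  }
  missing_cols <- setdiff(setdiff(trial_columns(), .trial_optional_cols), names(raw))
  missing_cols <- setdiff(missing_cols, .trial_meta_cols[-1])  # metadata beyond id optional
  if (length(missing_cols))
    stop("mandatory column(s) missing: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (col in setdiff(trial_columns(), names(raw))) raw[[col]] <- NA
  df <- raw[trial_columns()]
  for (col in .trial_meta_cols) df[[col]] <- as.character(df[[col]])
  for (col in .trial_num_cols) {
    v <- df[[col]]
    if (is.character(v)) v[!nzchar(trimws(v))] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at file row(s) %s",
                   col, paste(bad + 1L, collapse = ", ")), call. = FALSE)
    df[[col]] <- num
  }
  reasons <- .check_trial_rows(df, conc_max)
  rejected <- data.frame(file_row = which(!is.na(reasons)) + 1L,
                         reason = reasons[!is.na(reasons)],
                         stringsAsFactors = FALSE)
  if (nrow(rejected))
    warning(sprintf("rejected %d of %d rows; see attr(, 'rejected')",
                    nrow(rejected), nrow(df)), call. = FALSE)
  out <- df[is.na(reasons), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  class(out) <- c("trial_table", class(out))
  out
}

#' Write a trial table to CSV
#'
#' @param trials A trial table (see [read_trials()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials)[trial_columns()], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Derive per-plot nutrient quantities
#'
#' Computes, for every plot, the organ and whole-plant nutrient uptakes, the
#' harvest index, the nutrient harvest indices, and the internal efficiencies
#' on both the plant-uptake and root-removal bases.
#'
#' Units make the arithmetic exact: organ uptake (kg/ha) is organ dry matter
#' (t/ha) times concentration (g/kg), since t x g/kg = kg. The internal
#' efficiency IE (kg fresh fleshy root per kg nutrient) is
#' `1000 * fresh yield (t/ha) / plant uptake (kg/ha)` on a fresh-matter basis
#' (set `dry_matter = TRUE` to express it per kg root dry matter instead),
#' and the reciprocal internal efficiency is `RIE = 1000 / IE`, kg nutrient
#' per 1000 kg fleshy root. The harvest index is root dry matter over plant
#' dry matter, never fresh mass.
#'
#' Plots without leaf measurements get `NA` harvest index and plant-basis
#' quantities (they remain usable on the root-removal basis); plots with
#' `leaf_dm_t_ha = 0` are whole-plant = root plots with harvest index 1.
#'
#' @param trials A trial table from [read_trials()] or
#'   [generate_database()].
#' @param dry_matter If `TRUE`, internal efficiencies are per kg root dry
#'   matter rather than fresh root (default `FALSE`, the fresh-matter
#'   convention used for calibration).
#' @return A `data.frame` of class `derived_trials`: the input columns plus
#'   `root_uptake_*`, `leaf_uptake_*`, `plant_uptake_*` (kg/ha),
#'   `total_dm_t_ha`, `harvest_index`, `nhi_*` (nutrient harvest index,
#'   kg/kg), `ie_plant_*`, `rie_plant_*`, `ie_root_*` where `*` is `n`, `p`,
#'   `k`.
#' @examples
#' tr <- generate_database(synth_config(n_trials = 5, seed = 1))
#' d <- derive_trials(tr)
#' d[, c("harvest_index", "ie_plant_n", "rie_plant_n")]
#' @export
derive_trials <- function(trials, dry_matter = FALSE) {
  df <- as.data.frame(trials)
  yield_basis <- if (dry_matter) df$root_dm_t_ha else df$root_fresh_yield_t_ha
  for (nu in tolower(NUTRIENTS)) {
    root_u <- df$root_dm_t_ha * df[[paste0("root_", nu, "_g_kg")]]
    leaf_u <- ifelse(is.na(df$leaf_dm_t_ha), NA_real_,
                     ifelse(df$leaf_dm_t_ha == 0, 0,
                            df$leaf_dm_t_ha * df[[paste0("leaf_", nu, "_g_kg")]]))
    plant_u <- root_u + leaf_u
    if (any(!is.na(plant_u) & plant_u <= 0))
      stop("zero plant uptake: internal efficiency undefined for plot(s) ",
           paste(df$record_id[!is.na(plant_u) & plant_u <= 0], collapse = ", "),
           call. = FALSE)
    df[[paste0("root_uptake_", nu)]] <- root_u
    df[[paste0("leaf_uptake_", nu)]] <- leaf_u
    df[[paste0("plant_uptake_", nu)]] <- plant_u
    df[[paste0("nhi_", nu)]] <- root_u / plant_u
    df[[paste0("ie_plant_", nu)]] <- 1000 * yield_basis / plant_u
    df[[paste0("rie_plant_", nu)]] <- plant_u / yield_basis
    df[[paste0("ie_root_", nu)]] <- 1000 * yield_basis / root_u
  }
  df$total_dm_t_ha <- df$root_dm_t_ha + ifelse(is.na(df$leaf_dm_t_ha), NA_real_,
                                               df$leaf_dm_t_ha)
  df$harvest_index <- df$root_dm_t_ha / df$total_dm_t_ha
  class(df) <- c("derived_trials", "data.frame")
  df
}

#' Descriptive summary table
#'
#' Replicates the layout of on-farm database summaries: per variable the
#' number of non-missing plots, mean, standard deviation (n - 1 denominator),
#' minimum, quartiles (linear interpolation between order statistics, see
#' [pctile()]) and maximum. Missingness is pairwise-complete: each variable
#' is summarised over the plots where it is observed.
#'
#' @param records A trial table or derived-trials data frame.
#' @param vars Character vector of column names to summarise; defaults to all
#'   numeric columns.
#' @return A `data.frame` with columns `variable`, `n`, `mean`, `sd`, `min`,
#'   `q25`, `median`, `q75`, `max`. Variables absent from the data are
#'   dropped with a warning; a variable observed on a single plot gets `NA`
#'   standard deviation.
#' @export
summarize_trials <- function(records, vars = NULL) {
  df <- as.data.frame(records)
  if (is.null(vars))
    vars <- names(df)[vapply(df, is.numeric, logical(1))]
  absent <- setdiff(vars, names(df))
  if (length(absent)) {
    warning("variable(s) not present, omitted: ", paste(absent, collapse = ", "),
            call. = FALSE)
    vars <- setdiff(vars, absent)
  }
  rows <- lapply(vars, function(v) {
    x <- df[[v]]
    x <- x[!is.na(x)]
    if (length(x) == 0L) {
      warning("variable '", v, "' has no observed values, omitted", call. = FALSE)
      return(NULL)
    }
    q <- pctile(x, c(0, 25, 50, 75, 100))
    data.frame(variable = v, n = length(x), mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
               min = q[1], q25 = q[2], median = q[3], q75 = q[4], max = q[5],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
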