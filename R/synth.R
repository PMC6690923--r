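## Synthetic on-farm trial database generator. Emulates the statistical
## structure of the 2000-2017 Chinese radish database (which has no public
## accession): truncated-normal yield, harvest index and dry-matter fraction,
## and quantile-matched log-normal internal efficiencies whose 2.5th/97.5th
## percentiles equal a chosen envelope, so calibration can be tested against
## a known truth.

# inverse-CDF sampler for a normal truncated to [lo, hi]
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Synthetic database configuration
#'
#' Defaults reproduce the summary statistics of the radish trial database
#' underlying the published calibration: fleshy-root yield 63.5 +/- 26.4 t/ha
#' on [4.6, 119.8], harvest index 0.64 +/- 0.10 on [0.34, 0.91], nutrient
#' harvest indices 0.60/0.68/0.72 (+/- 0.12/0.14/0.12), a root dry-matter
#' fraction of 0.054 +/- 0.01 (from the printed yield, dry-matter and
#' harvest-index means), and plant internal efficiencies drawn from
#' log-normals whose 2.5th/97.5th percentiles equal the set-I envelope
#' constants.
#'
#' @param n_trials Number of plots to generate.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param envelope [envelope_constants()] giving the true IE envelope
#'   (`a*`, `d*`) that the generator's 2.5th/97.5th IE percentiles match.
#' @param yield_mean,yield_sd,yield_range Truncated-normal fleshy-root fresh
#'   yield, t/ha.
#' @param hi_mean,hi_sd,hi_range Truncated-normal harvest index, kg/kg.
#' @param nhi_mean,nhi_sd Nutrient-harvest-index triples, truncated to
#'   (0.05, 0.99).
#' @param root_dmf_mean,root_dmf_sd,root_dmf_range Root dry-matter fraction
#'   (root DM over fresh yield).
#' @param treatments Named fractions of plots per treatment; must sum to 1.
#'   `OPT` is optimal management, `CK` unfertilized check, `minusN`/`minusP`/
#'   `minusK` omission plots.
#' @param omission_bias Strength (>= 0) of the preference with which omission
#'   plots receive the high-IE (diluted) draws of the omitted nutrient. The
#'   assignment reshuffles draws rather than shifting them, so the pooled IE
#'   marginal keeps the configured log-normal exactly.
#' @param conc_max Sanity bound on back-solved concentrations, g/kg;
#'   offending plots are redrawn (capped retries).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_trials = 1000, seed = 1,
                         envelope = envelope_constants(
                           a = c(N = 241.0, P = 1069.2, K = 170.6),
                           d = c(N = 844.6, P = 4480.0, K = 878.7)),
                         yield_mean = 63.5, yield_sd = 26.4,
                         yield_range = c(4.6, 119.8),
                         hi_mean = 0.64, hi_sd = 0.10, hi_range = c(0.34, 0.91),
                         nhi_mean = c(N = 0.60, P = 0.68, K = 0.72),
                         nhi_sd = c(N = 0.12, P = 0.14, K = 0.12),
                         root_dmf_mean = 0.054, root_dmf_sd = 0.01,
                         root_dmf_range = c(0.03, 0.10),
                         treatments = c(OPT = 0.40, CK = 0.15, minusN = 0.15,
                                        minusP = 0.15, minusK = 0.15),
                         omission_bias = 2, conc_max = 200) {
  stopifnot(n_trials >= 0, inherits(envelope, "envelope_constants"),
            yield_range[1] < yield_range[2], hi_range[1] < hi_range[2],
            root_dmf_range[1] < root_dmf_range[2],
            abs(sum(treatments) - 1) < 1e-8, omission_bias >= 0)
  structure(as.list(environment()), class = "synth_config")
}

# log-normal parameters whose 2.5/97.5 percentiles are (a, d)
.ie_lognorm <- function(a, d) {
  list(mu = (log(a) + log(d)) / 2,
       sigma = (log(d) - log(a)) / (2 * stats::qnorm(0.975)))
}

#' Generate a synthetic trial database
#'
#' Draws per-plot yield, harvest index and dry-matter fraction from truncated
#' normals; draws each nutrient's plant internal efficiency from the
#' quantile-matched log-normal (omission plots preferentially receive the
#' diluted, high-IE draws of their omitted nutrient); converts IE to plant
#' uptake, splits it between root and leaf with the nutrient harvest index,
#' and back-solves dry matter and concentrations so that [derive_trials()]
#' reproduces the drawn quantities exactly.
#'
#' @param config A [synth_config()].
#' @return A trial table (see [read_trials()]) with `n_trials` rows. The
#'   drawn IE/HI values round-trip through [derive_trials()] to within
#'   floating-point error.
#' @examples
#' tr <- generate_database(synth_config(n_trials = 3, seed = 42))
#' derive_trials(tr)$ie_plant_n
#' @export
generate_database <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_trials
  cols <- trial_columns()
  if (n == 0) {
    empty <- as.data.frame(stats::setNames(rep(list(character(0)), 5), .trial_meta_cols),
                           stringsAsFactors = FALSE)
    for (col in .trial_num_cols) empty[[col]] <- numeric(0)
    class(empty) <- c("trial_table", class(empty))
    return(empty)
  }
  set.seed(config$seed)
  counts <- diff(round(cumsum(c(0, config$treatments)) * n))
  treatment <- sample(rep(names(config$treatments), times = counts))

  draw_plot <- function(idx) {
    m <- length(idx)
    yield <- .rtruncnorm(m, config$yield_mean, config$yield_sd,
                         config$yield_range[1], config$yield_range[2])
    hi <- .rtruncnorm(m, config$hi_mean, config$hi_sd,
                      config$hi_range[1], config$hi_range[2])
    dmf <- .rtruncnorm(m, config$root_dmf_mean, config$root_dmf_sd,
                       config$root_dmf_range[1], config$root_dmf_range[2])
    list(yield = yield, hi = hi, dmf = dmf)
  }

  base <- draw_plot(seq_len(n))
  ie <- matrix(NA_real_, n, 3, dimnames = list(NULL, NUTRIENTS))
  for (nu in NUTRIENTS) {
    par <- .ie_lognorm(config$envelope$a[[nu]], config$envelope$d[[nu]])
    draws <- stats::rlnorm(n, par$mu, par$sigma)
    omit <- treatment == paste0("minus", nu)
    if (any(omit) && config$omission_bias > 0) {
      # hand the high-IE (diluted) draws to the omission plots, sampling
      # without replacement with rank-power weights; pooled marginal unchanged
      w <- rank(draws)^config$omission_bias
      take <- sample.int(n, sum(omit), prob = w)
      rest <- setdiff(seq_len(n), take)
      ord <- numeric(n)
      ord[omit] <- draws[take]
      ord[!omit] <- draws[rest]
      draws <- ord
    }
    ie[, nu] <- draws
  }
  # nutrient harvest index, truncated per plot to the window where both
  # back-solved organ concentrations stay inside (0, conc_max); this keeps
  # the yield, HI and IE marginals exactly as configured
  draw_nhi <- function(b, ie) {
    root_dm <- b$yield * b$dmf
    leaf_dm <- root_dm / b$hi - root_dm
    plant_u <- 1000 * b$yield / ie
    out <- matrix(NA_real_, length(b$yield), 3, dimnames = list(NULL, NUTRIENTS))
    for (nu in NUTRIENTS) {
      lo <- pmax(0.05, 1 - config$conc_max * 0.99 * leaf_dm / plant_u[, nu])
      hi <- pmin(0.99, config$conc_max * 0.99 * root_dm / plant_u[, nu])
      feasible <- lo < hi
      out[feasible, nu] <- .rtruncnorm(sum(feasible), config$nhi_mean[[nu]],
                                       config$nhi_sd[[nu]],
                                       lo[feasible], hi[feasible])
    }
    out  # NA marks plots with no feasible window (redrawn below)
  }
  nhi <- draw_nhi(base, ie)

  build <- function(b, ie, nhi) {
    root_dm <- b$yield * b$dmf
    total_dm <- root_dm / b$hi
    leaf_dm <- total_dm - root_dm
    plant_u <- 1000 * b$yield / ie              # kg/ha
    root_u <- plant_u * nhi
    leaf_u <- plant_u - root_u
    conc_root <- root_u / root_dm               # g/kg
    conc_leaf <- leaf_u / leaf_dm
    list(root_dm = root_dm, leaf_dm = leaf_dm,
         conc_root = conc_root, conc_leaf = conc_leaf)
  }
  # plots with no feasible nutrient-HI window (joint tails of HI, dry-matter
  # fraction and IE) are redrawn wholesale; rare under the defaults
  retries <- 0
  while (anyNA(nhi) && retries < 20) {
    idx <- which(rowSums(is.na(nhi)) > 0)
    redraw <- draw_plot(idx)
    base$yield[idx] <- redraw$yield
    base$hi[idx] <- redraw$hi
    base$dmf[idx] <- redraw$dmf
    for (nu in NUTRIENTS) {
      par <- .ie_lognorm(config$envelope$a[[nu]], config$envelope$d[[nu]])
      ie[idx, nu] <- stats::rlnorm(length(idx), par$mu, par$sigma)
    }
    sub <- draw_nhi(lapply(base, `[`, idx), ie[idx, , drop = FALSE])
    nhi[idx, ] <- sub
    retries <- retries + 1
  }
  if (anyNA(nhi))
    stop("could not generate plots with concentrations inside the sanity ",
         "bound; reconsider the configuration", call. = FALSE)
  built <- build(base, ie, nhi)
  stopifnot(all(built$conc_root > 0 & built$conc_root < config$conc_max),
            all(built$conc_leaf > 0 & built$conc_leaf < config$conc_max))

  out <- data.frame(
    record_id = sprintf("SYN%05d", seq_len(n)),
    province = "synthetic", year = "2020", season = "autumn",
    treatment = treatment,
    root_fresh_yield_t_ha = base$yield,
    leaf_fresh_yield_t_ha = built$leaf_dm / 0.12,  # nominal leaf DM content
    root_dm_t_ha = built$root_dm,
    leaf_dm_t_ha = built$leaf_dm,
    root_n_g_kg = built$conc_root[, "N"],
    root_p_g_kg = built$conc_root[, "P"],
    root_k_g_kg = built$conc_root[, "K"],
    leaf_n_g_kg = built$conc_leaf[, "N"],
    leaf_p_g_kg = built$conc_leaf[, "P"],
    leaf_k_g_kg = built$conc_leaf[, "K"],
    stringsAsFactors = FALSE
  )
  out <- out[cols]
  class(out) <- c("trial_table", class(out))
  out
}

#' Generate paired simulated/measured validation data
#'
#' Emulates a field validation campaign: draws field target yields, computes
#' the QUEFTS-simulated balanced uptake for each, and perturbs it with
#' additive Gaussian noise to stand in for measured uptake.
#'
#' @param n_fields Number of validation fields (63 mirrors the published
#'   campaign's scale).
#' @param constants [envelope_constants()] driving the simulation.
#' @param ymax Potential yield, kg/ha.
#' @param noise_sd Standard deviation of the additive measurement noise,
#'   kg/ha (scalar or nutrient triple). Zero noise gives measured ==
#'   simulated.
#' @param yield_range Range of field yields as fractions of `ymax`.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `field_id`, `nutrient`, `yield`,
#'   `simulated`, `measured`.
#' @export
generate_validation_pairs <- function(n_fields = 63, constants, ymax = 120000,
                                      noise_sd = 15, yield_range = c(0.2, 0.8),
                                      seed = 1) {
  stopifnot(n_fields >= 1, inherits(constants, "envelope_constants"))
  noise_sd <- if (length(noise_sd) == 1) rep(noise_sd, 3) else as_triple(noise_sd)
  set.seed(seed)
  yields <- stats::runif(n_fields, yield_range[1], yield_range[2]) * ymax
  sim <- t(vapply(yields, balanced_uptake, numeric(3),
                  constants = constants, ymax = ymax))
  out <- do.call(rbind, lapply(1:3, function(i)
    data.frame(field_id = sprintf("F%03d", seq_len(n_fields)),
               nutrient = NUTRIENTS[i], yield = yields,
               simulated = sim[, i],
               measured = sim[, i] + stats::rnorm(n_fields, 0, noise_sd[i]),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
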