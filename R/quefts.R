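## QUEFTS linear-parabolic-plateau engine: yield bounds, pairwise estimates,
## forward prediction, balanced-uptake solving, requirement curves.

#' Engine configuration
#'
#' @param potential_yield Season- and climate-adjusted maximum attainable
#'   fleshy-root yield Ymax, kg/ha (fresh). Radish calibrations in China span
#'   40 000 to 120 000 kg/ha.
#' @param yield_step Spacing of target yields in [uptake_curve()], kg/ha.
#' @param tol Relative convergence tolerance of the balanced-uptake solver on
#'   yield.
#' @param objective Balanced-uptake criterion, see [balanced_uptake()].
#' @return A list of class `quefts_config`.
#' @export
quefts_config <- function(potential_yield = 120000, yield_step = 6000,
                          tol = 1e-8,
                          objective = c("balanced_position", "min_total",
                                        "min_scaled")) {
  stopifnot(potential_yield > 0, yield_step > 0, yield_step <= potential_yield,
            tol > 0)
  structure(list(potential_yield = potential_yield, yield_step = yield_step,
                 tol = tol, objective = match.arg(objective)),
            class = "quefts_config")
}

#' Yield bounds at maximum accumulation and dilution
#'
#' For an uptake `U_i` of nutrient `i`, the yield cannot fall below
#' `YA_i = a_i * U_i` (all of the nutrient hoarded, maximum accumulation) nor
#' exceed `YD_i = d_i * U_i` (nutrient maximally diluted), both capped at the
#' potential yield.
#'
#' @param uptake Nutrient triple of plant uptakes, kg/ha (non-negative).
#' @param constants [envelope_constants()].
#' @param ymax Potential yield, kg/ha.
#' @return A list with triples `ya` and `yd`, kg/ha, `ya <= yd` componentwise.
#' @examples
#' setI <- envelope_constants(a = c(N = 241.0, P = 1069.2, K = 170.6),
#'                            d = c(N = 844.6, P = 4480.0, K = 878.7))
#' yield_bounds(c(N = 100, P = 20, K = 120), setI, 120000)
#' @export
yield_bounds <- function(uptake, constants, ymax) {
  u <- as_triple(uptake)
  stopifnot(inherits(constants, "envelope_constants"), ymax > 0)
  list(ya = pmin(constants$a * u, ymax), yd = pmin(constants$d * u, ymax))
}

#' Pairwise linear-parabolic-plateau yield estimate
#'
#' The yield estimate for nutrient `i` given the yield range
#' `[ya_j, yd_j]` allowed by another nutrient `j`: linear at maximum dilution
#' (`EY = d_i * U_i`) while `U_i <= ya_j / d_i`, a parabola rising to the
#' plateau `EY = yd_j` with zero slope at `U_i = yd_j / a_i`, and the plateau
#' beyond. Continuous at both junctions; the result is additionally capped at
#' the potential yield.
#'
#' @param u_i Uptake of the estimated nutrient, kg/ha (vectorised).
#' @param a_i,d_i Envelope constants of nutrient `i`, kg/kg.
#' @param ya_j,yd_j Yield bounds of the paired nutrient `j`, kg/ha, already
#'   capped at `ymax`.
#' @param ymax Potential yield, kg/ha.
#' @return Yield estimate(s), kg/ha.
#' @export
pairwise_yield <- function(u_i, a_i, d_i, ya_j, yd_j, ymax) {
  if (any(u_i < 0)) stop("uptake must be non-negative", call. = FALSE)
  if (yd_j == 0) return(rep(0, length(u_i)))  # paired nutrient absent: no yield
  low <- ya_j / d_i   # uptake below which nutrient i is maximally diluted
  high <- yd_j / a_i  # uptake beyond which extra i adds no yield
  if (any(high <= low))
    stop("invalid envelope: plateau onset at or below dilution limit", call. = FALSE)
  x <- (u_i - low) / (high - low)
  ey <- ifelse(u_i <= low, d_i * u_i,
               ifelse(u_i >= high, yd_j,
                      ya_j + (yd_j - ya_j) * (2 * x - x^2)))
  pmin(ey, ymax)
}

#' Forward yield prediction from an uptake triple
#'
#' Averages the six ordered-pair estimates `EY_ij` (`i != j` over N, P, K) --
#' the standard QUEFTS combination.
#'
#' @param uptake Nutrient triple of plant uptakes, kg/ha.
#' @param constants [envelope_constants()].
#' @param ymax Potential yield, kg/ha.
#' @return Predicted fleshy-root yield, kg/ha, in
#'   `[0, min(ymax, min(d * uptake))]`.
#' @examples
#' setI <- envelope_constants(a = c(N = 241.0, P = 1069.2, K = 170.6),
#'                            d = c(N = 844.6, P = 4480.0, K = 878.7))
#' predict_yield(c(N = 129, P = 27, K = 155), setI, 120000)
#' @export
predict_yield <- function(uptake, constants, ymax) {
  u <- as_triple(uptake)
  b <- yield_bounds(u, constants, ymax)
  tot <- 0
  for (i in 1:3) for (j in 1:3) if (i != j)
    tot <- tot + pairwise_yield(u[i], constants$a[i], constants$d[i],
                                b$ya[j], b$yd[j], ymax)
  unname(tot / 6)
}

# uptake triple at relative reciprocal-IE position t in [0, 1]:
# t = 0 puts every nutrient at maximum dilution (RIE = 1/d),
# t = 1 at maximum accumulation (RIE = 1/a)
.uptake_at_position <- function(t, yt, constants) {
  rie <- 1 / constants$d + t * (1 / constants$a - 1 / constants$d)
  rie * yt
}

#' Balanced nutrient uptake for a target yield
#'
#' Solves the QUEFTS model in reverse: the uptake triple `U*` with
#' `predict_yield(U*) = yt`. The default criterion, `"balanced_position"`,
#' defines balance as all three nutrients sitting at the same relative
#' position between their dilution and accumulation boundaries -- the
#' reciprocal internal efficiency of each nutrient is the same fraction of
#' the way from `1/d` to `1/a` -- which reduces the solve to a monotone
#' one-dimensional root problem. At `yt = ymax` the solution is exactly
#' `ymax / a` (all nutrients at maximum accumulation), the smallest uptake
#' achieving the potential yield.
#'
#' Two alternative criteria are provided for comparison (see the methods
#' vignette for the selection protocol): `"min_total"` minimises
#' `U_N + U_P + U_K` and `"min_scaled"` minimises uptake scaled by the
#' mid-envelope requirement `sum(U_i * (a_i + d_i) / 2)`, both subject to
#' `predict_yield(U) >= yt` via multi-start Nelder-Mead around the
#' balanced-position solution.
#'
#' @param yt Target yield, kg/ha, in `[0, ymax]`.
#' @param constants [envelope_constants()].
#' @param ymax Potential yield, kg/ha.
#' @param config [quefts_config()]; supplies the tolerance and default
#'   objective.
#' @param objective Overrides `config$objective`.
#' @return Nutrient triple of uptakes, kg/ha. `yt = 0` returns zeros.
#' @examples
#' setI <- envelope_constants(a = c(N = 241.0, P = 1069.2, K = 170.6),
#'                            d = c(N = 844.6, P = 4480.0, K = 878.7))
#' balanced_uptake(60000, setI, 120000)
#' @export
balanced_uptake <- function(yt, constants, ymax,
                            config = quefts_config(potential_yield = ymax),
                            objective = config$objective) {
  stopifnot(inherits(constants, "envelope_constants"))
  if (yt < 0 || yt > ymax)
    stop("target yield must be within [0, potential yield]", call. = FALSE)
  if (yt == 0) return(nutrient_triple(0, 0, 0))
  u_pos <- .solve_position(yt, constants, ymax, config$tol)
  u <- switch(objective,
              balanced_position = u_pos,
              min_total = .solve_min(yt, constants, ymax, config$tol, u_pos,
                                     weights = c(1, 1, 1)),
              min_scaled = .solve_min(yt, constants, ymax, config$tol, u_pos,
                                      weights = (constants$a + constants$d) / 2))
  ye <- predict_yield(u, constants, ymax)
  if (abs(ye - yt) > 1e-3 * yt)
    stop(sprintf(paste0("balanced-uptake solver did not converge: target %g, ",
                        "achieved %g (objective %s)"), yt, ye, objective),
         call. = FALSE)
  u
}

.solve_position <- function(yt, constants, ymax, tol) {
  g <- function(t) predict_yield(.uptake_at_position(t, yt, constants),
                                 constants, ymax) - yt
  # g is increasing in t; g(1) >= 0 always (uptake ymax/a at yt = ymax)
  g1 <- g(1)
  if (g1 < 0)
    stop("target yield unreachable within the envelope", call. = FALSE)
  if (g1 == 0) return(.uptake_at_position(1, yt, constants))
  t <- stats::uniroot(g, c(0, 1), tol = tol, maxiter = 200L)$root
  .uptake_at_position(t, yt, constants)
}

.solve_min <- function(yt, constants, ymax, tol, start, weights) {
  # minimise weighted total uptake over (U_P, U_K), with U_N solved from the
  # yield constraint; multi-start to dodge local minima on the kinked surface
  solve_un <- function(upk) {
    f <- function(un) predict_yield(c(N = un, P = upk[1], K = upk[2]),
                                    constants, ymax) - yt
    hi <- ymax / constants$a[["N"]] * 2
    if (f(hi) < 0) return(NA_real_)
    if (f(0) >= 0) return(0)
    stats::uniroot(f, c(0, hi), tol = tol * yt)$root
  }
  fn <- function(lp) {
    upk <- unname(exp(lp))
    if (any(!is.finite(upk))) return(1e12)
    un <- solve_un(upk)
    if (is.na(un)) return(1e12)
    sum(weights * c(un, upk))
  }
  best <- NULL
  starts <- list(log(start[c("P", "K")]),
                 log(start[c("P", "K")] * c(1.5, 0.7)),
                 log(start[c("P", "K")] * c(0.7, 1.5)),
                 log(start[c("P", "K")] * c(2.0, 2.0)))
  for (st in starts) {
    o <- stats::optim(st, fn, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  upk <- unname(exp(best$par))
  nutrient_triple(solve_un(upk), upk[1], upk[2])
}

#' Balanced uptake requirement curve
#'
#' Evaluates [balanced_uptake()] at target yields `0, step, 2 step, ...,
#' ymax` and tabulates the uptakes with their internal and reciprocal
#' internal efficiencies -- the requirement table a fertilizer recommendation
#' is built from. The headline per-1000-kg requirement is the reciprocal
#' internal efficiency on the linear segment, reported at `0.25 * ymax`
#' (safely inside the linear range, where it is independent of the potential
#' yield).
#'
#' @inheritParams balanced_uptake
#' @param constants [envelope_constants()].
#' @param ymax Potential yield, kg/ha.
#' @return A `data.frame` of class `uptake_curve` with columns `yield`,
#'   `uptake_n`, `uptake_p`, `uptake_k` (kg/ha), `ie_n`, `ie_p`, `ie_k`
#'   (kg/kg) and `rie_n`, `rie_p`, `rie_k` (kg/t); the linear-segment RIE
#'   triple is attached as `attr(x, "linear_rie")`.
#' @examples
#' setI <- envelope_constants(a = c(N = 241.0, P = 1069.2, K = 170.6),
#'                            d = c(N = 844.6, P = 4480.0, K = 878.7))
#' cv <- uptake_curve(setI, ymax = 120000)
#' attr(cv, "linear_rie")
#' @export
uptake_curve <- function(constants, ymax,
                         config = quefts_config(potential_yield = ymax)) {
  yts <- seq(0, ymax, by = config$yield_step)
  if (yts[length(yts)] != ymax) yts <- c(yts, ymax)
  rows <- t(vapply(yts, function(yt)
    balanced_uptake(yt, constants, ymax, config), numeric(3)))
  ie <- ifelse(rows > 0, yts / rows, 0)
  out <- data.frame(yield = yts,
                    uptake_n = rows[, 1], uptake_p = rows[, 2], uptake_k = rows[, 3],
                    ie_n = ie[, 1], ie_p = ie[, 2], ie_k = ie[, 3],
                    rie_n = ifelse(ie[, 1] > 0, 1000 / ie[, 1], 0),
                    rie_p = ifelse(ie[, 2] > 0, 1000 / ie[, 2], 0),
                    rie_k = ifelse(ie[, 3] > 0, 1000 / ie[, 3], 0))
  attr(out, "linear_rie") <- linear_rie(constants, ymax, config)
  class(out) <- c("uptake_curve", "data.frame")
  out
}

#' Linear-segment nutrient requirement per 1000 kg fleshy root
#'
#' The balanced reciprocal internal efficiency on the linear part of the
#' requirement curve, evaluated at a target of `0.25 * ymax` where no
#' envelope cap binds; by the homogeneity of the model it is independent of
#' the potential yield.
#'
#' @inheritParams uptake_curve
#' @return Nutrient triple, kg nutrient per 1000 kg fleshy root.
#' @export
linear_rie <- function(constants, ymax,
                       config = quefts_config(potential_yield = ymax)) {
  yt <- 0.25 * ymax
  u <- balanced_uptake(yt, constants, ymax, config)
  1000 * u / yt
}
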