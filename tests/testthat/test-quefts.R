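test_that("yield bounds are products capped at the potential yield", {
  b0 <- yield_bounds(c(N = 0, P = 0, K = 0), set1, 120000)
  expect_equal(unname(b0$ya), c(0, 0, 0))
  expect_equal(unname(b0$yd), c(0, 0, 0))

  b <- yield_bounds(c(N = 100, P = 20, K = 120), set1, 120000)
  expect_equal(unname(b$ya["N"]), 24100)
  expect_equal(unname(b$yd["N"]), 84460)

  b_cap <- yield_bounds(c(N = 1000, P = 1000, K = 1000), set1, 120000)
  expect_equal(unname(b_cap$ya["N"]), 120000)
  expect_equal(unname(b_cap$yd["N"]), 120000)

  expect_error(yield_bounds(c(N = -1, P = 1, K = 1), set1, 120000),
               "non-negative")
})

test_that("pairwise estimate matches the hand-evaluated parabola and is continuous", {
  # hand oracle: a_N 241.0, d_N 844.6, bounds of the paired nutrient
  # (20000, 40000): low = 20000/844.6, high = 40000/241, at U = 60
  # x = (60 - 23.6799) / (165.9751 - 23.6799) = 0.25525
  low <- 20000 / 844.6
  high <- 40000 / 241.0
  x <- (60 - low) / (high - low)
  expect_equal(x, 0.25525, tolerance = 1e-4)
  hand <- 20000 + (40000 - 20000) * (2 * x - x^2)
  got <- pairwise_yield(60, 241.0, 844.6, 20000, 40000, 120000)
  expect_equal(got, hand)
  expect_equal(round(got), 28907)

  # continuity at both junctions, zero slope at the plateau onset
  expect_equal(pairwise_yield(low, 241.0, 844.6, 20000, 40000, 120000),
               844.6 * low)
  expect_equal(pairwise_yield(high, 241.0, 844.6, 20000, 40000, 120000), 40000)
  expect_equal(pairwise_yield(high * 1.5, 241.0, 844.6, 20000, 40000, 120000),
               40000)

  # property: continuity across junctions for random envelopes
  set.seed(42)
  for (r in 1:20) {
    a_i <- runif(1, 100, 500); d_i <- a_i * runif(1, 2, 6)
    ya <- runif(1, 5000, 30000); yd <- ya * runif(1, 1.5, 4)
    lo <- ya / d_i; hi <- yd / a_i
    eps <- 1e-7
    for (u0 in c(lo, hi)) {
      left <- pairwise_yield(u0 * (1 - eps), a_i, d_i, ya, yd, 1e9)
      right <- pairwise_yield(u0 * (1 + eps), a_i, d_i, ya, yd, 1e9)
      expect_equal(left, right, tolerance = 1e-4)
    }
  }
})

test_that("forward prediction: zeros, saturation, homogeneity, monotonicity", {
  expect_equal(predict_yield(c(N = 0, P = 0, K = 0), set1, 120000), 0)
  expect_equal(predict_yield(c(N = 1e4, P = 1e4, K = 1e4), set1, 120000), 120000)

  # printed balanced triple for the 60 t/ha target predicts ~60 t/ha
  expect_equal(predict_yield(c(N = 129, P = 27, K = 155), set1, 120000),
               60000, tolerance = 0.01)

  # homogeneity when no cap binds
  u <- c(N = 30, P = 6, K = 36)
  y1 <- predict_yield(u, set1, 1e9)
  y2 <- predict_yield(2.5 * u, set1, 1e9)
  expect_equal(y2, 2.5 * y1, tolerance = 1e-10)

  # monotone in every component (random spot checks)
  set.seed(7)
  for (r in 1:10) {
    env <- random_envelope()
    u <- c(N = runif(1, 10, 200), P = runif(1, 2, 50), K = runif(1, 10, 250))
    y0 <- predict_yield(u, env, 120000)
    for (nu in c("N", "P", "K")) {
      u2 <- u; u2[nu] <- u2[nu] * 1.1
      expect_gte(predict_yield(u2, env, 120000) + 1e-9, y0)
    }
  }

  # bounded by the weakest dilution yield
  u3 <- c(N = 50, P = 10, K = 60)
  expect_lte(predict_yield(u3, set1, 120000), min(120000, min(set1$d * u3)))
})

test_that("balanced uptake round-trips through forward prediction", {
  expect_equal(unname(balanced_uptake(0, set1, 120000)), c(0, 0, 0))
  expect_error(balanced_uptake(130000, set1, 120000), "within")

  for (yt in c(6000, 30000, 48000, 90000, 120000)) {
    u <- balanced_uptake(yt, set1, 120000)
    expect_equal(predict_yield(u, set1, 120000), yt, tolerance = 1e-3)
  }

  # at the potential yield the solution is the smallest uptake achieving it:
  # every nutrient at maximum accumulation
  u_top <- balanced_uptake(120000, set1, 120000)
  expect_equal(unclass(u_top), unclass(120000 / set1$a), tolerance = 1e-6)
})

test_that("balanced uptake agrees with the brute-force grid oracle", {
  set.seed(123)
  for (r in 1:20) {
    env <- random_envelope()
    ymax <- runif(1, 60000, 140000)
    yt <- runif(1, 0.1, 0.95) * ymax
    u_solver <- balanced_uptake(yt, env, ymax)
    u_oracle <- oracle_balanced(yt, env$a, env$d, ymax)
    expect_equal(unclass(u_solver), unclass(u_oracle), tolerance = 0.01)
    # the oracle's own yield evaluation confirms the solve
    expect_equal(oracle_yield(u_solver, env$a, env$d, ymax), yt,
                 tolerance = 1e-3 * yt)
  }
})

test_that("alternative solver objectives satisfy the yield constraint", {
  for (obj in c("min_total", "min_scaled")) {
    u <- balanced_uptake(30000, set1, 120000, objective = obj)
    expect_equal(predict_yield(u, set1, 120000), 30000, tolerance = 1e-3)
  }
  # minimising raw total uptake spends less on the cheap-per-kg nutrients:
  # total is below the balanced-position total
  u_min <- balanced_uptake(30000, set1, 120000, objective = "min_total")
  u_bal <- balanced_uptake(30000, set1, 120000)
  expect_lt(sum(u_min), sum(u_bal))
})

test_that("requirement curve is monotone with the expected IE/RIE structure", {
  cv <- uptake_curve(set1, 120000)
  expect_equal(cv$yield, seq(0, 120000, by = 6000))
  for (col in c("uptake_n", "uptake_p", "uptake_k"))
    expect_true(all(diff(cv[[col]]) > 0))
  pos <- cv$yield > 0
  for (nu in c("n", "p", "k")) {
    ie <- cv[[paste0("ie_", nu)]][pos]
    rie <- cv[[paste0("rie_", nu)]][pos]
    # non-increasing / non-decreasing up to the root solver's precision
    expect_true(all(diff(ie) < 1e-6 * ie[-1]))
    expect_true(all(diff(rie) > -1e-6 * rie[-1]))
    expect_equal(cv[[paste0("ie_", nu)]][pos] * cv[[paste0("rie_", nu)]][pos],
                 rep(1000, sum(pos)), tolerance = 1e-9)
  }
  # near the potential yield the requirement per tonne exceeds the linear part
  lr <- attr(cv, "linear_rie")
  expect_gt(cv$rie_n[cv$yield == 120000], 1.4 * lr[["N"]])
})

test_that("linear-part requirement is independent of the potential yield", {
  lr <- lapply(c(40000, 80000, 120000), function(ym) linear_rie(set1, ym))
  expect_equal(lr[[1]], lr[[2]], tolerance = 1e-6)
  expect_equal(lr[[2]], lr[[3]], tolerance = 1e-6)
})

test_that("the same engine runs on root-removal constants", {
  d <- derive_trials(generate_database(synth_config(n_trials = 400, seed = 13)))
  env_root <- calibrate_envelope(d, calibration_spec(basis = "root"))
  cv <- uptake_curve(env_root, 120000)
  lr_root <- attr(cv, "linear_rie")
  lr_plant <- linear_rie(calibrate_envelope(d, calibration_spec()), 120000)
  # removal requirements keep the curve structure but sit below plant uptake,
  # roughly in proportion to the nutrient harvest indices
  expect_true(all(lr_root < lr_plant))
  expect_true(all(diff(cv$uptake_n) > 0))
})
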