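# shared fixtures

# published set-I envelope constants for radish in China (plant basis)
set1 <- envelope_constants(a = c(N = 241.0, P = 1069.2, K = 170.6),
                           d = c(N = 844.6, P = 4480.0, K = 878.7),
                           set = "I")

# a small handwritten trial table
make_trials <- function() {
  data.frame(
    record_id = c("A1", "A2", "A3"),
    province = "Hebei", year = "2015", season = "autumn",
    treatment = c("OPT", "CK", "minusN"),
    root_fresh_yield_t_ha = c(72.4, 41.2, 55.8),
    leaf_fresh_yield_t_ha = c(28.1, 18.9, 20.3),
    root_dm_t_ha = c(3.91, 2.43, 3.07),
    leaf_dm_t_ha = c(2.05, 1.41, 1.52),
    root_n_g_kg = c(27.5, 24.1, 19.8),
    root_p_g_kg = c(6.1, 5.2, 6.4),
    root_k_g_kg = c(45.2, 40.6, 47.0),
    leaf_n_g_kg = c(33.0, 29.4, 24.6),
    leaf_p_g_kg = c(5.0, 4.4, 5.3),
    leaf_k_g_kg = c(30.8, 27.5, 32.1),
    stringsAsFactors = FALSE
  )
}

write_trials_csv <- function(df = make_trials()) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# random valid envelope for property tests
random_envelope <- function() {
  a <- c(N = runif(1, 150, 400), P = runif(1, 700, 1500), K = runif(1, 100, 300))
  d <- a * runif(3, 2.2, 6)
  envelope_constants(a, d)
}
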