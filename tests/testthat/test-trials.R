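test_that("CSV round trip preserves every field and survives column permutation", {
  df <- make_trials()
  path <- write_trials_csv(df)
  tr <- read_trials(path)
  expect_s3_class(tr, "trial_table")
  expect_equal(nrow(tr), 3)
  expect_equal(tr$root_fresh_yield_t_ha, df$root_fresh_yield_t_ha, tolerance = 1e-9)

  # write-then-read round trip
  path2 <- tempfile(fileext = ".csv")
  write_trials(tr, path2)
  tr2 <- read_trials(path2)
  for (col in trial_columns())
    expect_equal(tr2[[col]], tr[[col]], tolerance = 1e-9, label = col)

  # permuted column order parses identically (header-keyed)
  perm <- df[, sample(ncol(df))]
  tr3 <- read_trials(write_trials_csv(perm))
  expect_equal(as.data.frame(tr3), as.data.frame(tr))
})

test_that("invalid rows are rejected with diagnostics, bad schema errors", {
  df <- make_trials()
  df$root_dm_t_ha[2] <- df$root_fresh_yield_t_ha[2] + 1  # DM > fresh mass
  expect_warning(tr <- read_trials(write_trials_csv(df)), "rejected 1 of 3")
  expect_equal(nrow(tr), 2)
  rej <- attr(tr, "rejected")
  expect_equal(rej$file_row, 3L)  # header is row 1
  expect_match(rej$reason, "dry matter exceeds")

  # missing mandatory column
  df2 <- make_trials()
  df2$root_dm_t_ha <- NULL
  expect_error(read_trials(write_trials_csv(df2)), "root_dm_t_ha")

  # non-numeric cell names the column and row
  df3 <- make_trials()
  df3$root_n_g_kg <- as.character(df3$root_n_g_kg)
  df3$root_n_g_kg[3] <- "oops"
  expect_error(read_trials(write_trials_csv(df3)), "root_n_g_kg.*4")

  # col_map renames foreign headers
  df4 <- make_trials()
  names(df4)[names(df4) == "root_fresh_yield_t_ha"] <- "yield"
  tr4 <- read_trials(write_trials_csv(df4),
                     col_map = c(yield = "root_fresh_yield_t_ha"))
  expect_equal(tr4$root_fresh_yield_t_ha, make_trials()$root_fresh_yield_t_ha)
})

test_that("empty optional cells become NA, never zero", {
  df <- make_trials()
  df$leaf_dm_t_ha[1] <- NA
  df$leaf_n_g_kg[1] <- NA
  tr <- read_trials(write_trials_csv(df))
  expect_true(is.na(tr$leaf_dm_t_ha[1]))
  expect_true(is.na(tr$leaf_n_g_kg[1]))
})

test_that("derivation arithmetic matches hand calculations", {
  df <- make_trials()[1, ]
  df$root_dm_t_ha <- 3.5
  df$root_n_g_kg <- 28.0
  d <- derive_trials(df)
  # t/ha x g/kg = kg/ha with conversion factor exactly 1
  expect_equal(d$root_uptake_n, 3.5 * 28.0)

  # IE / RIE from a printed-magnitude example: yield 63 t/ha, plant N uptake
  # 151.6 kg/ha -> IE 63000/151.6, RIE = 1000/IE (hand arithmetic)
  df2 <- make_trials()[1, ]
  df2$root_fresh_yield_t_ha <- 63.0
  df2$root_dm_t_ha <- 4.0
  df2$leaf_dm_t_ha <- 2.0
  df2$root_n_g_kg <- 25.0   # root uptake 100
  df2$leaf_n_g_kg <- 25.8   # leaf uptake 51.6 -> plant 151.6
  d2 <- derive_trials(df2)
  expect_equal(d2$plant_uptake_n, 151.6)
  expect_equal(d2$ie_plant_n, 63000 / 151.6, tolerance = 1e-12)
  expect_equal(round(d2$ie_plant_n, 2), 415.57)
  expect_equal(round(d2$rie_plant_n, 3), 2.406)

  # componentwise identities
  dd <- derive_trials(make_trials())
  for (nu in c("n", "p", "k")) {
    expect_equal(dd[[paste0("plant_uptake_", nu)]],
                 dd[[paste0("root_uptake_", nu)]] + dd[[paste0("leaf_uptake_", nu)]])
    expect_equal(dd[[paste0("ie_plant_", nu)]] * dd[[paste0("rie_plant_", nu)]],
                 rep(1000, 3), tolerance = 1e-9)
    expect_true(all(dd[[paste0("nhi_", nu)]] > 0 & dd[[paste0("nhi_", nu)]] <= 1))
  }
  expect_equal(dd$harvest_index,
               dd$root_dm_t_ha / (dd$root_dm_t_ha + dd$leaf_dm_t_ha))
})

test_that("degenerate organs: no leaves means HI 1, missing leaves means NA", {
  df <- make_trials()[1, ]
  df$leaf_dm_t_ha <- 0
  d <- derive_trials(df)
  expect_equal(d$harvest_index, 1)
  expect_equal(d$plant_uptake_n, d$root_uptake_n)

  df$leaf_dm_t_ha <- NA
  d2 <- derive_trials(df)
  expect_true(is.na(d2$harvest_index))
  expect_true(is.na(d2$ie_plant_n))
  expect_false(is.na(d2$ie_root_n))  # still usable on the removal basis
})

test_that("derivation is scale-consistent", {
  df <- make_trials()
  d0 <- derive_trials(df)

  # doubling DM alone doubles uptakes but changes HI-free ratios: IE halves
  df_dm <- df
  for (col in c("root_dm_t_ha", "leaf_dm_t_ha")) df_dm[[col]] <- 2 * df[[col]]
  d1 <- derive_trials(df_dm)
  expect_equal(d1$plant_uptake_n, 2 * d0$plant_uptake_n)
  expect_equal(d1$harvest_index, d0$harvest_index)
  expect_equal(d1$ie_plant_n, d0$ie_plant_n / 2)

  # doubling DM and fresh yield together leaves HI and IE unchanged
  df_all <- df_dm
  df_all$root_fresh_yield_t_ha <- 2 * df$root_fresh_yield_t_ha
  d2 <- derive_trials(df_all)
  expect_equal(d2$ie_plant_n, d0$ie_plant_n)
  expect_equal(d2$harvest_index, d0$harvest_index)
})

test_that("summaries match closed forms and are permutation-invariant", {
  df <- data.frame(v = c(1, 2, 3, 4, 5))
  s <- summarize_trials(df, "v")
  expect_equal(s$mean, 3)
  expect_equal(s$median, 3)
  expect_equal(s$min, 1)
  expect_equal(s$max, 5)
  expect_equal(s$sd, sd(1:5))

  # single record: sd missing, quartiles equal the value
  s1 <- summarize_trials(data.frame(v = 7), "v")
  expect_true(is.na(s1$sd))
  expect_equal(unlist(s1[c("min", "q25", "median", "q75", "max")]),
               rep(7, 5), ignore_attr = TRUE)

  # permutation invariance
  set.seed(1)
  x <- rnorm(40)
  s_a <- summarize_trials(data.frame(v = x), "v")
  s_b <- summarize_trials(data.frame(v = sample(x)), "v")
  expect_equal(s_a, s_b)

  # absent variable warns and is omitted
  expect_warning(s2 <- summarize_trials(df, c("v", "nope")), "nope")
  expect_equal(s2$variable, "v")
})

test_that("bundled demo table reads cleanly", {
  path <- system.file("extdata", "synthetic_trials_demo.csv",
                      package = "queftsnpk")
  tr <- read_trials(path)
  expect_equal(nrow(tr), 12)
  d <- derive_trials(tr)
  expect_true(is.na(d$harvest_index[d$record_id == "D011"]))  # no leaf data
  expect_true(all(d$harvest_index > 0.5, na.rm = TRUE))
})
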