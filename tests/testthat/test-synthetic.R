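test_that("every generator round-trips through its paired fit at zero noise", {
  wt <- wt_defaults()
  cv <- simulate_melt_curve(noise_frac = 0)
  f <- fit_two_state_melt(cv)
  expect_equal(f$Tm, wt$Tm, tolerance = 1e-4)
  expect_equal(f$dH_vH, wt$dH, tolerance = 1e-4)

  cd <- simulate_chem_denat(noise_frac = 0)
  fc <- fit_chemical_denaturation(cd$denaturant_M, cd$ellipticity)
  expect_equal(fc$dG0, wt$dG0, tolerance = 1e-4)

  dc <- simulate_decay_trace(noise_frac = 0)
  fd <- fit_decay(dc$time_s, dc$ellipticity)
  expect_equal(fd$k_Ag, wt$k_Ag, tolerance = 1e-4)

  ar <- simulate_arrhenius_series(noise_cv = 0)
  fa <- fit_arrhenius(ar$temperature_K, ar$k_Ag)
  expect_equal(fa$Ea, wt$Ea, tolerance = 1e-6)
  expect_equal(fa$lnA, wt$lnA, tolerance = 1e-6)

  mm <- simulate_mm_titration(noise_cv = 0)
  fm <- fit_michaelis_menten(mm$substrate_uM, mm$rate_uM_per_s,
                             enzyme_C_T = 5, K_D = wt$K_D)
  expect_equal(fm$Km, wt$Km, tolerance = 1e-4)
  expect_equal(fm$kcat, wt$kcat, tolerance = 1e-4)

  cs <- simulate_ctotal_scan(noise_cv = 0)
  fk <- fit_activity_vs_concentration(cs$ctotal_uM, cs$rate_uM_per_s, 2000,
                                      enzyme_kinetics(wt$Km, wt$kcat))
  expect_equal(fk$K_D, wt$K_D, tolerance = 1e-4)

  dy <- simulate_dosy_decay(noise_frac = 0)
  fy <- fit_stejskal_tanner(dy$gradient_fraction, dy$intensity)
  expect_equal(fy$D, 5e-11, tolerance = 1e-4)
})

test_that("generate() is deterministic and writes matching truth records", {
  d1 <- tempfile("gen1"); d2 <- tempfile("gen2")
  des <- simulation_design("monomer_melt", seed = 7L)
  g1 <- generate(des, dir = d1)
  g2 <- generate(des, dir = d2)
  expect_identical(readLines(file.path(d1, "melt.csv")),
                   readLines(file.path(d2, "melt.csv")))
  expect_identical(readLines(file.path(d1, "truth.json")),
                   readLines(file.path(d2, "truth.json")))
  tr <- jsonlite::read_json(file.path(d1, "truth.json"),
                            simplifyVector = TRUE)
  expect_equal(tr$Tm, wt_defaults()$Tm)
  expect_equal(tr$seed, 7)
  # the written file refits to the truth record's parameters
  cv <- read_melt_csv(file.path(d1, "melt.csv"), C_T = 0.5)
  f <- fit_two_state_melt(cv)
  expect_equal(f$Tm, tr$Tm, tolerance = 5e-3)
  unlink(c(d1, d2), recursive = TRUE)
  expect_error(simulation_design("not_a_scenario"), class = "invalid_input")
})

test_that("noise realizations differ across seeds but reproduce per seed", {
  a <- simulate_melt_curve(seed = 1)
  b <- simulate_melt_curve(seed = 1)
  c3 <- simulate_melt_curve(seed = 2)
  expect_identical(a$ellipticity, b$ellipticity)
  expect_false(identical(a$ellipticity, c3$ellipticity))
})

test_that("dimer-regime family generator yields increasing aggregate fractions", {
  fam <- simulate_melt_family(noise_frac = 0.02, seed = 21)
  f <- fit_bimodal_melts(fam$curves)
  expect_false(is.unsorted(f$chiA$chiA))
  expect_equal(f$Tm1, fam$truth$Tm1, tolerance = 0.01)
})

test_that("generate() covers the remaining scenarios with file output", {
  for (sc in c("chem_denat", "arrhenius_series", "mm_titration",
               "ctotal_scan", "dosy_decay", "decay_series",
               "dimer_melt_family")) {
    dir <- tempfile(sc)
    g <- generate(simulation_design(sc, seed = 3L), dir = dir)
    expect_true(all(file.exists(g$files)))
    expect_identical(g$truth$scenario, sc)
    unlink(dir, recursive = TRUE)
  }
})

test_that("manifest and rate-table readers parse their dialects", {
  dir <- tempfile("io")
  dir.create(dir)
  g <- generate(simulation_design("ctotal_scan", seed = 2L), dir = dir)
  df <- read_data_csv(file.path(dir, "ctotal_scan.csv"),
                      expected = c("ctotal_uM", "rate_uM_per_s"))
  expect_equal(nrow(df), 7)
  expect_error(read_data_csv(file.path(dir, "ctotal_scan.csv"),
                             expected = "substrate_uM"),
               class = "io_error")
  writeLines(c("file: ctotal_scan.csv", "type: ctotal", "C_T_uM: 5",
               "label: WT"), file.path(dir, "manifest"))
  m <- read_manifest(file.path(dir, "manifest"))
  expect_equal(m$type, "ctotal")
  expect_equal(m$C_T_uM, 5)
  unlink(dir, recursive = TRUE)
})
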