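test_that("two-state melt fit recovers noiseless parameters", {
  temp <- seq(298.15, 363.15, by = 0.5)
  y <- lem_melt_signal(temp, Tm = 341.45, dH = 75,
                       bf = c(-20, -0.01), bu = c(-4, 0.01))
  f <- fit_two_state_melt(melt_curve(temp, y))
  expect_equal(f$Tm, 341.45, tolerance = 1e-4)
  expect_equal(f$dH_vH, 75, tolerance = 1e-4)
  # van't Hoff extrapolation vanishes exactly at the midpoint
  expect_identical(two_state_dG(f, f$Tm), 0)
})

test_that("melt fitting is invariant to the input temperature unit", {
  temp_C <- seq(25, 90, by = 0.5)
  y <- lem_melt_signal(celsius_to_kelvin(temp_C), 341.45, 75,
                       c(-20, -0.01), c(-4, 0.01))
  f_K <- fit_two_state_melt(melt_curve(celsius_to_kelvin(temp_C), y,
                                       unit = "K"))
  f_C <- fit_two_state_melt(melt_curve(temp_C, y, unit = "C"))
  expect_equal(f_K$Tm, f_C$Tm, tolerance = 1e-9)
})

test_that("degenerate melts are rejected", {
  temp <- seq(298, 363, by = 1)
  expect_error(fit_two_state_melt(melt_curve(temp, rep(-10, length(temp)))),
               class = "fit_failure")
  expect_error(fit_two_state_melt(melt_curve(temp, -10 + 0.01 * temp)),
               class = "fit_failure")
  expect_error(melt_curve(seq(298, 310, by = 1), rnorm(13)),
               class = "invalid_input")  # span too short
  expect_error(melt_curve(temp, c(NA, rnorm(length(temp) - 1))),
               class = "invalid_input")
})

test_that("bimodal model with chi_A = 0 reduces to the two-state fit", {
  temp <- seq(298.15, 363.15, by = 0.5)
  y <- lem_melt_signal(temp, 343.15, 75, c(-20, -0.01), c(-4, 0.01))
  cv <- melt_curve(temp, y, C_T = 5)
  f2 <- fit_two_state_melt(cv)
  fb <- fit_bimodal_melts(list(cv), chiA_fixed = 0)
  expect_equal(fb$Tm2, f2$Tm, tolerance = 1e-6)
  expect_equal(fb$dH2, f2$dH_vH, tolerance = 1e-5)
})

test_that("global bimodal fit recovers a noiseless concentration family", {
  fam <- simulate_melt_family(noise_frac = 0)
  f <- fit_bimodal_melts(fam$curves)
  expect_equal(f$Tm1, fam$truth$Tm1, tolerance = 1e-4)
  expect_equal(f$Tm2, fam$truth$Tm2, tolerance = 1e-4)
  expect_equal(f$chiA$chiA, fam$truth$chiA, tolerance = 1e-3)
  expect_false(is.unsorted(f$chiA$chiA))
  expect_warning(fit_bimodal_melts(fam$curves[[1]]), "single curve")
})

test_that("chemical denaturation fit recovers the LEM parameters", {
  x <- seq(0, 7, by = 0.1)
  d <- simulate_chem_denat(dG0 = 9.5, m_value = 3, noise_frac = 0)
  f <- fit_chemical_denaturation(d$denaturant_M, d$ellipticity)
  expect_equal(f$dG0, 9.5, tolerance = 1e-4)
  expect_equal(f$m_value, 3, tolerance = 1e-4)
  expect_equal(f$Cm, f$dG0 / f$m_value, tolerance = 1e-6)
  # sign-agnostic: inverted ellipticity direction gives the same energies
  f_inv <- fit_chemical_denaturation(d$denaturant_M, -d$ellipticity)
  expect_equal(f_inv$dG0, f$dG0, tolerance = 1e-6)
  expect_error(fit_chemical_denaturation(x, rep(1, length(x))),
               class = "fit_failure")
  expect_error(fit_chemical_denaturation(x[1:10], rnorm(10)),
               class = "invalid_input")
})

test_that("Tm-shift destabilization energy is linear and sign-correct", {
  expect_identical(ddg_from_tm_shift(75, 341.45, 341.45), 0)
  expect_equal(ddg_from_tm_shift(75, 341.45, 341.45 - 4.553),
               75 * 4.553 / 341.45, tolerance = 1e-12)
  expect_equal(ddg_from_tm_shift(75, 341.45, 341.45 - 4.553), 1.0001,
               tolerance = 1e-4)
  # stabilizing shift comes out negative
  expect_equal(ddg_from_tm_shift(75, 341.45, 351.45), -2.1965,
               tolerance = 1e-4)
  # linear in the shift; antisymmetric up to the reference normalization
  d1 <- ddg_from_tm_shift(75, 341.45, 341.45 - 2)
  d2 <- ddg_from_tm_shift(75, 341.45, 341.45 - 4)
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  swap <- ddg_from_tm_shift(75, 339.45, 341.45)
  expect_equal(swap, -d1 * 341.45 / 339.45, tolerance = 1e-12)
  expect_error(ddg_from_tm_shift(75, -1, 300), class = "invalid_parameter")
})

test_that("phase diagram fits the exponential monomer line", {
  C_T <- c(0.5, 1, 2.5, 5, 10, 25)
  chiA <- 1 - exp(-C_T / 5)
  f <- phase_diagram(C_T, chiA)
  expect_equal(f$C_star, 5, tolerance = 1e-4)
  # the monomer line lies below the diagonal whenever chiA > 0
  expect_true(all(f$table$M < f$table$diagonal))
  expect_equal(f$table$M, (1 - chiA) * C_T)
  # aggregation-free limit: diagonal, unbounded scale constant
  f0 <- phase_diagram(C_T, rep(0, 6))
  expect_identical(f0$C_star, Inf)
  expect_true(any(grepl("diagonal", f0$flags)))
  expect_equal(f0$table$M, C_T)
  expect_error(phase_diagram(C_T, chiA * 2), class = "invalid_input")
  expect_error(phase_diagram(C_T[1:2], chiA[1:2]), class = "invalid_input")
})
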