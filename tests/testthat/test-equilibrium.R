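test_that("monomer-dimer partition matches the bisection oracle", {
  # frozen spot checks computed with bisect_partition
  st <- monomer_dimer_partition(equilibrium_spec(C_T = 1, K_D = 0.5))
  expect_equal(st$M, 0.390388203202208, tolerance = 1e-9)
  expect_equal(st$D, 0.304805898398896, tolerance = 1e-9)
  expect_equal(st$fraction_dimer, 0.609611796797792, tolerance = 1e-9)

  # randomized oracle equivalence over wide parameter ranges
  set.seed(42)
  for (i in 1:50) {
    C_T <- 10^runif(1, -3, 3); K_D <- 10^runif(1, -3, 3)
    M_oracle <- bisect_partition(C_T, K_D)
    st <- monomer_dimer_partition(equilibrium_spec(C_T, K_D))
    expect_equal(st$M, M_oracle, tolerance = 1e-9)
    expect_equal(st$M + 2 * st$D, C_T, tolerance = 1e-9)
  }
})

test_that("partition limits behave: empty system and strong-dimer regime", {
  st0 <- monomer_dimer_partition(equilibrium_spec(0, 0.5))
  expect_identical(st0$M, 0)
  expect_identical(st0$D, 0)
  expect_identical(st0$fraction_dimer, 0)

  st_hi <- monomer_dimer_partition(equilibrium_spec(1e4 * 0.5, 0.5))
  expect_gt(st_hi$fraction_dimer, 0.98)
  expect_error(equilibrium_spec(1, K_D = -1), class = "invalid_parameter")
  expect_error(equilibrium_spec(1, K_D = 0), class = "invalid_parameter")
})

test_that("dimer fraction is monotone in C_T and K_D; dG_DM sign is sensible", {
  ct <- 10^seq(-2, 2, length.out = 25)
  fr_ct <- vapply(ct, function(x)
    monomer_dimer_partition(equilibrium_spec(x, 0.5))$fraction_dimer, 1)
  expect_false(is.unsorted(fr_ct))
  kd <- 10^seq(-2, 2, length.out = 25)
  fr_kd <- vapply(kd, function(x)
    monomer_dimer_partition(equilibrium_spec(1, x))$fraction_dimer, 1)
  expect_false(is.unsorted(rev(fr_kd)))
  # sub-molar K_D: dissociation is unfavourable, dG_DM > 0
  expect_gt(monomer_dimer_partition(equilibrium_spec(1, 0.5))$dG_DM, 0)
})

test_that("two-state folded population follows the Boltzmann expression", {
  expect_equal(folded_fraction(0, 310.15), 0.5)
  expect_gt(folded_fraction(9.5, 310.15), 0.99)
  # marginally stable variant: ~12.5% unfolded at 37 C
  expect_equal(1 - folded_fraction(1.2, 310.15), 0.1248585,
               tolerance = 1e-6)
  # symmetry and monotonicity
  dg <- seq(-5, 5, by = 0.5)
  expect_equal(folded_fraction(dg) + folded_fraction(-dg), rep(1, length(dg)))
  expect_false(is.unsorted(folded_fraction(dg)))
  expect_error(folded_fraction(1, temperature = -1),
               class = "invalid_parameter")
})

test_that("dimer-only activity model composes partition and saturation", {
  kin <- enzyme_kinetics(Km = 25.2, kcat = 0.10)
  expect_equal(dimer_activity_rate(equilibrium_spec(0, 0.5), kin, 250), 0)
  # half-saturation identity at S = Km
  st <- monomer_dimer_partition(equilibrium_spec(10, 0.5))
  expect_equal(dimer_activity_rate(equilibrium_spec(10, 0.5), kin, 25.2),
               0.10 * 2 * st$D / 2)
  # frozen value from the bisection + saturation composition:
  # M = bisect(10, 0.5) = 1.461073..., v = 0.1 * (10 - M) * 250/275.2
  M <- bisect_partition(10, 0.5)
  expect_equal(dimer_activity_rate(equilibrium_spec(10, 0.5), kin, 250),
               0.10 * (10 - M) * 250 / 275.2, tolerance = 1e-9)
  expect_equal(dimer_activity_rate(equilibrium_spec(10, 0.5), kin, 250),
               0.775702, tolerance = 1e-5)
  # monotone in C_T, saturating in S
  v_ct <- dimer_activity_rate(equilibrium_spec(c(0.1, 0.5, 1, 5, 10), 0.5),
                              kin, 250)
  expect_false(is.unsorted(v_ct))
  v_s <- vapply(c(1, 10, 100, 1000, 1e4),
                function(S) dimer_activity_rate(equilibrium_spec(10, 0.5),
                                                kin, S), 1)
  expect_false(is.unsorted(v_s))
  expect_lt(max(v_s), 0.10 * (10 - M) * 1.0001)
  expect_error(dimer_activity_rate(equilibrium_spec(10, 0.5), kin, -1),
               class = "invalid_parameter")
})

test_that("Michaelis-Menten fit recovers noiseless parameters exactly", {
  S <- c(5, 10, 25, 50, 100, 250, 500)
  v <- 0.4 * S / (25.2 + S)
  f <- fit_michaelis_menten(S, v, enzyme_C_T = 5, K_D = 0.5)
  expect_equal(f$Km, 25.2, tolerance = 1e-6)
  expect_equal(f$Vmax, 0.4, tolerance = 1e-6)
  # at 5 uM enzyme with K_D = 0.5, active sites = 2 D = 4 uM exactly
  expect_equal(f$kcat, 0.1, tolerance = 1e-6)
  expect_error(fit_michaelis_menten(S, rep(0.2, length(S))),
               class = "fit_failure")
  expect_error(fit_michaelis_menten(c(1, 2, 3), c(0.1, 0.2, 0.3)),
               class = "fit_failure")
})

test_that("K_D fit recovers a noiseless activity-vs-concentration scan", {
  kin <- enzyme_kinetics(25.2, 0.10)
  C_T <- c(0.1, 0.25, 0.5, 1, 2.5, 5, 10)
  v <- dimer_activity_rate(equilibrium_spec(C_T, 0.5), kin, 2000)
  f <- fit_activity_vs_concentration(C_T, v, 2000, kin)
  expect_equal(f$K_D, 0.5, tolerance = 1e-4)
  expect_length(f$flags, 0)
  # saturated design: every C_T far above K_D -> unidentifiability flag
  C_hi <- c(50, 100, 200, 400, 800) * 0.5
  v_hi <- dimer_activity_rate(equilibrium_spec(C_hi, 0.5), kin, 2000)
  f_hi <- fit_activity_vs_concentration(C_hi, v_hi, 2000, kin)
  expect_true(any(grepl("saturated", f_hi$flags)))
})

test_that("scheme timecourse conserves mass and obeys its limits", {
  spec <- equilibrium_spec(10, 0.5)
  t <- seq(0, 2e4, length.out = 21)
  # no aggregation: state frozen
  tr0 <- simulate_scheme1_timecourse(spec, 0, t)
  expect_equal(unique(round(tr0$Ag, 12)), 0)
  expect_equal(tr0$M, rep(tr0$M[1], nrow(tr0)))
  # monomeric limit: closed-form exponential decay
  k <- 1e-3
  spec_m <- equilibrium_spec(0.001, 1000)
  tr_m <- simulate_scheme1_timecourse(spec_m, k, seq(0, 4000, by = 200))
  expect_equal(tr_m$M + 2 * tr_m$D, 0.001 * exp(-k * tr_m$time),
               tolerance = 1e-4)
  # dimer regime: mass conserved, Ag non-decreasing, decay slower than
  # the pure-monomer exponential
  tr_d <- simulate_scheme1_timecourse(spec, k, t)
  expect_equal(tr_d$M + 2 * tr_d$D + tr_d$Ag, rep(10, nrow(tr_d)),
               tolerance = 1e-6)
  expect_false(is.unsorted(tr_d$Ag))
  soluble <- tr_d$M + 2 * tr_d$D
  expect_true(all(soluble[-1] > 10 * exp(-k * tr_d$time[-1])))
  expect_error(simulate_scheme1_timecourse(spec, -1, t),
               class = "invalid_parameter")
})
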