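test_that("mechanism classification follows the documented rule", {
  expect_identical(classify_mechanism(1.0, 1.0, 9.5)$group, "WT-like")
  expect_identical(classify_mechanism(0.3, 1.2, 9.0)$group, "Gr1")
  expect_identical(classify_mechanism(0.95, 8, 8.5)$group, "Gr2")
  # severe loss of intrinsic stability overrides everything else
  expect_identical(classify_mechanism(0.9, 1.0, 1.2)$group,
                   "unfolding-destabilized")
  # both mechanisms at once: indeterminate, with both flags
  both <- classify_mechanism(0.3, 8, 9.0)
  expect_identical(both$group, "indeterminate")
  expect_length(both$flags, 2)
  # missing inputs: indeterminate with a diagnostic
  miss <- classify_mechanism(NA_real_, 1.0)
  expect_identical(miss$group, "indeterminate")
  expect_match(miss$flags, "missing")
  # pure function: identical inputs, identical outputs
  expect_identical(classify_mechanism(0.5, 3, 8),
                   classify_mechanism(0.5, 3, 8))
  # thresholds are configurable
  expect_identical(
    classify_mechanism(0.3, 1.2, 9, thresholds = list(dimer_cut = 0.2))$group,
    "WT-like")
  expect_error(classify_mechanism(-0.1, 1), class = "invalid_input")
})

test_that("landscape assembly produces WT-referenced energies", {
  wt <- wt_defaults()
  variants <- list(
    WT = list(K_D = wt$K_D, k_Ag = wt$k_Ag, dG_MU = wt$dG0, activity = 1.0),
    interface = list(K_D = wt$K_D * 20, k_Ag = wt$k_Ag, dG_MU = 8.5,
                     activity = 0.3),
    kinetic = list(K_D = wt$K_D, k_Ag = wt$k_Ag * 10, dG_MU = 8.0,
                   activity = 0.8),
    fragile = list(K_D = wt$K_D, k_Ag = wt$k_Ag, dG_MU = 1.2,
                   activity = 0.5))
  ls <- assemble_landscape(variants)
  wt_row <- ls[ls$label == "WT", ]
  expect_equal(wt_row$rel_activity, 1)
  expect_equal(wt_row$rel_dimer_fraction, 1)
  expect_equal(wt_row$rel_kAg, 1)
  expect_identical(wt_row$group, "WT-like")
  # weaker dimer: lower association stability and Gr1 call
  iface <- ls[ls$label == "interface", ]
  expect_lt(iface$dG_DM, wt_row$dG_DM)
  expect_identical(iface$group, "Gr1")
  # faster aggregation: lower Eyring barrier and Gr2 call
  kin <- ls[ls$label == "kinetic", ]
  expect_lt(kin$barrier_dG, wt_row$barrier_dG)
  expect_identical(kin$group, "Gr2")
  expect_identical(ls[ls$label == "fragile", ]$group,
                   "unfolding-destabilized")
  expect_error(assemble_landscape(variants[-1]), class = "missing_reference")
})

test_that("landscape serialization round-trips", {
  wt <- wt_defaults()
  variants <- list(
    WT = list(K_D = wt$K_D, k_Ag = wt$k_Ag, dG_MU = wt$dG0, activity = 1.0),
    mutA = list(K_D = 10, k_Ag = wt$k_Ag * 3, dG_MU = 7.5, activity = 0.2))
  ls <- assemble_landscape(variants)
  jf <- tempfile(fileext = ".json"); cf <- tempfile(fileext = ".csv")
  write_landscape(ls, jf, cf)
  back <- read_landscape(jf)
  expect_equal(as.data.frame(back), as.data.frame(ls), tolerance = 1e-12)
  expect_equal(attr(back, "thresholds"), attr(ls, "thresholds"))
  csv <- read.csv(cf)
  expect_equal(nrow(csv), 2)
  unlink(c(jf, cf))
})

test_that("synthetic mutant panel is classified end to end", {
  wt <- wt_defaults()
  panel <- mutant_panel(list(
    Gr1like = list(kd_mult = 20, kag_mult = 1, dTm = 3),
    Gr2like = list(kd_mult = 1, kag_mult = 10, dTm = 5)),
    seed = 5L)
  fits <- lapply(panel, function(v) {
    kd <- fit_activity_vs_concentration(
      v$datasets$ctotal_scan$ctotal_uM, v$datasets$ctotal_scan$rate_uM_per_s,
      S_fixed = 2000, kinetics = enzyme_kinetics(wt$Km, wt$kcat))
    dec <- fit_decay(v$datasets$decay$time_s, v$datasets$decay$ellipticity)
    melt <- fit_two_state_melt(v$datasets$melt)
    ddg <- ddg_from_tm_shift(wt$dH, wt$Tm, melt$Tm)
    list(K_D = kd$K_D, k_Ag = dec$k_Ag, dG_MU = wt$dG0 - ddg)
  })
  ls <- assemble_landscape(fits)
  expect_identical(ls[ls$label == "WT", ]$group, "WT-like")
  expect_identical(ls[ls$label == "Gr1like", ]$group, "Gr1")
  expect_identical(ls[ls$label == "Gr2like", ]$group, "Gr2")
  expect_error(mutant_panel(list(bad = list(kd_mult = -1, kag_mult = 1,
                                            dTm = 0))),
               class = "invalid_parameter")
})
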