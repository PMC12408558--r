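test_that("AUC0-336 reduces to the one-compartment closed form", {
  # near-bolus dose into the dissolved-irinotecan central compartment with
  # peripheral exchange shut off: D/CL (1 - exp(-336 CL/V))
  p <- fixed_effects(Q2 = 0, Q3 = 0, fnp_iri = 1e-9)
  reg <- dose_regimen(80, 0, infusion_duration = 1e-3)
  prof <- simulate_profile(p, reg, c(1e-3, 1, 336))
  D <- 128; CL <- p[["CL1"]]; V <- p[["V3"]]
  expect_equal(auc_0_336(prof, "s_iri"),
               1000 * D / CL * (1 - exp(-336 * CL / V)), tolerance = 1e-4)
  # zero profile integrates to zero
  z <- simulate_profile(p, dose_regimen(0, 0), c(1, 336))
  expect_equal(auc_0_336(z, "s_iri"), 0)
  expect_error(auc_0_336(prof, "s_iri", to = 400), "before")
})

test_that("cmax uses the grid and doubles with the dose", {
  p <- typical_params()
  reg <- regimen_5080()
  prof <- simulate_profile(p, reg, exposure_grid(reg))
  reg2 <- dose_regimen(160, 100)
  prof2 <- simulate_profile(p, reg2, exposure_grid(reg2))
  for (f in c("np_iri", "s_iri", "np_sn38", "s_sn38"))
    expect_equal(cmax(prof2, f), 2 * cmax(prof, f), tolerance = 1e-10)
  # monotone decay after a near-bolus peaks at the first grid point
  pb <- fixed_effects(Q2 = 0, Q3 = 0, fnp_iri = 1e-9)
  regb <- dose_regimen(80, 0, infusion_duration = 1e-3)
  profb <- simulate_profile(pb, regb, c(1e-3, seq(0.5, 336, by = 0.5)))
  expect_equal(cmax(profb, "s_iri"), unname(profb$conc["s_iri", 1]))
})

test_that("np_share_auc behaves as a fraction", {
  expect_equal(np_share_auc(3, 3), 0.5)
  expect_equal(np_share_auc(0, 5), 0)
  expect_error(np_share_auc(0, 0), "undefined")
  expect_error(np_share_auc(-1, 2), "non-negative")
})

test_that("exposure summary matches the reported normalization conventions", {
  ex <- exposure_summary(typical_params(), regimen_5080())
  m <- ex$metrics
  # irinotecan forms normalised by the irinotecan dose, SN-38 forms by the
  # SN-38 dose
  expect_equal(m$auc_per_mgm2[m$form == "s_iri"],
               m$auc_0_336[m$form == "s_iri"] / 80)
  expect_equal(m$cmax_per_mgm2[m$form == "np_sn38"],
               m$cmax[m$form == "np_sn38"] / 50)
  expect_equal(ex$ratios$np_share_auc[ex$ratios$analyte == "sn38"],
               0.804, tolerance = 5e-3)
})

test_that("AUC0-336 captures at least 99% of total exposure", {
  p <- typical_params()
  reg <- regimen_5080()
  prof <- simulate_profile(p, reg, exposure_grid(reg))
  for (f in c("np_iri", "s_iri", "np_sn38", "s_sn38"))
    expect_gt(auc_0_336(prof, f) / auc_inf(prof, f), 0.99)
})

test_that("exposure table is linear across dose levels", {
  tab <- exposure_table(typical_params(),
                        default_dose_levels()[c(1, 5, 10), ])
  vals <- as.matrix(tab[, -(1:2)])
  expect_equal(vals[3, ], 2 * vals[2, ], tolerance = 1e-10)
  expect_equal(vals[1, ], 0.2 * vals[2, ], tolerance = 1e-10)
  # NP share of exposure is invariant across dose levels
  share <- tab$auc_np_sn38 / (tab$auc_np_sn38 + tab$auc_s_sn38)
  expect_equal(share, rep(share[1], 3), tolerance = 1e-10)
  expect_error(exposure_table(typical_params(),
                              data.frame(dose_sn38 = -1, dose_iri = 2)),
               "malformed")
})
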