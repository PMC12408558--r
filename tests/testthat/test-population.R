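test_that("individual sampling realises log-normal variability", {
  theta <- typical_params()
  # all omegas zero reproduces the typical subject exactly
  v0 <- variability_spec(omega = c(CL1 = 0))
  ind <- sample_individual(theta, v0, n = 2, seed = 1)
  expect_equal(unclass(ind$params[[1]]), unclass(theta))
  expect_equal(max(abs(ind$eta)), 0)

  # Monte-Carlo check of the sampler: sd of log(CL1) and median
  v <- variability_spec()
  ind <- sample_individual(theta, v, n = 10000, seed = 42)
  cl1 <- vapply(ind$params, function(p) p[["CL1"]], 0)
  expect_equal(sd(log(cl1)), 0.347, tolerance = 0.03)
  expect_equal(median(cl1), 29.7, tolerance = 0.02)
  # parameters without a BSV entry never vary
  expect_equal(unique(vapply(ind$params, function(p) p[["Q1"]], 0)), 6.45)
  expect_error(sample_individual(theta, structure(list(
    omega = c(CL1 = -1), sigma = v$sigma), class = "variability_spec")),
    "negative")
})

test_that("proportional residual error has the specified CV", {
  v <- variability_spec()
  expect_equal(apply_residual_error(c(5, 50), "iri",
                                    variability_spec(sigma = c(iri = 0,
                                                               sn38 = 0.1,
                                                               sn38g = 0.1))),
               c(5, 50), ignore_attr = TRUE)
  obs <- apply_residual_error(rep(100, 10000), "sn38", v, seed = 7)
  expect_equal(sd(obs / 100 - 1), 0.416, tolerance = 0.03)
  expect_equal(apply_residual_error(0, "sn38g", v, seed = 1), 0,
               ignore_attr = TRUE)
  expect_true(all(obs >= 0))
  expect_error(apply_residual_error(10, "unknown", v))
})

test_that("trial simulation produces the full event-record layout", {
  ds <- simulate_trial(default_design(), typical_params(),
                       variability_spec(), seed = 11)
  expect_s3_class(ds, "trial_dataset")
  expect_equal(length(unique(ds$ID)), 21)
  expect_equal(sum(ds$EVID == 0), 21 * 17 * 3)
  expect_equal(sum(ds$EVID == 1), 21 * 4)
  # dose split carries the NP/S ratio: CMT 1 holds 15% of the irinotecan dose
  d1 <- ds[ds$ID == 1 & ds$EVID == 1, ]
  expect_equal(d1$AMT[d1$CMT == 1] / (d1$AMT[d1$CMT == 1] + d1$AMT[d1$CMT == 3]),
               0.15)
  expect_equal(d1$AMT / d1$RATE, rep(1.5, 4))
  # pre-dose records are non-evaluable zeros
  pre <- ds[ds$EVID == 0 & ds$TIME == 0, ]
  expect_true(all(pre$MDV == 1) && all(pre$DV == 0))
  # same seed, same dataset; different seed differs
  expect_identical(ds, simulate_trial(default_design(), typical_params(),
                                      variability_spec(), seed = 11))
  ds2 <- simulate_trial(default_design(), typical_params(),
                        variability_spec(), seed = 12)
  expect_false(identical(ds$DV, ds2$DV))
})

test_that("with zero variability the trial reproduces typical totals", {
  v0 <- variability_spec(omega = c(CL1 = 0),
                         sigma = c(iri = 0, sn38 = 0, sn38g = 0))
  des <- mini_design(n = c(1, 1))
  ds <- simulate_trial(des, typical_params(), v0, seed = 5)
  reg <- dose_regimen(48, 30, bsa = des$bsa,
                      infusion_duration = des$infusion_duration)
  prof <- simulate_profile(typical_params(), reg, des$times[-1])
  tot <- observe_totals(prof)
  obs <- ds[ds$ID == 1 & ds$EVID == 0 & ds$MDV == 0, ]
  expect_equal(obs$DV[obs$DVID == 1], tot$iri, tolerance = 1e-10)
  expect_equal(obs$DV[obs$DVID == 2], tot$sn38, tolerance = 1e-10)
  expect_equal(obs$DV[obs$DVID == 3], tot$sn38g, tolerance = 1e-10)
})
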