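test_that("rate matrix encodes the release/conversion/elimination topology", {
  p <- typical_params()
  M <- rate_matrix(p)
  # hand-computed from the parameter table: -(K13 + Q1/V1)
  expect_equal(M[1, 1], -(64.4 + 6.45 / 54.4), tolerance = 1e-12)
  expect_equal(M[3, 1], 64.4)            # all released NP-iri mass enters S-iri
  expect_equal(M[8, 6], 0.712)
  # molar conversion flux into S-SN-38
  expect_equal(M[8, 3], 0.03 * (392.40 / 586.68) * 29.7 / 68.6,
               tolerance = 1e-12)
  # glucuronidation feeds SN-38G 1:1 in mass
  expect_equal(M[10, 8], 167 / 40.3, tolerance = 1e-12)
  # intercompartmental terms symmetric in concentration
  expect_equal(M[1, 2] * p[["V2"]], M[2, 1] * p[["V1"]], tolerance = 1e-12)

  # mass-balance audit: no column creates mass; mass leaves the system only
  # through S-irinotecan clearance (col 3, net of the 3% molar conversion)
  # and SN-38G clearance (col 10); the S-SN-38 column balances exactly
  # because its entire elimination flux enters SN-38G
  cs <- colSums(M)
  expect_true(all(cs <= 1e-12))
  expect_lt(cs[3], -1e-3)
  expect_lt(cs[10], -1e-3)
  expect_equal(cs[[8]], 0, tolerance = 1e-12)
  expect_equal(unname(cs[c(1, 2, 4:7, 9, 11)]), rep(0, 8), tolerance = 1e-12)
})

test_that("parameter validation rejects bad values by name", {
  expect_error(fixed_effects(V8 = -1), "V8")
  expect_error(fixed_effects(CL1 = 0), "CL1")
  expect_error(fixed_effects(Q1 = -0.1), "Q1")
  expect_error(fixed_effects(fnp_iri = 1.2), "fnp_iri")
  # zero rate constants and intercompartmental clearances are legal
  p0 <- fixed_effects(Q1 = 0, K13 = 0)
  M <- rate_matrix(p0)
  expect_equal(unname(M[-1, 1]), rep(0, 10))   # NP-iri central is isolated
  expect_equal(M[1, 1], 0)
})

test_that("simulated profiles solve the system exactly", {
  p <- typical_params()
  reg <- regimen_5080()
  times <- c(seq(0.25, 12, by = 0.25), seq(13, 336, by = 1))

  # zero doses give an identically zero profile
  z <- simulate_profile(p, dose_regimen(0, 0), times)
  expect_equal(max(abs(z$conc)), 0)

  prof <- simulate_profile(p, reg, sort(unique(c(times, 1.5))))
  expect_true(all(prof$conc >= 0))

  # NP-iri at end of infusion: fast release (K13 = 64.4/h) puts the central
  # compartment at its infusion steady state R/(K13 V1), up to the small
  # Q1 correction
  c_np_iri <- unname(prof$conc["np_iri", prof$time == 1.5])
  expect_equal(c_np_iri, 1000 * (0.15 * 128 / 1.5) / (64.4 * 54.4),
               tolerance = 5e-3)

  # NP-SN-38 at end of infusion: independent bi-exponential closed form
  cc <- 1000 * two_cpt_infusion_conc(1.5, 0.98 * 80 / 1.5, 54.4, 0.712,
                                     6.45 / 54.4, 6.45 / 287)
  expect_equal(unname(prof$conc["np_sn38", prof$time == 1.5]), cc,
               tolerance = 1e-8)

  # totals are the sums of the form-specific curves
  tot <- observe_totals(prof)
  expect_equal(tot$iri, prof$conc["np_iri", ] + prof$conc["s_iri", ])
  expect_equal(tot$sn38, prof$conc["np_sn38", ] + prof$conc["s_sn38", ])
  expect_equal(tot$sn38g, prof$conc["sn38g", ])
  expect_true(all(tot$iri >= prof$conc["np_iri", ]))

  expect_error(simulate_profile(p, reg, c(2, 1)), "sorted")
  expect_error(simulate_profile(p, reg, c(-1, 2)), "negative")
})

test_that("dose scaling is exactly proportional", {
  p <- typical_params()
  times <- c(0.5, 1.5, 4, 24, 168, 336)
  a <- simulate_profile(p, dose_regimen(80, 50), times)
  b <- simulate_profile(p, dose_regimen(80 * 2.5, 50 * 2.5), times)
  expect_equal(b$conc, 2.5 * a$conc, tolerance = 1e-12)
})

test_that("mass balance holds to 1e-6 at all times", {
  p <- typical_params()
  reg <- regimen_5080()
  sys <- npsplit:::.lin_system(p, reg)
  tt <- c(0.5, 1, 1.5, 2, 6, 24, 96, 336)
  A <- npsplit:::.solve_amounts(sys, tt)
  I <- npsplit:::.integral_amounts(sys, tt)
  dosed_iri <- 128 * pmin(tt / 1.5, 1)
  eliminated <- (p[["CL1"]] / p[["V3"]]) * I[3, ]
  in_system <- colSums(A[1:5, ])
  expect_equal(in_system + eliminated, dosed_iri, tolerance = 1e-6)
})

test_that("matrix-exponential solution matches an implicit stiff ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- typical_params()
  reg <- regimen_5080()
  M <- rate_matrix(p)
  u <- npsplit:::infusion_rates(p, reg)
  rhs <- function(t, A, parms) list(M %*% A + if (t <= 1.5) u else 0 * u)
  tt <- c(0, 0.5, 1, 1.5, 2, 4, 8, 12, 24, 48, 96, 168, 336)
  num <- deSolve::lsoda(numeric(11), tt, rhs, NULL, rtol = 1e-11,
                        atol = 1e-12)[-1, -1]
  prof <- simulate_profile(p, reg, tt[-1])
  rel <- abs(t(num) - prof$amounts) / (abs(t(num)) + 1e-9 * max(num))
  expect_lt(max(rel), 1e-6)
})

test_that("degenerate parameter sets fall back to a stepwise exponential", {
  skip_if_not_installed("deSolve")
  # Q1 = K13 = 0 gives repeated zero eigenvalues (isolated NP-iri block)
  p <- fixed_effects(Q1 = 0, K13 = 0)
  reg <- dose_regimen(80, 50)
  tt <- c(0.5, 1.5, 4, 24, 96)
  prof <- simulate_profile(p, reg, tt)
  M <- rate_matrix(p)
  u <- npsplit:::infusion_rates(p, reg)
  rhs <- function(t, A, parms) list(M %*% A + if (t <= 1.5) u else 0 * u)
  num <- deSolve::lsoda(numeric(11), c(0, tt), rhs, NULL, rtol = 1e-11,
                        atol = 1e-12)[-1, -1]
  expect_equal(prof$amounts, t(num), tolerance = 1e-6,
               ignore_attr = TRUE)
  # NP-iri mass is trapped: amount equals the dosed NP fraction
  expect_equal(prof$amounts[1, 5], 0.15 * 128, tolerance = 1e-8)
})

test_that("AUC0-inf is infusion-duration invariant, Cmax non-increasing", {
  p <- typical_params()
  durs <- c(0.5, 1.5, 3, 6)
  aucs <- cmaxs <- numeric(length(durs))
  for (i in seq_along(durs)) {
    reg <- dose_regimen(80, 50, infusion_duration = durs[i])
    prof <- simulate_profile(p, reg, exposure_grid(reg))
    aucs[i] <- auc_inf(prof, "s_sn38")
    cmaxs[i] <- cmax(prof, "np_sn38")
  }
  expect_equal(aucs, rep(aucs[1], 4), tolerance = 1e-10)
  expect_true(all(diff(cmaxs) < 0))
})
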