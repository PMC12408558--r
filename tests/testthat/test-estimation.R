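test_that("with no random effects the OFV is the weighted LS deviance", {
  v0 <- variability_spec(omega = c(CL1 = 0),
                         sigma = c(iri = 0.2, sn38 = 0.3, sn38g = 0.25))
  des <- mini_design(c(1, 1))
  ds <- simulate_trial(des, typical_params(), v0, seed = 8)
  ofv <- np_neg2ll(ds, typical_params(), v0)
  # independent assembly from profile predictions
  obs <- ds[ds$EVID == 0 & ds$MDV == 0 & ds$DV > 0, ]
  sig <- c(0.2, 0.3, 0.25)
  expected <- 0
  for (id in unique(obs$ID)) {
    o <- obs[obs$ID == id, ]
    reg <- dose_regimen(c(48, 80)[id], c(30, 50)[id])
    tot <- observe_totals(simulate_profile(typical_params(), reg,
                                           sort(unique(o$TIME))))
    f <- as.matrix(tot[-1])[cbind(match(o$TIME, tot$time), o$DVID)]
    expected <- expected - 2 * sum(dnorm(o$DV, f, sig[o$DVID] * f, log = TRUE))
  }
  expect_equal(ofv, expected, tolerance = 1e-8)
})

test_that("Laplace OFV matches 64-point Gauss-Hermite quadrature", {
  des <- trial_design(cohorts = data.frame(n = 1, dose_iri = 80,
                                           dose_sn38 = 50),
                      times = c(0, 1, 4, 12, 48, 169.5))
  quad_vs_laplace <- function(om) {
    v <- variability_spec(omega = c(CL2 = om),
                          sigma = c(iri = 0.2, sn38 = 0.2, sn38g = 0.2))
    ds <- simulate_trial(des, typical_params(), v, seed = 17)
    lap <- np_neg2ll(ds, typical_params(), v)
    obs <- ds[ds$EVID == 0 & ds$MDV == 0 & ds$DV > 0, ]
    loglik_eta <- function(eta) {
      p <- unclass(typical_params()); p["CL2"] <- p["CL2"] * exp(eta)
      tot <- observe_totals(simulate_profile(
        structure(p, class = "fixed_effects"), dose_regimen(80, 50),
        sort(unique(obs$TIME))))
      f <- as.matrix(tot[-1])[cbind(match(obs$TIME, tot$time), obs$DVID)]
      sum(dnorm(obs$DV, f, 0.2 * f, log = TRUE))
    }
    gh <- gauss_hermite(64)
    vals <- vapply(sqrt(2) * om * gh$nodes, loglik_eta, 0)
    lap - (-2 * log(sum(gh$weights * exp(vals)) / sqrt(pi)))
  }
  # near-Gaussian regime: Laplace is essentially exact
  expect_lt(abs(quad_vs_laplace(0.05)), 1e-4)
  # larger variability: the second-order approximation degrades gracefully
  expect_lt(abs(quad_vs_laplace(0.3)), 0.05)
})

test_that("near-noiseless data recover a single free clearance within 1%", {
  v_small <- variability_spec(omega = c(CL2 = 1e-3),
                              sigma = c(iri = 0.01, sn38 = 0.01,
                                        sn38g = 0.01))
  ds <- simulate_trial(mini_design(c(2, 1)), typical_params(), v_small,
                       seed = 19)
  start <- typical_params(); start["CL2"] <- 220
  fit <- np_fit(ds, start = start, variability = v_small, free = "CL2",
                eta_on = "CL2",
                control = list(diagnostics = FALSE, inner_starts = 1))
  expect_equal(unname(coef(fit)[["CL2"]]), 167, tolerance = 0.01)
})

test_that("a fully fixed problem only evaluates and never moves theta", {
  v <- variability_spec(omega = c(K68 = 0.2),
                        sigma = c(iri = 0.2, sn38 = 0.2, sn38g = 0.2))
  ds <- simulate_trial(mini_design(c(1, 1)), typical_params(), v, seed = 4)
  fit <- np_fit(ds, variability = v, free = character(0), eta_on = "K68",
                control = list(diagnostics = FALSE, inner_starts = 1))
  expect_length(coef(fit), 0)
  expect_equal(unclass(fit$theta), unclass(typical_params()))
  expect_equal(fit$ofv, np_neg2ll(ds, typical_params(), v, eta_on = "K68",
                                  control = list(inner_starts = 1)),
               tolerance = 1e-6)
  # the fit is deterministic: same data, same result
  fit2 <- np_fit(ds, variability = v, free = character(0), eta_on = "K68",
                 control = list(diagnostics = FALSE, inner_starts = 1))
  expect_identical(fit$ofv, fit2$ofv)
})

test_that("freeing an extra parameter never worsens the optimal OFV", {
  v <- variability_spec(omega = c(K68 = 0.3, CL2 = 0.3),
                        sigma = c(iri = 0.2, sn38 = 0.2, sn38g = 0.2))
  ds <- simulate_trial(mini_design(c(2, 1)), typical_params(), v, seed = 23)
  ctl <- list(diagnostics = FALSE, inner_starts = 2)
  fit1 <- np_fit(ds, free = "CL2", variability = v,
                 eta_on = c("K68", "CL2"), control = ctl)
  fit2 <- np_fit(ds, free = c("CL2", "K68"), variability = v,
                 eta_on = c("K68", "CL2"), control = ctl)
  expect_lte(fit2$ofv, fit1$ofv + 0.5)
  lrt <- ofv_test(fit1, fit2)
  expect_equal(lrt$df, 1)
  expect_equal(lrt$critical, qchisq(0.95, 1))
  expect_equal(lrt$delta_ofv, fit1$ofv - fit2$ofv)
})

test_that("empirical Bayes estimates recover known individual effects", {
  v <- variability_spec(omega = c(CL2 = 0.3),
                        sigma = c(iri = 0.01, sn38 = 0.01, sn38g = 0.01))
  des <- mini_design(c(2, 2))
  ds <- simulate_trial(des, typical_params(), v, seed = 29)
  true_eta <- attr(ds, "eta")[, "CL2"]
  fit <- np_fit(ds, variability = v, free = character(0), eta_on = "CL2",
                control = list(diagnostics = FALSE, inner_starts = 2))
  for (i in 1:4) {
    eb <- empirical_bayes(fit, i)
    expect_lt(abs(eb$eta[["CL2"]] - true_eta[i]), 0.1)
    # form-specific curves add up to the individual totals
    expect_equal(eb$curves$total_sn38,
                 eb$curves$np_sn38 + eb$curves$s_sn38)
  }
  # zero omega pins every eta at zero
  v0 <- variability_spec(omega = c(CL1 = 0),
                         sigma = c(iri = 0.1, sn38 = 0.1, sn38g = 0.1))
  ds0 <- simulate_trial(mini_design(c(1, 1)), typical_params(), v0, seed = 2)
  fit0 <- np_fit(ds0, variability = v0, free = character(0),
                 control = list(diagnostics = FALSE))
  expect_equal(ncol(fit0$eta), 0)
  expect_equal(empirical_bayes(fit0, 1)$eta, numeric(0))
})

test_that("fit methods expose coefficients, likelihood, residuals, predictions", {
  v <- variability_spec(omega = c(K68 = 0.2, CL2 = 0.2),
                        sigma = c(iri = 0.15, sn38 = 0.2, sn38g = 0.2))
  ds <- simulate_trial(mini_design(c(1, 1)), typical_params(), v, seed = 41)
  fit <- np_fit(ds, free = "CL2", variability = v, eta_on = c("K68", "CL2"),
                control = list(diagnostics = TRUE, inner_starts = 1))
  expect_named(coef(fit), "CL2")
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), -fit$ofv / 2)
  expect_equal(attr(ll, "df"), 1)
  expect_true(is.finite(fit$grad_norm))
  expect_true(all(fit$shrinkage <= 1))
  r <- residuals(fit)
  expect_equal(length(r), fit$n_obs)
  expect_lt(abs(mean(r)), 1)
  f <- fitted(fit)
  expect_equal(residuals(fit, type = "response"),
               unlist(lapply(fit$subjects, `[[`, "dv"),
                      use.names = FALSE) - f)
  pr <- predict(fit, subjects = 1, times = c(1, 24, 336))
  expect_equal(pr$total_sn38, pr$np_sn38 + pr$s_sn38)
  expect_equal(nrow(pr), 3)
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]), fit$n_obs)
  s <- summary(fit)
  expect_s3_class(s, "summary.np_fit")
  expect_output(print(s), "OFV")
})
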