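# ---- between-subject variability and trial simulation ----------------------

# lean prediction path shared by trial simulation and estimation:
# dosing = list(amt = named amounts (mg) for compartments "1","3","6","8",
#               dur = infusion duration (h), t0 = start time (h))
.dosing_from_regimen <- function(params, regimen) {
  u <- infusion_rates(params, regimen)
  list(amt = u * regimen$infusion_duration, dur = regimen$infusion_duration,
       t0 = regimen$start_time)
}

.predict_conc <- function(params, dosing, times) {
  sys <- list(M = .rate_matrix_num(params), u = dosing$amt / dosing$dur,
              t0 = dosing$t0, dur = dosing$dur)
  .amounts_to_conc(.solve_amounts(sys, times), params)
}

# 3 x n matrix of total concentrations, rows iri / sn38 / sn38g
.predict_totals <- function(params, dosing, times) {
  C <- .predict_conc(params, dosing, times)
  rbind(iri = C["np_iri", ] + C["s_iri", ],
        sn38 = C["np_sn38", ] + C["s_sn38", ],
        sn38g = C["sn38g", ])
}

#' Sample individual parameter sets
#'
#' Draws per-subject log-normal random effects, `eta_p ~ N(0, omega_p^2)`
#' independently across parameters, and realizes individual parameters as
#' `theta_p * exp(eta_p)`. Parameters sharing a stored value (the NP
#' disposition parameters of both drugs, and the S-SN-38 / SN-38G
#' peripheral volume) automatically share one eta.
#'
#' @param theta typical values, a [fixed_effects()] object.
#' @param spec a [variability_spec()] object.
#' @param n number of subjects.
#' @param seed optional integer seed (RNG state is restored on exit).
#' @return An object of class `individual_parameters`: list with `eta`
#'   (n x 18 matrix, zero columns where omega = 0) and `params` (list of n
#'   realized [fixed_effects()] vectors).
#' @examples
#' ind <- sample_individual(fixed_effects(), variability_spec(), n = 3, seed = 1)
#' ind$params[[1]][["CL1"]]
#' @export
sample_individual <- function(theta, spec, n = 1, seed = NULL) {
  validate_fixed_effects(theta)
  stopifnot(inherits(spec, "variability_spec"))
  if (any(spec$omega < 0)) stop("negative omega")
  .with_seed(seed, {
    k <- length(.structural_names)
    eta <- matrix(stats::rnorm(n * k), n, k,
                  dimnames = list(NULL, .structural_names))
    eta <- sweep(eta, 2, spec$omega, `*`)
    params <- lapply(seq_len(n), function(i) {
      p <- unclass(theta)
      p[.structural_names] <- p[.structural_names] * exp(eta[i, ])
      structure(p, class = "fixed_effects")
    })
    structure(list(eta = eta, params = params),
              class = "individual_parameters")
  })
}

#' Apply proportional residual error
#'
#' `obs = true * (1 + eps)`, `eps ~ N(0, sigma_analyte^2)`. Draws that land
#' below zero are floored at 0 and counted in the `"floored"` attribute.
#'
#' @param true_conc non-negative true concentrations (ng/mL).
#' @param analyte `"iri"`, `"sn38"` or `"sn38g"`.
#' @param spec a [variability_spec()] object.
#' @param seed optional integer seed.
#' @return Observed concentrations, with attribute `floored` (count).
#' @export
apply_residual_error <- function(true_conc, analyte, spec, seed = NULL) {
  analyte <- match.arg(analyte, c("iri", "sn38", "sn38g"))
  stopifnot(inherits(spec, "variability_spec"))
  if (any(true_conc < 0)) stop("true_conc must be non-negative")
  .with_seed(seed, {
    eps <- stats::rnorm(length(true_conc), 0, spec$sigma[[analyte]])
    obs <- true_conc * (1 + eps)
    n_floor <- sum(obs < 0)
    obs[obs < 0] <- 0
    structure(obs, floored = n_floor)
  })
}

#' Simulate a full trial dataset
#'
#' Simulates every subject of a [trial_design()]: individual parameters
#' from the between-subject model, exact concentration profiles at the
#' sampling times, and per-analyte proportional residual error on the
#' observed totals. The output is a long-format dataset in the field's
#' event-record convention: four simultaneous infusion records per subject
#' (compartments 1, 3, 6, 8 carrying the NP/S dose split) and one
#' observation record per subject, time and analyte. The pre-dose sample is
#' kept as a non-evaluable record (`MDV = 1`, `DV = 0`).
#'
#' @param design a [trial_design()] object.
#' @param theta typical values, a [fixed_effects()] object.
#' @param spec a [variability_spec()] object.
#' @param seed optional integer seed; the same seed reproduces the dataset
#'   exactly.
#' @return A data frame of class `trial_dataset` with columns `ID`, `TIME`,
#'   `EVID`, `CMT`, `AMT` (mg), `RATE` (mg/h), `DV` (ng/mL), `DVID`
#'   (1 = total irinotecan, 2 = total SN-38, 3 = SN-38G), `MDV`, `COHORT`.
#'   The matrix of simulated random effects is attached as attribute
#'   `"eta"`.
#' @examples
#' ds <- simulate_trial(default_design(), fixed_effects(),
#'                      variability_spec(), seed = 42)
#' nrow(ds[ds$EVID == 0, ])    # 21 x 17 x 3 observation records
#' @export
simulate_trial <- function(design, theta, spec, seed = NULL) {
  stopifnot(inherits(design, "trial_design"))
  validate_fixed_effects(theta)
  stopifnot(inherits(spec, "variability_spec"))
  if (nrow(design$cohorts) == 0) stop("empty design")
  .with_seed(seed, {
    analytes <- c("iri", "sn38", "sn38g")
    rows <- list()
    etas <- list()
    id <- 0L
    for (ci in seq_len(nrow(design$cohorts))) {
      ch <- design$cohorts[ci, ]
      regimen <- dose_regimen(ch$dose_iri, ch$dose_sn38, bsa = design$bsa,
                              infusion_duration = design$infusion_duration)
      for (s in seq_len(ch$n)) {
        id <- id + 1L
        ind <- sample_individual(theta, spec, n = 1)
        etas[[id]] <- ind$eta[1, ]
        p_i <- ind$params[[1]]
        dosing <- .dosing_from_regimen(p_i, regimen)
        dose_cpt <- c(1L, 3L, 6L, 8L)
        amt <- dosing$amt[dose_cpt]
        dose_rows <- data.frame(
          ID = id, TIME = dosing$t0, EVID = 1L, CMT = dose_cpt, AMT = amt,
          RATE = amt / dosing$dur, DV = NA_real_, DVID = NA_integer_,
          MDV = 1L, COHORT = ch$cohort)
        post <- design$times[design$times > dosing$t0]
        totals <- .predict_totals(p_i, dosing, post)
        obs <- expand.grid(TIME = design$times, DVID = seq_along(analytes))
        obs <- obs[order(obs$TIME, obs$DVID), ]
        pre <- obs$TIME <= dosing$t0
        dv <- numeric(nrow(obs))
        for (a in seq_along(analytes)) {
          sel <- obs$DVID == a & !pre
          dv[sel] <- apply_residual_error(
            totals[a, match(obs$TIME[sel], post)], analytes[a], spec)
        }
        obs_rows <- data.frame(
          ID = id, TIME = obs$TIME, EVID = 0L, CMT = NA_integer_,
          AMT = NA_real_, RATE = NA_real_, DV = dv, DVID = obs$DVID,
          MDV = as.integer(pre), COHORT = ch$cohort)
        rows[[length(rows) + 1L]] <- dose_rows
        rows[[length(rows) + 1L]] <- obs_rows
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("trial_dataset", "data.frame")
    attr(out, "eta") <- do.call(rbind, etas)
    attr(out, "design") <- design
    out
  })
}
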