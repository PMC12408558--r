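# ---- exposure metrics -------------------------------------------------------

.check_form <- function(form) {
  form <- match.arg(form, .form_names)
  form
}

#' Area under the concentration curve over 0-336 h
#'
#' Computed exactly from the linear system (`AUC = M^-1 (A(T) - U(T))`
#' evaluated per compartment and scaled to concentration units), not by
#' quadrature on the grid, so the value carries no grid-resolution error.
#'
#' @param profile a [simulate_profile()] result whose grid extends to at
#'   least 336 h.
#' @param form one of `"np_iri"`, `"s_iri"`, `"np_sn38"`, `"s_sn38"`,
#'   `"sn38g"`.
#' @param to upper limit of integration (h); default 336.
#' @return AUC in ng·h/mL.
#' @examples
#' prof <- simulate_profile(fixed_effects(), dose_regimen(80, 50),
#'                          times = c(seq(0, 48, 0.5), seq(49, 336, 1)))
#' auc_0_336(prof, "np_sn38")
#' @export
auc_0_336 <- function(profile, form, to = 336) {
  stopifnot(inherits(profile, "concentration_profile"))
  form <- .check_form(form)
  if (max(profile$time) < to)
    stop(sprintf("profile ends at %g h, before the %g h integration limit",
                 max(profile$time), to))
  I <- .integral_amounts(profile$sys, to)
  cpt <- .form_central[[form]]
  V <- profile$params[[.form_volume[[form]]]]
  1000 * I[cpt, 1] / V
}

#' Area under the concentration curve extrapolated to infinity
#'
#' For the stable linear system `AUC0-inf = -M^-1 U_total` per compartment,
#' where `U_total` is the vector of total dosed amounts.
#'
#' @inheritParams auc_0_336
#' @return AUC0-inf in ng·h/mL.
#' @export
auc_inf <- function(profile, form) {
  stopifnot(inherits(profile, "concentration_profile"))
  form <- .check_form(form)
  sys <- profile$sys
  Utot <- sys$u * sys$dur
  live <- colSums(abs(sys$M)) > 0 | rowSums(abs(sys$M)) > 0 | sys$u != 0
  I <- numeric(11)
  I[live] <- tryCatch(solve(sys$M[live, live, drop = FALSE], -Utot[live]),
                      error = function(e)
                        stop("rate matrix is singular; AUC0-inf is infinite"))
  cpt <- .form_central[[form]]
  V <- profile$params[[.form_volume[[form]]]]
  1000 * I[cpt] / V
}

#' Maximum concentration over the profile grid
#'
#' The maximum is taken over the evaluation grid, so the grid must resolve
#' the peak; the NP forms peak at the end of the infusion and profiles built
#' with [exposure_grid()] include that point exactly.
#'
#' @inheritParams auc_0_336
#' @return Cmax in ng/mL.
#' @export
cmax <- function(profile, form) {
  stopifnot(inherits(profile, "concentration_profile"))
  form <- .check_form(form)
  if (length(profile$time) == 0) stop("empty grid")
  te <- profile$regimen$start_time + profile$regimen$infusion_duration
  if (min(abs(profile$time - te)) > 1e-9)
    warning("profile grid does not include the end-of-infusion time; ",
            "Cmax of NP forms may be underestimated")
  max(profile$conc[form, ])
}

#' NP share of total exposure
#'
#' Fraction of an analyte's total exposure attributable to the nanoparticle
#' form, `auc_np / (auc_np + auc_s)`. By linearity of the model this share
#' is invariant to the dose level.
#'
#' @param auc_np,auc_s non-negative exposures of the NP and S form.
#' @return A fraction in \[0, 1\].
#' @export
np_share_auc <- function(auc_np, auc_s) {
  if (auc_np < 0 || auc_s < 0) stop("AUC values must be non-negative")
  if (auc_np + auc_s == 0) stop("both AUC values are zero; share undefined")
  auc_np / (auc_np + auc_s)
}

#' Evaluation grid for exposure metrics
#'
#' Dense (0.025 h) around the infusion, 0.05 h out to 48 h to resolve the
#' delayed S-SN-38 peak, 0.5 h thereafter, with the exact end-of-infusion
#' time appended.
#'
#' @param regimen a [dose_regimen()] object.
#' @param t_end end of the grid (h); default 336.
#' @return Sorted numeric vector of times.
#' @export
exposure_grid <- function(regimen, t_end = 336) {
  t0 <- regimen$start_time
  dur <- regimen$infusion_duration
  sort(unique(c(seq(0, t0 + 2 * dur, by = 0.025), t0 + dur,
                seq(t0 + 2 * dur, min(48, t_end), by = 0.05),
                seq(min(48, t_end), t_end, by = 0.5), t_end)))
}

#' Exposure summary for one dose level
#'
#' Cmax and AUC0-336 for the four drug forms, their per-dose
#' normalizations (irinotecan forms normalised by the irinotecan mg/m^2
#' dose, SN-38 forms by the SN-38 mg/m^2 dose), NP-to-S Cmax ratios and the
#' NP share of AUC0-336 per analyte.
#'
#' @param params a [fixed_effects()] object.
#' @param regimen a [dose_regimen()] object.
#' @param t_end upper AUC limit (h); default 336.
#' @return An object of class `exposure_summary`: list with `metrics` (data
#'   frame, one row per form) and `ratios` (data frame, one row per
#'   analyte).
#' @examples
#' ex <- exposure_summary(fixed_effects(), dose_regimen(80, 50))
#' ex$metrics
#' ex$ratios
#' @export
exposure_summary <- function(params, regimen, t_end = 336) {
  prof <- simulate_profile(params, regimen, exposure_grid(regimen, t_end))
  forms <- c("np_iri", "s_iri", "np_sn38", "s_sn38")
  cm <- vapply(forms, function(f) cmax(prof, f), 0)
  au <- vapply(forms, function(f) auc_0_336(prof, f, to = t_end), 0)
  per_dose <- c(iri = regimen$dose_iri_per_m2, sn38 = regimen$dose_sn38_per_m2)
  analyte <- c("iri", "iri", "sn38", "sn38")
  metrics <- data.frame(form = forms, analyte = analyte,
                        cmax = cm, auc_0_336 = au,
                        cmax_per_mgm2 = cm / per_dose[analyte],
                        auc_per_mgm2 = au / per_dose[analyte],
                        row.names = NULL)
  ratios <- data.frame(
    analyte = c("iri", "sn38"),
    np_share_auc = c(np_share_auc(au[["np_iri"]], au[["s_iri"]]),
                     np_share_auc(au[["np_sn38"]], au[["s_sn38"]])),
    np_to_s_cmax = c(cm[["np_iri"]] / cm[["s_iri"]],
                     cm[["np_sn38"]] / cm[["s_sn38"]]))
  structure(list(metrics = metrics, ratios = ratios, regimen = regimen),
            class = "exposure_summary")
}

#' @export
print.exposure_summary <- function(x, ...) {
  cat(sprintf("Exposure at %g:%g mg/m^2 (SN-38:irinotecan), BSA %g m^2\n",
              x$regimen$dose_sn38_per_m2, x$regimen$dose_iri_per_m2,
              x$regimen$bsa))
  m <- x$metrics
  m[3:6] <- lapply(m[3:6], signif, 6)
  print(m, row.names = FALSE)
  cat("NP share of AUC:",
      sprintf("%s %.3f%%", x$ratios$analyte, 100 * x$ratios$np_share_auc),
      "\n")
  invisible(x)
}

#' Default dose-escalation levels
#'
#' Ten SN-38:irinotecan levels from 10:16 to 100:160 mg/m^2 at the product's
#' fixed 1:1.6 per-m^2 ratio, extending the studied range up to 100 mg/m^2
#' SN-38.
#'
#' @return Data frame with columns `dose_sn38`, `dose_iri` (mg/m^2).
#' @export
default_dose_levels <- function() {
  data.frame(dose_sn38 = seq(10, 100, by = 10),
             dose_iri = 1.6 * seq(10, 100, by = 10))
}

#' Exposure table across dose levels
#'
#' Typical-subject Cmax and AUC0-336 of the four drug forms at each dose
#' level.
#'
#' @param params a [fixed_effects()] object.
#' @param dose_levels data frame with columns `dose_sn38`, `dose_iri`
#'   (mg/m^2); default [default_dose_levels()].
#' @param bsa body surface area (m^2).
#' @param infusion_duration infusion length (h).
#' @return Data frame, one row per level: `dose_sn38`, `dose_iri`, then
#'   `cmax_<form>` and `auc_<form>` for the four forms.
#' @export
exposure_table <- function(params, dose_levels = default_dose_levels(),
                           bsa = 1.6, infusion_duration = 1.5) {
  if (!all(c("dose_sn38", "dose_iri") %in% names(dose_levels)))
    stop("dose_levels must have columns dose_sn38 and dose_iri")
  if (any(!is.finite(as.matrix(dose_levels[c("dose_sn38", "dose_iri")]))) ||
      any(dose_levels$dose_sn38 < 0) || any(dose_levels$dose_iri < 0))
    stop("malformed dose pair in dose_levels")
  rows <- lapply(seq_len(nrow(dose_levels)), function(i) {
    reg <- dose_regimen(dose_levels$dose_iri[i], dose_levels$dose_sn38[i],
                        bsa = bsa, infusion_duration = infusion_duration)
    ex <- exposure_summary(params, reg)$metrics
    out <- c(ex$cmax, ex$auc_0_336)
    names(out) <- c(paste0("cmax_", ex$form), paste0("auc_", ex$form))
    out
  })
  cbind(dose_levels[c("dose_sn38", "dose_iri")],
        do.call(rbind, rows))[, c("dose_sn38", "dose_iri",
                                  "cmax_np_iri", "auc_np_iri",
                                  "cmax_s_iri", "auc_s_iri",
                                  "cmax_np_sn38", "auc_np_sn38",
                                  "cmax_s_sn38", "auc_s_sn38")]
}

#' Write an exposure table to CSV
#'
#' @param x a data frame from [exposure_table()].
#' @param path output file.
#' @export
write_exposure_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
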