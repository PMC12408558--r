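#' Structural (fixed-effect) parameters of the NP/S split model
#'
#' Constructs the full fixed-effect parameter vector of the 11-compartment
#' model that tracks nanoparticle-bound (NP) and dissolved (S) irinotecan,
#' NP and S SN-38, and SN-38 glucuronide (SN-38G). Defaults are the final
#' population estimates for the SNB-101-type product: a two-compartment
#' disposition for the NP forms (shared volumes and intercompartmental
#' clearance, reflecting co-encapsulation in the same particle), the
#' literature three-compartment model for S-irinotecan, two compartments
#' each for S-SN-38 and SN-38G, and first-order NP-to-S release as the sole
#' NP elimination route.
#'
#' Shared parameters are stored once: `V1` serves both NP central volumes,
#' `V2` both NP peripheral volumes, `Q1` both NP intercompartmental
#' clearances, and `V9` the peripheral volumes of S-SN-38 and SN-38G.
#'
#' @param CL1 clearance of S-irinotecan (L/h).
#' @param V1 central volume of the NP forms (L).
#' @param V2 peripheral volume of the NP forms (L).
#' @param Q1 intercompartmental clearance of the NP forms (L/h).
#' @param K13 first-order release rate, NP-irinotecan to S-irinotecan (1/h).
#' @param V3,V4,V5 central, rapid-peripheral and slow-peripheral volumes of
#'   S-irinotecan (L); literature-fixed.
#' @param Q2,Q3 intercompartmental clearances of S-irinotecan (L/h);
#'   literature-fixed.
#' @param K68 first-order release rate, NP-SN-38 to S-SN-38 (1/h).
#' @param V8 central volume of S-SN-38 (L).
#' @param V9 peripheral volume of S-SN-38 and of SN-38G (L).
#' @param Q5 intercompartmental clearance of S-SN-38 (L/h).
#' @param CL2 clearance of S-SN-38 by glucuronidation to SN-38G (L/h).
#' @param CL3 clearance of SN-38G (L/h).
#' @param Q6 intercompartmental clearance of SN-38G (L/h).
#' @param V10 central volume of SN-38G (L).
#' @param fnp_iri fraction of the irinotecan dose present in NP form (0.15).
#' @param fnp_sn38 fraction of the SN-38 dose present in NP form (0.98).
#' @param fmet molar fraction of irinotecan clearance converted to SN-38
#'   (0.03); the mass flux is scaled by `mw_sn38 / mw_iri`.
#' @param mw_iri,mw_sn38 molar masses (g/mol) of irinotecan and SN-38.
#'
#' @return An object of class `fixed_effects`: a named numeric vector.
#' @examples
#' p <- fixed_effects()
#' p[["CL1"]]
#' @export
fixed_effects <- function(CL1 = 29.7, V1 = 54.4, V2 = 287, Q1 = 6.45,
                          K13 = 64.4, V3 = 68.6, V4 = 67.2, V5 = 127,
                          Q2 = 114, Q3 = 9.89, K68 = 0.712, V8 = 40.3,
                          V9 = 491, Q5 = 121, CL2 = 167, CL3 = 16.9,
                          Q6 = 11.3, V10 = 7.84,
                          fnp_iri = 0.15, fnp_sn38 = 0.98, fmet = 0.03,
                          mw_iri = 586.68, mw_sn38 = 392.40) {
  p <- c(CL1 = CL1, V1 = V1, V2 = V2, Q1 = Q1, K13 = K13, V3 = V3, V4 = V4,
         V5 = V5, Q2 = Q2, Q3 = Q3, K68 = K68, V8 = V8, V9 = V9, Q5 = Q5,
         CL2 = CL2, CL3 = CL3, Q6 = Q6, V10 = V10,
         fnp_iri = fnp_iri, fnp_sn38 = fnp_sn38, fmet = fmet,
         mw_iri = mw_iri, mw_sn38 = mw_sn38)
  validate_fixed_effects(p)
  structure(p, class = "fixed_effects")
}

# volumes and elimination clearances must be strictly positive; rate
# constants and intercompartmental clearances may be zero (a closed or
# absent pathway), never negative
validate_fixed_effects <- function(p) {
  strict <- c("CL1", "V1", "V2", "V3", "V4", "V5", "V8", "V9", "CL2",
              "CL3", "V10", "mw_iri", "mw_sn38")
  nonneg <- c("Q1", "K13", "Q2", "Q3", "K68", "Q5", "Q6")
  frac <- c("fnp_iri", "fnp_sn38", "fmet")
  miss <- setdiff(c(strict, nonneg, frac), names(p))
  if (length(miss))
    stop("missing fixed-effect parameter(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(p)))
    stop("non-finite fixed-effect parameter(s): ",
         paste(names(p)[!is.finite(p)], collapse = ", "))
  bad <- strict[p[strict] <= 0]
  if (length(bad))
    stop("parameter(s) must be strictly positive: ", paste(bad, collapse = ", "))
  bad <- nonneg[p[nonneg] < 0]
  if (length(bad))
    stop("parameter(s) must be non-negative: ", paste(bad, collapse = ", "))
  bad <- frac[p[frac] <= 0 | p[frac] >= 1]
  if (length(bad))
    stop("fraction(s) must lie strictly in (0, 1): ", paste(bad, collapse = ", "))
  invisible(p)
}

#' @export
print.fixed_effects <- function(x, ...) {
  cat("Fixed effects of the NP/S split model\n")
  print(round(unclass(x), 5), ...)
  invisible(x)
}

# parameters eligible for between-subject variability (the model's full
# structural set, excluding dose-split fractions and molar-mass constants)
.structural_names <- c("CL1", "V1", "V2", "Q1", "K13", "V3", "V4", "V5",
                       "Q2", "Q3", "K68", "V8", "V9", "Q5", "CL2", "CL3",
                       "Q6", "V10")

#' Between-subject variability and residual-error specification
#'
#' Log-normal between-subject variability (BSV) is parameterised by the
#' standard deviation of the log-scale random effect for each structural
#' parameter (reported in the field as "BSV%" = 100 * sd(log)); parameters
#' with no BSV carry an omega of zero. Residual error is proportional with a
#' separate standard deviation per observed analyte (total irinotecan, total
#' SN-38, SN-38G). Defaults are the final model values; the S-irinotecan
#' BSVs are literature-fixed but still sampled when simulating subjects.
#'
#' @param omega named numeric vector of log-scale SDs; names must be
#'   structural parameter names. Parameters not named get omega = 0.
#' @param sigma named numeric vector of proportional residual SDs with names
#'   `iri`, `sn38`, `sn38g`.
#' @return An object of class `variability_spec` with elements `omega`
#'   (full-length, zero-filled) and `sigma`.
#' @examples
#' v <- variability_spec()
#' v$omega[["CL1"]]    # 0.347, i.e. 34.7% BSV
#' @export
variability_spec <- function(omega = c(CL1 = 0.347, V1 = 0.409, V2 = 0.945,
                                       V3 = 0.154, V4 = 0.162, V5 = 0.291,
                                       Q2 = 0.861, Q3 = 0.495, K68 = 0.396,
                                       CL2 = 0.449, CL3 = 1.159, V10 = 1.221),
                             sigma = c(iri = 0.21, sn38 = 0.416, sn38g = 0.308)) {
  if (length(omega) && (is.null(names(omega)) || any(names(omega) == "")))
    stop("omega must be a named vector")
  unknown <- setdiff(names(omega), .structural_names)
  if (length(unknown))
    stop("unknown omega parameter(s): ", paste(unknown, collapse = ", "))
  if (any(omega < 0)) stop("omega values must be non-negative")
  full <- stats::setNames(numeric(length(.structural_names)), .structural_names)
  full[names(omega)] <- omega
  if (!all(c("iri", "sn38", "sn38g") %in% names(sigma)))
    stop("sigma must have entries named iri, sn38, sn38g")
  sigma <- sigma[c("iri", "sn38", "sn38g")]
  if (any(sigma < 0)) stop("sigma values must be non-negative")
  structure(list(omega = full, sigma = sigma), class = "variability_spec")
}

#' @export
print.variability_spec <- function(x, ...) {
  cat("Between-subject variability (sd of log):\n")
  print(round(x$omega[x$omega > 0], 4))
  cat("Proportional residual error (sd):\n")
  print(round(x$sigma, 4))
  invisible(x)
}

#' Dosing regimen for a single intravenous administration
#'
#' Doses are given per body surface area, the field's convention for
#' cytotoxics; absolute amounts are `dose * bsa`. Both drugs are infused
#' simultaneously at constant (zero-order) rate over `infusion_duration`.
#' At dosing time the product carries its storage-equilibrium NP/S split,
#' so the absolute dose of each drug is divided between the NP and S
#' central compartments according to `fnp_iri` and `fnp_sn38`.
#'
#' @param dose_iri_per_m2 irinotecan dose (mg/m^2).
#' @param dose_sn38_per_m2 SN-38 dose (mg/m^2).
#' @param bsa body surface area (m^2); default 1.6, a typical adult subject.
#' @param infusion_duration infusion length (h); default 1.5.
#' @param start_time infusion start (h); default 0.
#' @return An object of class `dose_regimen`.
#' @examples
#' dose_regimen(80, 50)    # the 50:80 mg/m^2 (SN-38:irinotecan) level
#' @export
dose_regimen <- function(dose_iri_per_m2, dose_sn38_per_m2, bsa = 1.6,
                         infusion_duration = 1.5, start_time = 0) {
  if (dose_iri_per_m2 < 0 || dose_sn38_per_m2 < 0) stop("doses must be >= 0")
  if (bsa <= 0) stop("bsa must be > 0")
  if (infusion_duration <= 0) stop("infusion_duration must be > 0")
  if (start_time < 0) stop("start_time must be >= 0")
  structure(list(dose_iri_per_m2 = dose_iri_per_m2,
                 dose_sn38_per_m2 = dose_sn38_per_m2,
                 bsa = bsa,
                 dose_iri = dose_iri_per_m2 * bsa,
                 dose_sn38 = dose_sn38_per_m2 * bsa,
                 infusion_duration = infusion_duration,
                 start_time = start_time),
            class = "dose_regimen")
}

#' @export
print.dose_regimen <- function(x, ...) {
  cat(sprintf("Dose regimen: %g mg/m^2 irinotecan + %g mg/m^2 SN-38 (BSA %g m^2)\n",
              x$dose_iri_per_m2, x$dose_sn38_per_m2, x$bsa))
  cat(sprintf("  absolute: %g mg + %g mg, %g h infusion from t = %g h\n",
              x$dose_iri, x$dose_sn38, x$infusion_duration, x$start_time))
  invisible(x)
}
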