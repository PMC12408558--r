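#' Trial design: cohorts, sampling schedule, dosing conventions
#'
#' @param cohorts data frame with columns `n` (subjects), `dose_iri`,
#'   `dose_sn38` (mg/m^2), optionally a `cohort` id and demographic
#'   metadata columns (carried along, never used by the model).
#' @param times sampling times (h) including the pre-dose sample at 0.
#' @param bsa body surface area applied to every subject (m^2).
#' @param infusion_duration infusion length (h).
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(cohorts, times = default_sampling_times(),
                         bsa = 1.6, infusion_duration = 1.5) {
  if (!is.data.frame(cohorts) || nrow(cohorts) == 0)
    stop("cohorts must be a non-empty data frame")
  req <- c("n", "dose_iri", "dose_sn38")
  miss <- setdiff(req, names(cohorts))
  if (length(miss)) stop("cohorts missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(cohorts$cohort)) cohorts$cohort <- seq_len(nrow(cohorts))
  if (any(cohorts$n < 1)) stop("each cohort needs n >= 1")
  if (any(times < 0) || is.unsorted(times, strictly = TRUE))
    stop("times must be non-negative and strictly increasing")
  structure(list(cohorts = cohorts, times = times, bsa = bsa,
                 infusion_duration = infusion_duration),
            class = "trial_design")
}

#' First-cycle sampling schedule
#'
#' Pre-dose plus 16 post-dose samples out to 169.5 h.
#'
#' @return Numeric vector of 17 times (h).
#' @export
default_sampling_times <- function() {
  c(0, 0.5, 1, 2, 4, 6, 8, 10, 12, 24, 36, 48, 72, 96, 120, 144, 169.5)
}

#' The Phase-I dose-escalation design
#'
#' Seven cohorts (21 subjects) with SN-38 doses from 5 to 50 mg/m^2 at the
#' fixed 1.6:1 irinotecan:SN-38 per-m^2 ratio, sampled on the first-cycle
#' schedule. Demographics are metadata only; the final model has no
#' covariates.
#'
#' @return A [trial_design()] object.
#' @examples
#' d <- default_design()
#' sum(d$cohorts$n)    # 21 subjects
#' @export
default_design <- function() {
  trial_design(
    cohorts = data.frame(
      cohort = 1:7,
      n = c(1, 1, 1, 5, 7, 3, 3),
      dose_iri = c(8, 16, 32, 48, 64, 72, 80),
      dose_sn38 = c(5, 10, 20, 30, 40, 45, 50),
      sex_m = c(1, 1, 1, 3, 4, 2, 2),
      sex_f = c(0, 0, 0, 2, 3, 1, 1),
      age = c(60, 62, 58, 65, 63, 59, 62),
      weight = c(70, 72, 68, 75, 73, 70, 73)
    )
  )
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("trial_design: %d cohorts, %d subjects, %d sampling times (0-%g h)\n",
              nrow(x$cohorts), sum(x$cohorts$n), length(x$times), max(x$times)))
  cat(sprintf("  BSA %g m^2, %g h infusion\n", x$bsa, x$infusion_duration))
  print(x$cohorts[c("cohort", "n", "dose_iri", "dose_sn38")], row.names = FALSE)
  invisible(x)
}

#' Read / write a trial design as YAML
#'
#' @param path file path.
#' @return `read_trial_design` returns a [trial_design()]; the writer
#'   returns `path` invisibly.
#' @export
read_trial_design <- function(path) {
  y <- yaml::read_yaml(path)
  trial_design(cohorts = as.data.frame(lapply(y$cohorts, unlist)),
               times = as.numeric(y$times), bsa = y$bsa,
               infusion_duration = y$infusion_duration)
}

#' @rdname read_trial_design
#' @param design a [trial_design()] object.
#' @export
write_trial_design <- function(design, path) {
  yaml::write_yaml(list(cohorts = as.list(design$cohorts),
                        times = design$times, bsa = design$bsa,
                        infusion_duration = design$infusion_duration), path)
  invisible(path)
}
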