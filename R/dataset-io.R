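# ---- dataset and parameter file round-tripping ------------------------------

.dataset_cols <- c("ID", "TIME", "EVID", "CMT", "AMT", "RATE", "DV", "DVID",
                   "MDV", "COHORT")

#' Write / read a trial dataset as CSV
#'
#' Comma-separated, UTF-8, header row, no index column. The reader
#' validates the schema and basic integrity: required columns present,
#' non-negative dose amounts, and within each subject non-decreasing event
#' times; violations are reported with the offending row and column. A
#' dataset with dose records but no evaluable observations is accepted with
#' a warning.
#'
#' @param dataset a `trial_dataset` data frame (from [simulate_trial()] or
#'   [read_trial_dataset()]).
#' @param path file path.
#' @return `read_trial_dataset` returns a `trial_dataset` data frame; the
#'   writer returns `path` invisibly.
#' @export
write_trial_dataset <- function(dataset, path) {
  stopifnot(is.data.frame(dataset))
  utils::write.csv(dataset[.dataset_cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_dataset
#' @export
read_trial_dataset <- function(path) {
  x <- utils::read.csv(path, na.strings = "")
  validate_trial_dataset(x)
}

#' Validate a trial dataset
#'
#' @param x data frame to check.
#' @return `x` with class `trial_dataset`, invisibly usable.
#' @export
validate_trial_dataset <- function(x) {
  miss <- setdiff(.dataset_cols, names(x))
  if (length(miss))
    stop("dataset missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.na(x$AMT) & x$AMT < 0)
  if (length(bad))
    stop(sprintf("negative AMT at row %d (column AMT)", bad[1]))
  for (id in unique(x$ID)) {
    tt <- x$TIME[x$ID == id]
    if (is.unsorted(tt)) {
      row <- which(x$ID == id)[which(diff(tt) < 0)[1] + 1L]
      stop(sprintf("non-monotone TIME within subject %s at row %d (column TIME)",
                   id, row))
    }
  }
  n_obs <- sum(x$EVID == 0 & x$MDV == 0, na.rm = TRUE)
  if (n_obs == 0)
    warning("dataset contains zero evaluable observations (EVID == 0, MDV == 0)")
  class(x) <- c("trial_dataset", "data.frame")
  x
}

#' Read / write model parameters as YAML
#'
#' The file uses the final-model symbol names (`CL1` ... `V10`, residual
#' errors `PROP1`-`PROP3` for irinotecan / SN-38 / SN-38G), a `BSV` block of
#' log-scale standard deviations keyed by parameter, and the dose-split and
#' conversion constants `fnp_iri`, `fnp_sn38`, `fmet`, `mw_iri`, `mw_sn38`.
#'
#' @param path file path.
#' @return `read_model_params` returns `list(params, variability)`; the
#'   writer returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_model_params(f, fixed_effects(), variability_spec())
#' read_model_params(f)$params[["K68"]]
#' @export
read_model_params <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c(.structural_names, "fnp_iri", "fnp_sn38", "fmet",
            "mw_iri", "mw_sn38", "PROP1", "PROP2", "PROP3")
  miss <- setdiff(need, names(y))
  if (length(miss))
    stop("parameter file missing key(s): ", paste(miss, collapse = ", "))
  params <- do.call(fixed_effects, y[c(.structural_names, "fnp_iri",
                                       "fnp_sn38", "fmet", "mw_iri",
                                       "mw_sn38")])
  omega <- if (is.null(y$BSV)) numeric(0) else unlist(y$BSV)
  variability <- variability_spec(
    omega = omega,
    sigma = c(iri = y$PROP1, sn38 = y$PROP2, sn38g = y$PROP3))
  list(params = params, variability = variability)
}

#' @rdname read_model_params
#' @param params a [fixed_effects()] object.
#' @param variability a [variability_spec()] object.
#' @export
write_model_params <- function(path, params = fixed_effects(),
                               variability = variability_spec()) {
  validate_fixed_effects(params)
  p <- as.list(unclass(params))
  y <- c(p[c(.structural_names, "fnp_iri", "fnp_sn38", "fmet",
             "mw_iri", "mw_sn38")],
         list(PROP1 = unname(variability$sigma[["iri"]]),
              PROP2 = unname(variability$sigma[["sn38"]]),
              PROP3 = unname(variability$sigma[["sn38g"]]),
              BSV = as.list(variability$omega[variability$omega > 0])))
  yaml::write_yaml(y, path)
  invisible(path)
}
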