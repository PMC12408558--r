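# ---- methods for np_fit -----------------------------------------------------

#' @export
print.np_fit <- function(x, ...) {
  cat("Population NP/S pharmacokinetic fit (Laplace)\n")
  cat(sprintf("  %d subjects, %d observations, OFV = %.3f\n",
              x$n_subjects, x$n_obs, x$ofv))
  if (length(x$coefficients)) {
    cat("  estimates:\n")
    print(signif(x$coefficients, 5))
  } else cat("  all parameters fixed (evaluation only)\n")
  invisible(x)
}

#' @export
coef.np_fit <- function(object, ...) object$coefficients

#' @export
logLik.np_fit <- function(object, ...) {
  structure(-object$ofv / 2, df = length(object$coefficients),
            nobs = object$n_obs, class = "logLik")
}

#' Summary of an NP/S population fit
#'
#' @param object an [np_fit()] object.
#' @param ... unused.
#' @return A `summary.np_fit` object: estimate table (start vs estimate),
#'   BSV and residual-error values, eta shrinkage, and convergence
#'   diagnostics (gradient norm, information-matrix condition number).
#' @export
summary.np_fit <- function(object, ...) {
  free <- object$free$theta
  tab <- data.frame(
    parameter = c(free, paste0("omega_", object$free$omega),
                  paste0("sigma_", object$free$sigma)),
    start = unname(c(unclass(object$start)[free],
                     object$variability_start$omega[object$free$omega],
                     object$variability_start$sigma[object$free$sigma])),
    estimate = unname(object$coefficients))
  structure(list(table = tab, ofv = object$ofv,
                 omega = object$omega[object$omega > 0],
                 sigma = object$sigma,
                 shrinkage = object$shrinkage,
                 convergence = object$convergence,
                 grad_norm = object$grad_norm,
                 info_condition = object$info_condition,
                 n_subjects = object$n_subjects, n_obs = object$n_obs),
            class = "summary.np_fit")
}

#' @export
print.summary.np_fit <- function(x, ...) {
  cat(sprintf("NP/S population fit: %d subjects, %d observations\n",
              x$n_subjects, x$n_obs))
  cat(sprintf("OFV (-2 log marginal likelihood): %.3f\n", x$ofv))
  if (nrow(x$table)) {
    cat("\nFree parameters:\n")
    x$table$estimate <- signif(x$table$estimate, 5)
    x$table$start <- signif(x$table$start, 5)
    print(x$table, row.names = FALSE)
  }
  if (length(x$shrinkage)) {
    cat("\nEta shrinkage:\n")
    print(round(x$shrinkage, 3))
  }
  cat(sprintf("\nconvergence code %s; |gradient| %.3g; information condition %.3g\n",
              x$convergence, x$grad_norm, x$info_condition))
  invisible(x)
}

# individual predictions aligned with the evaluable observation records
.individual_pred <- function(object) {
  unlist(lapply(seq_along(object$subjects), function(i) {
    s <- object$subjects[[i]]
    .predict_totals(.ebe_params(object, i), s$dosing,
                    s$ut)[cbind(s$dvid, s$tidx)]
  }), use.names = FALSE)
}

#' @export
fitted.np_fit <- function(object, ...) .individual_pred(object)

#' Residuals of an NP/S population fit
#'
#' @param object an [np_fit()] object.
#' @param type `"iwres"` (individual weighted, `(DV - f)/(sigma f)`) or
#'   `"response"` (`DV - f`), with `f` the individual prediction at the
#'   eta mode.
#' @param ... unused.
#' @export
residuals.np_fit <- function(object, type = c("iwres", "response"), ...) {
  type <- match.arg(type)
  f <- .individual_pred(object)
  dv <- unlist(lapply(object$subjects, `[[`, "dv"), use.names = FALSE)
  dvid <- unlist(lapply(object$subjects, `[[`, "dvid"), use.names = FALSE)
  if (type == "response") return(dv - f)
  (dv - f) / (.resolve_sigma3(object$sigma)[dvid] * f)
}

#' Predicted concentration curves from a fit
#'
#' @param object an [np_fit()] object.
#' @param subjects subject positions (default all).
#' @param times prediction grid (h); default a dense grid over each
#'   subject's observation span.
#' @param level `"individual"` (empirical-Bayes parameters) or
#'   `"typical"` (population parameters).
#' @param ... unused.
#' @return Long data frame: `ID`, `time`, the five form concentrations and
#'   the analyte totals (ng/mL).
#' @export
predict.np_fit <- function(object, subjects = NULL, times = NULL,
                           level = c("individual", "typical"), ...) {
  level <- match.arg(level)
  if (is.null(subjects)) subjects <- seq_along(object$subjects)
  out <- lapply(subjects, function(i) {
    s <- object$subjects[[i]]
    tt <- if (is.null(times))
      sort(unique(c(seq(0, max(s$ut), length.out = 400), s$ut,
                    s$dosing$t0 + s$dosing$dur)))
    else times
    p <- if (level == "individual") .ebe_params(object, i) else object$theta
    C <- .predict_conc(p, s$dosing, tt)
    data.frame(ID = s$id, time = tt, t(C),
               total_iri = C["np_iri", ] + C["s_iri", ],
               total_sn38 = C["np_sn38", ] + C["s_sn38", ],
               total_sn38g = C["sn38g", ])
  })
  do.call(rbind, out)
}

#' Simulate replicate datasets from a fitted model
#'
#' Re-simulates the original subjects (their dosing and sampling records)
#' with fresh random effects and residual errors drawn from the estimated
#' model.
#'
#' @param object an [np_fit()] object.
#' @param nsim number of replicate datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A list of `nsim` data frames shaped like the observation rows of
#'   the original dataset (columns `ID`, `TIME`, `DVID`, `DV`, `COHORT`).
#' @export
simulate.np_fit <- function(object, nsim = 1, seed = NULL, ...) {
  .with_seed(seed, {
    omega <- object$omega
    sigma3 <- .resolve_sigma3(object$sigma)
    lapply(seq_len(nsim), function(r) {
      do.call(rbind, lapply(object$subjects, function(s) {
        eta <- stats::rnorm(length(.structural_names)) * omega
        p <- unclass(object$theta)
        p[.structural_names] <- p[.structural_names] * exp(eta)
        f <- .predict_totals(structure(p, class = "fixed_effects"),
                             s$dosing, s$ut)[cbind(s$dvid, s$tidx)]
        dv <- pmax(f * (1 + stats::rnorm(length(f), 0, sigma3[s$dvid])), 0)
        data.frame(ID = s$id, TIME = s$time, DVID = s$dvid, DV = dv,
                   COHORT = s$cohort)
      }))
    })
  })
}

#' @export
plot.np_fit <- function(x, log = "xy", ...) {
  f <- .individual_pred(x)
  dv <- unlist(lapply(x$subjects, `[[`, "dv"), use.names = FALSE)
  dvid <- unlist(lapply(x$subjects, `[[`, "dvid"), use.names = FALSE)
  labs <- c("total irinotecan", "total SN-38", "SN-38G")
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  for (a in 1:3) {
    sel <- dvid == a & dv > 0 & f > 0
    graphics::plot(f[sel], dv[sel], log = log, xlab = "Individual prediction",
                   ylab = "Observation", main = labs[a], ...)
    graphics::abline(0, 1, col = 2)
  }
  invisible(x)
}

#' Write a fit result as JSON
#'
#' @param fit an [np_fit()] object.
#' @param path output file.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "np_fit"))
  out <- list(ofv = fit$ofv,
              estimates = as.list(fit$coefficients),
              theta = as.list(unclass(fit$theta)),
              omega = as.list(fit$omega[fit$omega > 0]),
              sigma = as.list(fit$sigma),
              shrinkage = as.list(fit$shrinkage),
              convergence = fit$convergence,
              grad_norm = fit$grad_norm,
              info_condition = fit$info_condition,
              n_subjects = fit$n_subjects, n_obs = fit$n_obs)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Parameter table in the final-model layout
#'
#' @param fit an [np_fit()] object.
#' @return Data frame with columns `parameter`, `estimate`, `bsv_percent`,
#'   `estimated` (whether the value was free in this fit).
#' @export
fit_parameter_table <- function(fit) {
  stopifnot(inherits(fit, "np_fit"))
  th <- unclass(fit$theta)[.structural_names]
  data.frame(parameter = .structural_names,
             estimate = unname(th),
             bsv_percent = unname(100 * fit$omega[.structural_names]),
             estimated = .structural_names %in% fit$free$theta)
}
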