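# ---- exact solution of the linear system -----------------------------------
#
# The model is dA/dt = M A + u(t) with u piecewise constant (constant during
# the infusion, zero afterwards). With K13 = 64.4/h next to terminal phases
# of tens of hours the system is stiff, so profiles are computed exactly by
# the matrix exponential, evaluated through the eigendecomposition of M
# (real, distinct eigenvalues in the typical parameter region). During the
# infusion, with A(t0) = 0,
#   A(t0 + s) = P diag(expm1(lambda s)/lambda) P^-1 u,
# and after the end of infusion the homogeneous decay
#   A(t) = P diag(exp(lambda (t - te))) P^-1 A(te).
# When the eigendecomposition is ill-conditioned (repeated eigenvalues from
# degenerate parameter sets such as Q1 = K13 = 0) the solver falls back to
# stepwise Matrix::expm() on the forcing-augmented matrix, which is exact for
# any diagonalizability.

.lin_system <- function(params, regimen) {
  list(M = rate_matrix(params),
       u = infusion_rates(params, regimen),
       t0 = regimen$start_time,
       dur = regimen$infusion_duration)
}

.solve_amounts <- function(sys, times) {
  M <- sys$M; u <- sys$u; t0 <- sys$t0; dur <- sys$dur
  n <- length(times)
  s <- times - t0
  A <- matrix(0, 11, n)
  live <- s > 0
  if (!any(live) || all(u == 0)) return(A)

  eg <- eigen(M, symmetric = FALSE)
  P <- eg$vectors; lam <- eg$values
  Pi <- tryCatch(solve(P), error = function(e) NULL)
  ok <- !is.null(Pi) && max(Mod(P %*% Pi - diag(11))) < 1e-8
  if (!ok) return(.solve_amounts_expm(sys, times))

  scale <- max(Mod(lam))
  tiny <- Mod(lam) < 1e-12 * scale
  phi <- function(srel) {            # (exp(lam s) - 1) / lam, columnwise in s
    X <- outer(lam, srel)
    out <- (if (is.complex(X)) exp(X) - 1 else expm1(X)) / lam
    if (any(tiny)) out[tiny, ] <- rep(srel, each = sum(tiny))
    out
  }
  w <- drop(Pi %*% u)
  s_live <- s[live]
  Phi <- phi(pmin(s_live, dur))
  Ai <- P %*% (Phi * w)                      # 11 x n_live, at min(s, dur)
  post <- s_live > dur
  if (any(post)) {
    zdur <- drop(Pi %*% (P %*% (drop(phi(dur)) * w)))
    E <- exp(outer(lam, s_live[post] - dur))
    Ai[, post] <- P %*% (E * zdur)
  }
  A[, live] <- Re(Ai)
  A[A < 0 & A > -1e-9] <- 0
  A
}

# fallback: stepwise matrix exponential on the augmented system
# d/dt [A; 1] = [[M, u], [0, 0]] [A; 1] during the infusion
.solve_amounts_expm <- function(sys, times) {
  M <- sys$M; u <- sys$u; t0 <- sys$t0; dur <- sys$dur
  Maug <- rbind(cbind(M, u), 0)
  pts <- sort(unique(c(t0, t0 + dur, times[times > t0])))
  pts <- pts[pts >= t0]
  state <- c(numeric(11), 1)
  out <- matrix(0, 11, length(pts), dimnames = list(NULL, NULL))
  cur_t <- t0
  for (j in seq_along(pts)) {
    tj <- pts[j]
    while (cur_t < tj - 1e-12) {
      seg_end <- if (cur_t < t0 + dur - 1e-12) min(tj, t0 + dur) else tj
      dt <- seg_end - cur_t
      if (cur_t < t0 + dur - 1e-12) {
        state <- as.numeric(Matrix::expm(Maug * dt) %*% state)
      } else {
        state[1:11] <- as.numeric(Matrix::expm(M * dt) %*% state[1:11])
      }
      cur_t <- seg_end
    }
    out[, j] <- state[1:11]
  }
  A <- matrix(0, 11, length(times))
  idx <- match(round(times, 12), round(pts, 12))
  has <- !is.na(idx) & times > t0
  A[, has] <- out[, idx[has]]
  A[A < 0 & A > -1e-9] <- 0
  A
}

# cumulative dosed amount per compartment at time t (vectorised in t)
.cum_input <- function(sys, t) {
  s <- pmin(pmax(t - sys$t0, 0), sys$dur)
  outer(sys$u, s)
}

# exact running integral of amounts: int_0^t A ds = M^-1 (A(t) - U(t));
# M is invertible whenever every pathway out of the system is open
.integral_amounts <- function(sys, t) {
  A <- .solve_amounts(sys, t)
  U <- .cum_input(sys, t)
  M <- sys$M
  # compartments with no connections and no input never hold mass and can
  # be dropped before inverting (they make M trivially singular)
  live <- colSums(abs(M)) > 0 | rowSums(abs(M)) > 0 | sys$u != 0
  I <- matrix(0, nrow(M), ncol(A))
  sol <- tryCatch(solve(M[live, live, drop = FALSE],
                        (A - U)[live, , drop = FALSE]),
                  error = function(e) NULL)
  if (is.null(sol)) stop("rate matrix is singular; AUC integral undefined ",
                         "(a zero release or clearance leaves trapped mass)")
  I[live, ] <- sol
  I
}

.amounts_to_conc <- function(A, params) {
  V <- unname(params[.form_volume])
  C <- 1000 * A[.form_central, , drop = FALSE] / V   # mg/L -> ng/mL
  rownames(C) <- .form_names
  C
}

#' Simulate a typical-subject concentration profile
#'
#' Solves the 11-compartment system exactly (piecewise matrix exponential)
#' for a single simultaneous zero-order infusion of irinotecan and SN-38
#' split into NP and S forms, and returns compartment amounts (mg) and
#' form-specific plasma concentrations (ng/mL).
#'
#' @param params a [fixed_effects()] object.
#' @param regimen a [dose_regimen()] object.
#' @param times numeric time grid (h), sorted strictly increasing,
#'   non-negative.
#' @return An object of class `concentration_profile`: list with elements
#'   `time`, `amounts` (11 x n, mg), `conc` (5 x n, ng/mL, rows `np_iri`,
#'   `s_iri`, `np_sn38`, `s_sn38`, `sn38g`), `params`, `regimen`.
#' @examples
#' prof <- simulate_profile(fixed_effects(), dose_regimen(80, 50),
#'                          times = seq(0, 336, by = 0.5))
#' max(prof$conc["np_sn38", ])
#' @export
simulate_profile <- function(params, regimen, times) {
  validate_fixed_effects(params)
  if (!inherits(regimen, "dose_regimen")) stop("regimen must be a dose_regimen")
  if (length(times) == 0) stop("empty time grid")
  if (any(times < 0)) stop("negative time in grid")
  if (is.unsorted(times, strictly = TRUE)) stop("time grid must be sorted strictly increasing")
  sys <- .lin_system(params, regimen)
  A <- .solve_amounts(sys, times)
  structure(list(time = times, amounts = A,
                 conc = .amounts_to_conc(A, params),
                 params = params, regimen = regimen, sys = sys),
            class = "concentration_profile")
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf("concentration_profile: %d time points over [%g, %g] h\n",
              length(x$time), min(x$time), max(x$time)))
  cat(sprintf("  doses: %g mg irinotecan + %g mg SN-38 over %g h\n",
              x$regimen$dose_iri, x$regimen$dose_sn38,
              x$regimen$infusion_duration))
  cat("  peak concentrations (ng/mL):\n")
  print(round(apply(x$conc, 1, max), 3))
  invisible(x)
}

#' @export
as.data.frame.concentration_profile <- function(x, ...) {
  data.frame(time = x$time, t(x$conc),
             total_iri = x$conc["np_iri", ] + x$conc["s_iri", ],
             total_sn38 = x$conc["np_sn38", ] + x$conc["s_sn38", ],
             total_sn38g = x$conc["sn38g", ])
}

#' @export
plot.concentration_profile <- function(x, log = "y", forms = .form_names, ...) {
  C <- x$conc[forms, , drop = FALSE]
  C[C <= 0] <- NA
  graphics::matplot(x$time, t(C), type = "l", lty = 1, log = log,
                    xlab = "Time (h)", ylab = "Concentration (ng/mL)", ...)
  graphics::legend("topright", legend = forms, lty = 1,
                   col = seq_along(forms), bty = "n")
  invisible(x)
}

#' Total observed-analyte concentrations
#'
#' Total plasma irinotecan is the sum of the NP and S irinotecan forms,
#' total SN-38 the sum of the NP and S SN-38 forms; SN-38G circulates only
#' in dissolved form.
#'
#' @param profile a [simulate_profile()] result.
#' @return Data frame with columns `time`, `iri`, `sn38`, `sn38g` (ng/mL).
#' @export
observe_totals <- function(profile) {
  stopifnot(inherits(profile, "concentration_profile"))
  C <- profile$conc
  data.frame(time = profile$time,
             iri = C["np_iri", ] + C["s_iri", ],
             sn38 = C["np_sn38", ] + C["s_sn38", ],
             sn38g = C["sn38g", ])
}
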