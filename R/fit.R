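# ---- Laplace-approximated marginal likelihood and model fitting ------------
#
# Per subject i with random effects eta ~ N(0, Omega) and proportional
# residual error, the contribution to the objective function value is
#   -2 log integral p(y_i | eta) p(eta) d eta
# approximated by Laplace's method at the per-subject mode eta_i:
#   h(eta_i) - k log(2 pi) + log det(H/2),   H = hessian of h at the mode,
# where h(eta) = -2 log p(y|eta) - 2 log p(eta) including all 2-pi
# constants, so the OFV is the full -2 log marginal likelihood (no hidden
# additive constant). The observation density is
# Normal(pred, (sigma_analyte * pred)^2) with pred the individual
# prediction at eta (the conventional pairing for Laplace).

.fit_control <- function(control = list()) {
  defaults <- list(outer_reltol = 1e-7, outer_maxit = 1000,
                   outer_method = "nm", cyclic_sweeps = 3,
                   inner_reltol = 1e-10, inner_maxit = 200,
                   inner_gtol = 1e-8, fd = "central", inner_starts = 5,
                   inner_hessian = "fd",
                   outer_restarts = 2, diagnostics = TRUE, trace = 0)
  defaults[names(control)] <- control
  defaults
}

# split a long-format dataset into per-subject dosing + observations
.parse_dataset <- function(data) {
  data <- validate_trial_dataset(as.data.frame(data))
  lapply(split(data, data$ID), function(d) {
    dose <- d[d$EVID == 1, ]
    if (nrow(dose) == 0) stop("subject ", d$ID[1], " has no dose records")
    amt <- numeric(11)
    amt[dose$CMT] <- dose$AMT
    dur <- dose$AMT[1] / dose$RATE[1]
    obs <- d[d$EVID == 0 & d$MDV == 0, ]
    # a zero observation makes the proportional-error density unbounded as
    # the prediction vanishes; such records (residual draws floored at 0)
    # are excluded from the likelihood like any non-quantifiable sample
    n_zero <- sum(obs$DV <= 0)
    obs <- obs[obs$DV > 0, ]
    ut <- sort(unique(obs$TIME))
    tidx <- match(obs$TIME, ut)
    list(id = d$ID[1], cohort = d$COHORT[1],
         dosing = list(amt = amt, dur = dur, t0 = dose$TIME[1]),
         time = obs$TIME, tidx = tidx, ut = ut,
         dv = obs$DV, dvid = obs$DVID,
         fidx = obs$DVID + (tidx - 1L) * 3L, n_zero = n_zero)
  })
}

# individual predictions at the subject's observation records; p in
# canonical fixed_effects order
.subject_f <- function(p, subj) {
  if (any(!is.finite(p))) return(rep(NaN, length(subj$fidx)))
  sys <- list(M = .rate_matrix_fast(p), u = subj$dosing$amt / subj$dosing$dur,
              t0 = subj$dosing$t0, dur = subj$dosing$dur)
  if (any(!is.finite(sys$M))) return(rep(NaN, length(subj$fidx)))
  A <- .solve_amounts(sys, subj$ut)
  tot <- rbind(1000 * (A[1L, ] / p[[2L]] + A[3L, ] / p[[6L]]),
               1000 * (A[6L, ] / p[[2L]] + A[8L, ] / p[[12L]]),
               1000 * A[10L, ] / p[[18L]])
  tot[subj$fidx]
}

# Laplace -2 log marginal likelihood for one subject; returns value + mode.
# Inner machinery: the penalised deviance h(eta) is minimised by BFGS with
# an analytic gradient assembled from a central finite-difference Jacobian
# of the predictions, followed by a Newton polish with the
# finite-difference Hessian of that gradient (the same Hessian enters the
# Laplace determinant).
.subject_laplace <- function(subj, theta, eta_idx, omega_k, sigma3,
                             eta_start, control,
                             cold = all(eta_start == 0)) {
  k <- length(eta_idx)
  sig <- sigma3[subj$dvid]
  y <- subj$dv
  m <- length(y)
  cache <- new.env(parent = emptyenv())
  cache$eta <- NULL
  pred <- function(eta) {
    if (!is.null(cache$eta) && identical(eta, cache$eta)) return(cache$f)
    p <- theta
    p[eta_idx] <- p[eta_idx] * exp(eta)
    f <- .subject_f(p, subj)
    cache$eta <- eta; cache$f <- f
    f
  }
  dev_of_f <- function(f) {
    if (any(!is.finite(f)) || any(f <= 0)) return(1e10)
    sum(((y - f) / (sig * f))^2 + 2 * log(sig * f)) + m * log(2 * pi)
  }
  if (k == 0)
    return(list(value = dev_of_f(pred(numeric(0))), eta = numeric(0)))

  inv_om2 <- 1 / omega_k^2
  logdetO <- 2 * sum(log(omega_k))
  prior_const <- k * log(2 * pi) + logdetO
  h <- function(eta) {
    v <- dev_of_f(pred(eta))
    v + sum(eta^2 * inv_om2) + prior_const
  }
  jstep <- 1e-4
  central <- !identical(control$fd, "forward")
  jac <- function(eta, f0) {
    J <- matrix(0, m, k)
    p0 <- theta
    p0[eta_idx] <- p0[eta_idx] * exp(eta)
    for (j in seq_len(k)) {
      pj <- p0
      pj[eta_idx[j]] <- pj[eta_idx[j]] * exp(jstep)
      fp <- .subject_f(pj, subj)
      if (central) {
        pj[eta_idx[j]] <- p0[eta_idx[j]] * exp(-jstep)
        J[, j] <- (fp - .subject_f(pj, subj)) / (2 * jstep)
      } else {
        J[, j] <- (fp - f0) / jstep
      }
    }
    J
  }
  grad_of <- function(eta, f) {
    if (any(!is.finite(f)) || any(f <= 0)) return(rep(0, k))
    r <- y - f
    dtdf <- -2 * r / (sig^2 * f^2) - 2 * r^2 / (sig^2 * f^3) + 2 / f
    out <- drop(crossprod(jac(eta, f), dtdf)) + 2 * eta * inv_om2
    if (any(!is.finite(out))) return(rep(0, k))
    out
  }
  g <- function(eta) grad_of(eta, pred(eta))
  gn_parts <- function(eta, f) {
    # gradient and Gauss-Newton Hessian of h from one prediction Jacobian
    J <- jac(eta, f)
    r <- y - f
    dtdf <- -2 * r / (sig^2 * f^2) - 2 * r^2 / (sig^2 * f^3) + 2 / f
    w2 <- 2 / (sig^2 * f^2) + 8 * r / (sig^2 * f^3) +
      6 * r^2 / (sig^2 * f^4) - 2 / f^2
    list(g = drop(crossprod(J, dtdf)) + 2 * eta * inv_om2,
         H = crossprod(J, w2 * J) + diag(2 * inv_om2, k))
  }
  solve_mode_newton <- function(start) {
    eta <- start
    fval <- h(eta)
    if (fval >= 1e10) { eta <- numeric(k); fval <- h(eta) }
    for (it in seq_len(control$inner_maxit)) {
      f <- pred(eta)
      if (any(!is.finite(f)) || any(f <= 0)) break
      parts <- gn_parts(eta, f)
      if (any(!is.finite(parts$g)) || any(!is.finite(parts$H))) break
      if (sqrt(sum(parts$g^2)) < control$inner_gtol) break
      ev <- eigen(parts$H, symmetric = TRUE, only.values = TRUE)$values
      ridge <- max(abs(ev)) * 1e-10 + if (min(ev) < 1e-8) abs(min(ev)) + 1e-6 else 0
      H <- parts$H + diag(ridge, k)
      step <- tryCatch(solve(H, parts$g), error = function(e) NULL)
      if (is.null(step))
        step <- tryCatch(solve(H + diag(0.01 * max(abs(ev)), k), parts$g),
                         error = function(e) parts$g / sqrt(sum(parts$g^2)))
      improved <- FALSE
      t <- 1
      for (ls in 1:8) {
        cand <- eta - t * step
        fc <- h(cand)
        if (fc < fval - 1e-12) {
          gain <- fval - fc
          eta <- cand; fval <- fc; improved <- TRUE
          break
        }
        t <- t / 2
      }
      if (!improved || gain < 1e-6 * (abs(fval) + 1)) break
    }
    gn <- g(eta)
    list(par = eta, value = fval, gnorm = sqrt(sum(gn^2)))
  }
  solve_bfgs <- function(start) {
    stats::optim(start, h, g, method = "BFGS",
                 control = list(maxit = control$inner_maxit,
                                reltol = control$inner_reltol))
  }
  solve_mode <- function(start) {
    if (!identical(control$inner_hessian, "gn")) return(solve_bfgs(start))
    res <- solve_mode_newton(start)
    # far from the basin the Gauss-Newton direction can stall; hand the
    # stragglers to BFGS and keep the better mode
    if (res$gnorm > 1) {
      alt <- solve_bfgs(res$par)
      if (alt$value < res$value) res <- alt
    }
    res
  }
  opt <- solve_mode(eta_start)
  # with large omegas the penalised deviance can be multimodal; on a cold
  # start (all-zero eta) probe a deterministic set of omega-scaled starting
  # points (subject-keyed linear-congruential normal draws, independent of
  # the global RNG stream) and keep the best mode
  if (cold && control$inner_starts > 0) {
    state <- (sum(subj$dvid) * 2654435761 + length(subj$dv)) %% 2147483647
    for (r in seq_len(control$inner_starts)) {
      z <- numeric(k)
      for (j in seq_len(k)) {
        state <- (1103515245 * state + 12345) %% 2147483648
        z[j] <- stats::qnorm((state + 0.5) / 2147483648)
      }
      alt <- solve_mode(0.8 * omega_k * z)
      if (alt$value < opt$value - 1e-9) opt <- alt
    }
  }
  eta_hat <- opt$par
  # Hessian of h at the mode, then Newton-polish with it. Two variants:
  # "fd" differentiates the gradient (exact up to FD error); "gn" is the
  # Gauss-Newton form assembled from one prediction Jacobian (drops the
  # second-derivative-of-prediction terms; cheaper and smooth in theta)
  g0 <- g(eta_hat)
  if (identical(control$inner_hessian, "gn")) {
    f0 <- pred(eta_hat)
    if (any(!is.finite(f0)) || any(f0 <= 0)) {
      H <- diag(2 * inv_om2, k)
    } else {
      J <- jac(eta_hat, f0)
      r <- y - f0
      w2 <- 2 / (sig^2 * f0^2) + 8 * r / (sig^2 * f0^3) +
        6 * r^2 / (sig^2 * f0^4) - 2 / f0^2
      H <- crossprod(J, w2 * J) + diag(2 * inv_om2, k)
    }
  } else {
    hstep <- 1e-4
    H <- matrix(0, k, k)
    for (j in seq_len(k)) {
      e <- eta_hat; e[j] <- e[j] + hstep
      H[, j] <- (g(e) - g0) / hstep
    }
  }
  H <- (H + t(H)) / 2
  if (any(!is.finite(H))) H <- diag(2 * inv_om2, k)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (all(ev > 0) && sqrt(sum(g0^2)) > control$inner_gtol) {
    step <- solve(H, g0)
    cand <- eta_hat - step
    if (h(cand) <= opt$value + 1e-9) eta_hat <- cand
  }
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) H <- H + diag(abs(min(ev)) + 1e-8, k)
  ld <- determinant(H / 2, logarithm = TRUE)$modulus
  list(value = h(eta_hat) - k * log(2 * pi) + as.numeric(ld), eta = eta_hat)
}

.resolve_sigma3 <- function(sigma) unname(sigma[c("iri", "sn38", "sn38g")])

# deterministic cyclic parabolic line search on the log-offset scale:
# per sweep, each coordinate is probed on a fixed 5-point stencil and
# refined by a parabola through the best bracket; stencils shrink by half
# every sweep. Robust to the small history-dependence of the objective
# because decisions rest on OFV differences across wide brackets.
.cyclic_search <- function(objective, par0, control) {
  par <- par0
  f_cur <- objective(par)
  width <- 0.25
  for (sweep in seq_len(control$cyclic_sweeps)) {
    for (j in seq_along(par)) {
      offs <- c(-width, width)
      cand <- c(par[j] + offs, par[j])
      vals <- c(vapply(offs, function(d) {
        p <- par; p[j] <- p[j] + d; objective(p)
      }, 0), f_cur)
      # expand while the minimum sits on the stencil edge, so the search
      # can travel arbitrarily far along a descending coordinate
      for (ext in 1:12) {
        i_min <- which.min(vals)
        at_edge <- cand[i_min] >= max(cand) - 1e-12 ||
          cand[i_min] <= min(cand) + 1e-12
        if (!at_edge) break
        dirn <- if (cand[i_min] >= max(cand) - 1e-12) 1 else -1
        xnew <- cand[i_min] + dirn * width
        p <- par; p[j] <- xnew
        vnew <- objective(p)
        cand <- c(cand, xnew); vals <- c(vals, vnew)
        if (vnew >= vals[i_min]) break
      }
      ord <- order(cand)
      cand <- cand[ord]; vals <- vals[ord]
      i <- which.min(vals)
      best <- cand[i]; fbest <- vals[i]
      if (i > 1 && i < length(cand)) {
        # parabola through the bracketing triple
        x <- cand[(i - 1):(i + 1)]; y <- vals[(i - 1):(i + 1)]
        den <- (x[2] - x[1]) * (y[2] - y[3]) - (x[2] - x[3]) * (y[2] - y[1])
        if (is.finite(den) && abs(den) > 1e-12) {
          xv <- x[2] - 0.5 * ((x[2] - x[1])^2 * (y[2] - y[3]) -
                              (x[2] - x[3])^2 * (y[2] - y[1])) / den
          if (xv > x[1] && xv < x[3]) {
            p <- par; p[j] <- xv
            fv <- objective(p)
            if (fv < fbest) { best <- xv; fbest <- fv }
          }
        }
      }
      par[j] <- best
      f_cur <- fbest
    }
    width <- width / 2
  }
  list(par = par, value = f_cur, convergence = 0L,
       counts = c(`function` = NA, gradient = NA))
}

#' Objective function value of the mixed-effects model
#'
#' Computes the Laplace-approximated `-2 log` marginal likelihood (OFV,
#' including all `2*pi` constants) of a trial dataset under given fixed
#' effects, between-subject variability and residual error. Random effects
#' enter for the parameters named in `eta_on`; parameters with zero omega
#' are dropped from the integral. With no random effects the OFV reduces to
#' the fixed-effects weighted least-squares deviance.
#'
#' @param data a `trial_dataset` (data frame) with at least one evaluable
#'   observation per subject; pre-dose records (`MDV = 1`) are excluded.
#' @param params typical values, a [fixed_effects()] object.
#' @param variability a [variability_spec()] object.
#' @param eta_on names of parameters carrying random effects; default all
#'   parameters with positive omega.
#' @param control list of numerical settings, see [np_fit()].
#' @return The OFV (numeric scalar).
#' @export
np_neg2ll <- function(data, params, variability, eta_on = NULL,
                      control = list()) {
  control <- .fit_control(control)
  validate_fixed_effects(params)
  stopifnot(inherits(variability, "variability_spec"))
  subjects <- .parse_dataset(data)
  if (any(vapply(subjects, function(s) length(s$dv), 0L) == 0))
    stop("every subject needs at least one evaluable observation")
  if (is.null(eta_on))
    eta_on <- names(variability$omega)[variability$omega > 0]
  eta_names <- eta_on[variability$omega[eta_on] > 0]
  eta_idx <- match(eta_names, .structural_names)
  sigma3 <- .resolve_sigma3(variability$sigma)
  theta <- unclass(params)
  total <- 0
  for (s in subjects) {
    total <- total + .subject_laplace(
      s, theta, eta_idx, variability$omega[eta_names], sigma3,
      numeric(length(eta_names)), control)$value
  }
  total
}

#' Fit the NP/S population model by Laplace maximum likelihood
#'
#' Maximises the Laplace-approximated marginal likelihood of a long-format
#' trial dataset over a chosen set of free fixed effects (and optionally
#' omegas and sigmas), holding everything else fixed -- in particular the
#' literature parameters of dissolved irinotecan (`V3`, `V4`, `V5`, `Q2`,
#' `Q3` and their BSVs), which is what lets total-concentration data be
#' deconvoluted into NP and S contributions. Free parameters are optimised
#' on the log scale, so positivity holds by construction; the inner
#' per-subject mode search is a quasi-Newton iteration started from the
#' previous outer iteration's mode (zero initially).
#'
#' @param data a `trial_dataset` data frame (see [simulate_trial()],
#'   [read_trial_dataset()]).
#' @param start starting / fixed values, a [fixed_effects()] object.
#' @param variability a [variability_spec()] object (values for free omegas
#'   and sigmas are starting values).
#' @param free character vector of free structural parameters.
#' @param free_omega,free_sigma names of omegas (parameter names) and
#'   sigmas (`"iri"`, `"sn38"`, `"sn38g"`) to estimate; default none.
#' @param eta_on names of parameters whose random effects enter the
#'   marginal likelihood. Default: the parameters whose BSV the final model
#'   estimated (`CL1`, `V1`, `V2`, `K68`, `CL2`, `CL3`, `V10`), i.e. the
#'   literature-fixed BSVs of the S-irinotecan block are left out of the
#'   integral, which keeps the per-subject mode search seven-dimensional.
#'   Set to `names(variability$omega)[variability$omega > 0]` for the full
#'   random-effects model.
#' @param control list: `outer_reltol`, `outer_maxit` (Nelder-Mead),
#'   `inner_reltol`, `inner_maxit` (BFGS mode search), `diagnostics`
#'   (compute gradient norm and information-matrix condition number),
#'   `trace`.
#' @return An object of class `np_fit`; see [coef.np_fit()],
#'   [summary.np_fit()], [predict.np_fit()], [empirical_bayes()].
#' @examples
#' \donttest{
#' ds <- simulate_trial(default_design(), fixed_effects(),
#'                      variability_spec(), seed = 7)
#' fit <- np_fit(ds, free = c("K68", "CL2"),
#'               eta_on = c("K68", "CL2"),
#'               control = list(diagnostics = FALSE))
#' coef(fit)
#' }
#' @export
np_fit <- function(data, start = fixed_effects(),
                   variability = variability_spec(),
                   free = c("K68", "CL2", "V1"),
                   free_omega = character(), free_sigma = character(),
                   eta_on = NULL, control = list()) {
  control <- .fit_control(control)
  validate_fixed_effects(start)
  stopifnot(inherits(variability, "variability_spec"))
  if (length(bad <- setdiff(free, .structural_names)))
    stop("free parameters must be structural: ", paste(bad, collapse = ", "))
  if (length(bad <- setdiff(free_omega, .structural_names)))
    stop("unknown free omega: ", paste(bad, collapse = ", "))
  if (length(bad <- setdiff(free_sigma, c("iri", "sn38", "sn38g"))))
    stop("unknown free sigma: ", paste(bad, collapse = ", "))
  fixed_lit <- c("V3", "V4", "V5", "Q2", "Q3")
  if (length(hit <- intersect(free, fixed_lit)))
    warning("freeing literature-fixed parameter(s): ",
            paste(hit, collapse = ", "))
  subjects <- .parse_dataset(data)
  n_obs <- sum(vapply(subjects, function(s) length(s$dv), 0L))
  if (any(vapply(subjects, function(s) length(s$dv), 0L) == 0))
    stop("every subject needs at least one evaluable observation")
  if (is.null(eta_on))
    eta_on <- setdiff(names(variability$omega)[variability$omega > 0],
                      fixed_lit)
  n_free <- length(free) + length(free_omega) + length(free_sigma)
  if (n_free > n_obs)
    warning("more free parameters than observations; fit is not identifiable")

  theta0 <- unclass(start)
  omega0 <- variability$omega
  sigma0 <- variability$sigma
  if (any(omega0[free_omega] <= 0))
    stop("free omegas need positive starting values")
  if (any(sigma0[free_sigma] <= 0))
    stop("free sigmas need positive starting values")

  warm <- new.env(parent = emptyenv())
  warm$eta <- NULL

  # free parameters are optimised as log-offsets from their starting
  # values: every coordinate starts at 0 on a comparable (relative) scale,
  # which keeps the Nelder-Mead initial simplex balanced
  unpack <- function(par) {
    i <- 0L
    theta <- theta0
    if (length(free)) { theta[free] <- theta0[free] * exp(par[i + seq_along(free)]); i <- i + length(free) }
    omega <- omega0
    if (length(free_omega)) { omega[free_omega] <- omega0[free_omega] * exp(par[i + seq_along(free_omega)]); i <- i + length(free_omega) }
    sigma <- sigma0
    if (length(free_sigma)) sigma[free_sigma] <- sigma0[free_sigma] * exp(par[i + seq_along(free_sigma)])
    list(theta = theta, omega = omega, sigma = sigma)
  }

  objective <- function(par) {
    pp <- unpack(par)
    eta_names <- eta_on[pp$omega[eta_on] > 0]
    eta_idx <- match(eta_names, .structural_names)
    k <- length(eta_names)
    cold <- is.null(warm$eta) || ncol(warm$eta) != k
    if (cold) warm$eta <- matrix(0, length(subjects), max(k, 1L))
    sigma3 <- .resolve_sigma3(pp$sigma)
    total <- 0
    for (i in seq_along(subjects)) {
      res <- .subject_laplace(subjects[[i]], pp$theta, eta_idx,
                              pp$omega[eta_names], sigma3,
                              if (k) warm$eta[i, seq_len(k)] else numeric(0),
                              control, cold = cold)
      if (k) warm$eta[i, seq_len(k)] <- res$eta
      total <- total + res$value
    }
    if (control$trace > 0)
      cat(sprintf("OFV %.4f at ratio (%s)\n", total,
                  paste(signif(exp(par), 5), collapse = ", ")))
    total
  }

  par0 <- numeric(n_free)
  # one cold pass (with multistart mode probing) initialises the
  # per-subject modes; afterwards every evaluation the outer optimiser
  # sees is warm-started and mutually consistent
  objective(par0)
  if (n_free == 0) {
    ofv <- objective(numeric(0))
    opt <- list(par = numeric(0), value = ofv, convergence = 0L,
                message = "no free parameters")
  } else if (identical(control$outer_method, "cyclic") && n_free >= 1) {
    opt <- .cyclic_search(objective, par0, control)
  } else if (n_free == 1) {
    opt <- stats::optim(par0, objective, method = "Brent",
                        lower = par0 - 5, upper = par0 + 5,
                        control = list(maxit = control$outer_maxit))
  } else {
    # Nelder-Mead with restarts: a fresh simplex from the incumbent best
    # recovers from premature collapse (the warm-started inner modes make
    # the objective slightly history-dependent)
    opt <- stats::optim(par0, objective, method = "Nelder-Mead",
                        control = list(maxit = control$outer_maxit,
                                       reltol = control$outer_reltol))
    for (r in seq_len(control$outer_restarts)) {
      if (opt$convergence == 0) break
      opt2 <- stats::optim(opt$par, objective, method = "Nelder-Mead",
                           control = list(maxit = control$outer_maxit,
                                          reltol = control$outer_reltol))
      if (opt2$value <= opt$value) opt <- opt2 else break
    }
  }
  if (!is.null(opt$convergence) && opt$convergence != 0)
    warning("outer optimisation did not converge (code ", opt$convergence,
            "); inspect grad_norm and refit from the returned estimates")

  # final pass at the optimum: refresh modes, collect EBEs
  final <- unpack(opt$par)
  eta_names <- eta_on[final$omega[eta_on] > 0]
  eta_idx <- match(eta_names, .structural_names)
  k <- length(eta_names)
  sigma3 <- .resolve_sigma3(final$sigma)
  eta <- matrix(0, length(subjects), k,
                dimnames = list(names(subjects), eta_names))
  ofv <- 0
  for (i in seq_along(subjects)) {
    res <- .subject_laplace(subjects[[i]], final$theta, eta_idx,
                            final$omega[eta_names], sigma3,
                            if (k) warm$eta[i, seq_len(k)] else numeric(0),
                            control, cold = FALSE)
    if (k) eta[i, ] <- res$eta
    ofv <- ofv + res$value
  }

  grad_norm <- NA_real_
  info_condition <- NA_real_
  if (control$diagnostics && n_free > 0) {
    gr <- vapply(seq_len(n_free), function(j) {
      hstep <- 1e-4
      e <- numeric(n_free); e[j] <- hstep
      (objective(opt$par + e) - objective(opt$par - e)) / (2 * hstep)
    }, 0)
    grad_norm <- sqrt(sum(gr^2))
    info <- try(stats::optimHess(opt$par, objective), silent = TRUE)
    if (!inherits(info, "try-error")) {
      ev <- eigen((info + t(info)) / 2, symmetric = TRUE,
                  only.values = TRUE)$values
      info_condition <- if (min(ev) > 0) max(ev) / min(ev) else Inf
    }
  }

  shrinkage <- if (k && nrow(eta) > 1) {
    1 - apply(eta, 2, stats::sd) / final$omega[eta_names]
  } else stats::setNames(numeric(0), character(0))

  est <- c(final$theta[free],
           if (length(free_omega)) stats::setNames(final$omega[free_omega],
                                                   paste0("omega_", free_omega)),
           if (length(free_sigma)) stats::setNames(final$sigma[free_sigma],
                                                   paste0("sigma_", free_sigma)))

  structure(list(coefficients = est,
                 theta = structure(final$theta, class = "fixed_effects"),
                 omega = final$omega, sigma = final$sigma,
                 ofv = ofv, eta = eta, eta_names = eta_names,
                 shrinkage = shrinkage,
                 convergence = opt$convergence, grad_norm = grad_norm,
                 info_condition = info_condition,
                 free = list(theta = free, omega = free_omega,
                             sigma = free_sigma),
                 start = start, variability_start = variability,
                 subjects = subjects, data = as.data.frame(data),
                 n_obs = n_obs, n_subjects = length(subjects),
                 control = control),
            class = "np_fit")
}

# realized individual parameters at the empirical-Bayes mode
.ebe_params <- function(fit, i) {
  p <- unclass(fit$theta)
  if (length(fit$eta_names))
    p[fit$eta_names] <- p[fit$eta_names] * exp(fit$eta[i, ])
  structure(p, class = "fixed_effects")
}

#' Empirical-Bayes estimates and individual form-specific curves
#'
#' Returns the posterior-mode random effects of one subject together with
#' the resulting nanoparticle- and dissolved-form concentration curves --
#' the deconvolution deliverable: per-subject NP/S profiles inferred from
#' total-concentration data.
#'
#' @param fit an [np_fit()] object.
#' @param subject subject index (position) or ID.
#' @param times prediction grid (h); default a dense grid over the
#'   observation span.
#' @return List with `eta` (named vector), `params` (realized
#'   [fixed_effects()]), and `curves` (data frame: time, the five form
#'   concentrations, and analyte totals).
#' @export
empirical_bayes <- function(fit, subject = 1, times = NULL) {
  stopifnot(inherits(fit, "np_fit"))
  i <- if (is.character(subject)) match(subject, names(fit$subjects))
       else subject
  if (is.na(i) || i < 1 || i > length(fit$subjects))
    stop("unknown subject: ", subject)
  s <- fit$subjects[[i]]
  if (is.null(times))
    times <- sort(unique(c(seq(0, max(s$ut), length.out = 400), s$ut,
                           s$dosing$t0 + s$dosing$dur)))
  p <- .ebe_params(fit, i)
  C <- .predict_conc(p, s$dosing, times)
  curves <- data.frame(time = times, t(C),
                       total_iri = C["np_iri", ] + C["s_iri", ],
                       total_sn38 = C["np_sn38", ] + C["s_sn38", ],
                       total_sn38g = C["sn38g", ])
  eta <- if (length(fit$eta_names))
    stats::setNames(as.numeric(fit$eta[i, ]), fit$eta_names)
  else numeric(0)
  list(eta = eta, params = p, curves = curves)
}

#' Likelihood-ratio comparison of nested fits
#'
#' The conventional gate for adding one parameter is a drop in OFV of at
#' least 3.84 (chi-square, 1 df, p < 0.05).
#'
#' @param fit_reduced,fit_full nested [np_fit()] objects (the full model
#'   has more free parameters).
#' @param df degrees of freedom; default the difference in free-parameter
#'   counts.
#' @return List with `delta_ofv`, `df`, `critical` (the 5% chi-square
#'   cutoff), `p_value`, `significant`.
#' @export
ofv_test <- function(fit_reduced, fit_full, df = NULL) {
  stopifnot(inherits(fit_reduced, "np_fit"), inherits(fit_full, "np_fit"))
  n_red <- length(fit_reduced$coefficients)
  n_full <- length(fit_full$coefficients)
  if (is.null(df)) df <- n_full - n_red
  if (df < 1) stop("full model must have more free parameters")
  delta <- fit_reduced$ofv - fit_full$ofv
  crit <- stats::qchisq(0.95, df)
  list(delta_ofv = delta, df = df, critical = crit,
       p_value = stats::pchisq(max(delta, 0), df, lower.tail = FALSE),
       significant = delta >= crit)
}
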