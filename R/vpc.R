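# ---- visual predictive check ------------------------------------------------

#' Visual predictive check by replicate trial simulation
#'
#' Simulates `n_rep` replicates of the trial design and summarises the
#' simulated observations per dose level (cohort), analyte and nominal
#' sampling time as the median and the 90% prediction interval (5th and
#' 95th percentiles, linear-interpolation quantiles, `stats::quantile`
#' type 7). Simulated and nominal times coincide, so no time binning is
#' needed; cohorts of one subject still get bands, which then reflect
#' prediction uncertainty only.
#'
#' @param design a [trial_design()] object.
#' @param params typical values, a [fixed_effects()] object.
#' @param variability a [variability_spec()] object.
#' @param n_rep number of replicate trials (>= 1); the reported bands use
#'   the pooled simulated observations of each bin across replicates.
#' @param seed optional integer seed; same seed, same bands.
#' @param obs optional observed `trial_dataset` to attach for overlay and
#'   coverage computation.
#' @return An object of class `np_vpc`: a data frame with columns
#'   `cohort`, `dose_iri`, `dose_sn38`, `analyte`, `time`, `p5`, `p50`,
#'   `p95`, with the observed data (if given) as attribute `"obs"`.
#' @examples
#' v <- np_vpc(default_design(), fixed_effects(), variability_spec(),
#'             n_rep = 20, seed = 1)
#' head(as.data.frame(v))
#' @export
np_vpc <- function(design, params, variability, n_rep = 1000, seed = NULL,
                   obs = NULL) {
  stopifnot(inherits(design, "trial_design"))
  if (nrow(design$cohorts) == 0) stop("empty design")
  if (n_rep < 1) stop("n_rep must be >= 1")
  analytes <- c("iri", "sn38", "sn38g")
  .with_seed(seed, {
    sims <- lapply(seq_len(n_rep), function(r) {
      ds <- simulate_trial(design, params, variability)
      ds[ds$EVID == 0 & ds$MDV == 0, c("COHORT", "DVID", "TIME", "DV")]
    })
    pool <- do.call(rbind, sims)
    key <- paste(pool$COHORT, pool$DVID, pool$TIME, sep = "|")
    first <- !duplicated(key)
    lev <- key[first]
    qs <- t(vapply(split(pool$DV, factor(key, levels = lev)),
                   stats::quantile, numeric(3),
                   probs = c(0.05, 0.5, 0.95), type = 7, names = FALSE))
    meta <- pool[first, c("COHORT", "DVID", "TIME")]
    out <- data.frame(cohort = meta$COHORT,
                      analyte = analytes[meta$DVID],
                      time = meta$TIME,
                      p5 = qs[, 1], p50 = qs[, 2], p95 = qs[, 3])
    ch <- design$cohorts
    out$dose_iri <- ch$dose_iri[match(out$cohort, ch$cohort)]
    out$dose_sn38 <- ch$dose_sn38[match(out$cohort, ch$cohort)]
    out <- out[order(out$cohort, out$analyte, out$time),
               c("cohort", "dose_iri", "dose_sn38", "analyte", "time",
                 "p5", "p50", "p95")]
    rownames(out) <- NULL
    structure(out, class = c("np_vpc", "data.frame"), obs = obs,
              n_rep = n_rep)
  })
}

#' Fraction of observations inside the VPC 90% band
#'
#' @param vpc an [np_vpc()] result.
#' @param data a `trial_dataset` with the observations to check (defaults
#'   to the dataset attached to the VPC).
#' @return The fraction of evaluable observations lying inside
#'   `[p5, p95]` of their (cohort, analyte, time) bin.
#' @export
vpc_coverage <- function(vpc, data = attr(vpc, "obs")) {
  stopifnot(inherits(vpc, "np_vpc"))
  if (is.null(data)) stop("no observed dataset supplied")
  o <- as.data.frame(data)
  o <- o[o$EVID == 0 & o$MDV == 0, ]
  analytes <- c("iri", "sn38", "sn38g")
  i <- match(paste(o$COHORT, analytes[o$DVID], o$TIME),
             paste(vpc$cohort, vpc$analyte, vpc$time))
  if (any(is.na(i))) stop("observations outside the VPC bins")
  mean(o$DV >= vpc$p5[i] & o$DV <= vpc$p95[i])
}

#' @export
plot.np_vpc <- function(x, cohort = max(x$cohort), log = "y", ...) {
  obs <- attr(x, "obs")
  analytes <- c(iri = "total irinotecan", sn38 = "total SN-38",
                sn38g = "SN-38G")
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  for (a in names(analytes)) {
    b <- x[x$cohort == cohort & x$analyte == a, ]
    ylim <- range(c(b$p5[b$p5 > 0], b$p95), na.rm = TRUE)
    graphics::plot(b$time, pmax(b$p50, ylim[1]), type = "l", log = log,
                   ylim = ylim, xlab = "Time (h)",
                   ylab = "Concentration (ng/mL)", main = analytes[[a]],
                   col = 2, ...)
    graphics::lines(b$time, pmax(b$p5, ylim[1]), lty = 2, col = 4)
    graphics::lines(b$time, pmax(b$p95, ylim[1]), lty = 2, col = 4)
    if (!is.null(obs)) {
      o <- as.data.frame(obs)
      o <- o[o$EVID == 0 & o$MDV == 0 & o$COHORT == cohort &
               o$DVID == match(a, names(analytes)) & o$DV > 0, ]
      graphics::points(o$TIME, o$DV, pch = 16, cex = 0.6)
    }
  }
  invisible(x)
}

#' Write VPC bands to CSV
#'
#' @param vpc an [np_vpc()] result.
#' @param path output file.
#' @export
write_vpc <- function(vpc, path) {
  utils::write.csv(as.data.frame(vpc), path, row.names = FALSE)
  invisible(path)
}
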