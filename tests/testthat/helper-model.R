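# shared fixtures and independent oracles for the test suite

typical_params <- function() fixed_effects()

regimen_5080 <- function() dose_regimen(80, 50)

# printed exposure grid (Cmax / AUC0-336 per form, by dose level) used as
# the reference in the acceptance checks; dose pairs are SN-38:irinotecan
reference_exposure_table <- function() {
  m <- rbind(
    c(10,  16, 0.73,  1.10,  168.72,  861.98,  164.95,  404.73,  23.53,  98.68),
    c(20,  32, 1.46,  2.19,  337.45, 1723.97,  329.91,  809.46,  47.06, 197.37),
    c(30,  48, 2.19,  3.29,  506.17, 2585.95,  494.86, 1214.20,  70.59, 296.05),
    c(40,  64, 2.92,  4.38,  674.88, 3447.92,  659.82, 1618.94,  94.12, 394.73),
    c(50,  80, 3.65,  5.48,  843.62, 4309.93,  824.79, 2023.68, 117.65, 493.42),
    c(60,  96, 4.38,  6.58, 1012.35, 5171.90,  989.75, 2428.45, 141.19, 592.10),
    c(70, 112, 5.11,  7.67, 1181.09, 6033.90, 1154.68, 2833.14, 164.71, 690.78),
    c(80, 128, 5.84,  8.77, 1349.82, 6895.87, 1319.64, 3237.85, 188.24, 789.46),
    c(90, 144, 6.56,  9.86, 1518.49, 7757.87, 1484.61, 3642.60, 211.77, 888.15),
    c(100, 160, 7.29, 10.96, 1687.23, 8619.83, 1649.53, 4047.32, 235.31, 986.83))
  colnames(m) <- c("dose_sn38", "dose_iri",
                   "cmax_np_iri", "auc_np_iri", "cmax_s_iri", "auc_s_iri",
                   "cmax_np_sn38", "auc_np_sn38", "cmax_s_sn38", "auc_s_sn38")
  as.data.frame(m)
}

# bi-exponential closed form: concentration in the central compartment of a
# two-compartment model during a constant-rate infusion (standard result,
# evaluated independently of the package's matrix-exponential solver)
two_cpt_infusion_conc <- function(t, R, V1, k10, k12, k21) {
  b <- k10 + k12 + k21
  l1 <- (b + sqrt(b^2 - 4 * k10 * k21)) / 2
  l2 <- (b - sqrt(b^2 - 4 * k10 * k21)) / 2
  # partial fractions of R/V1 * (s+k21)/(s (s+l1) (s+l2)):
  # C(t) = (R/V1) [ A1 (1-exp(-l1 t)) + A2 (1-exp(-l2 t)) ]
  A1 <- (k21 - l1) / (l1 * (l2 - l1))
  A2 <- (k21 - l2) / (l2 * (l1 - l2))
  (R / V1) * (A1 * (1 - exp(-l1 * t)) + A2 * (1 - exp(-l2 * t)))
}

# tiny two-cohort design for fast estimation tests
mini_design <- function(n = c(2, 2)) {
  trial_design(cohorts = data.frame(n = n, dose_iri = c(48, 80),
                                    dose_sn38 = c(30, 50)),
               times = c(0, 0.5, 1, 2, 4, 8, 12, 24, 48, 96, 169.5))
}

# Gauss-Hermite nodes/weights by the Golub-Welsch eigen decomposition of
# the Jacobi matrix (physicists' convention: weight exp(-x^2))
gauss_hermite <- function(n) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(1:(n - 1), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}
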