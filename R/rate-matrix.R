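.cpt_names <- c("np_iri_c", "np_iri_p", "s_iri_c", "s_iri_p1", "s_iri_p2",
                "np_sn38_c", "np_sn38_p", "s_sn38_c", "s_sn38_p",
                "sn38g_c", "sn38g_p")

.form_names <- c("np_iri", "s_iri", "np_sn38", "s_sn38", "sn38g")

# central compartment index and volume name for each observed analyte form
.form_central <- c(np_iri = 1L, s_iri = 3L, np_sn38 = 6L, s_sn38 = 8L,
                   sn38g = 10L)
.form_volume <- c(np_iri = "V1", s_iri = "V3", np_sn38 = "V1", s_sn38 = "V8",
                  sn38g = "V10")

#' Compartment layout of the 11-compartment NP/S model
#'
#' @param params a [fixed_effects()] object supplying the volumes.
#' @return A data frame with one row per compartment: index, name, analyte
#'   form, and volume (L).
#' @export
compartment_layout <- function(params = fixed_effects()) {
  validate_fixed_effects(params)
  data.frame(
    index = 1:11,
    name = .cpt_names,
    form = c("np_iri", "np_iri", "s_iri", "s_iri", "s_iri", "np_sn38",
             "np_sn38", "s_sn38", "s_sn38", "sn38g", "sn38g"),
    volume = unname(params[c("V1", "V2", "V3", "V4", "V5", "V1", "V2",
                             "V8", "V9", "V10", "V9")])
  )
}

#' First-order rate matrix of the NP/S split model
#'
#' Builds the 11 x 11 matrix `M` of the linear system `dA/dt = M A + u(t)`
#' on amounts (mg). All processes are first order. NP-irinotecan and
#' NP-SN-38 are eliminated solely by release into their dissolved central
#' compartments (`K13`, `K68`). S-irinotecan leaves its central compartment
#' at rate `CL1/V3`; a molar fraction `fmet` of that flux re-enters the
#' system as S-SN-38 mass (scaled by `mw_sn38/mw_iri`), the remainder
#' leaves the system. S-SN-38 is eliminated exclusively by glucuronidation
#' (`CL2`) into SN-38G, transferred 1:1 on a mass basis; SN-38G is cleared
#' by `CL3`. Intercompartmental exchange is symmetric in concentration
#' (`Q/V` on each side).
#'
#' @param params a [fixed_effects()] object.
#' @return An 11 x 11 numeric matrix with compartment dimnames.
#' @examples
#' M <- rate_matrix(fixed_effects())
#' M[1, 1]   # -(K13 + Q1/V1)
#' @export
rate_matrix <- function(params = fixed_effects()) {
  validate_fixed_effects(params)
  .rate_matrix_num(params)
}

# hot-path variant without validation; params is a named numeric vector
.rate_matrix_num <- function(params) {
  p <- as.list(unclass(params))
  M <- matrix(0, 11, 11, dimnames = list(.cpt_names, .cpt_names))
  # NP-irinotecan (1 central, 2 peripheral)
  M[1, 1] <- -(p$K13 + p$Q1 / p$V1); M[1, 2] <- p$Q1 / p$V2
  M[2, 1] <- p$Q1 / p$V1;            M[2, 2] <- -p$Q1 / p$V2
  M[3, 1] <- p$K13                   # release enters S-iri central
  # S-irinotecan (3 central, 4 rapid, 5 slow); CL1 flux leaves cpt 3
  M[3, 3] <- -(p$CL1 + p$Q2 + p$Q3) / p$V3
  M[3, 4] <- p$Q2 / p$V4;            M[3, 5] <- p$Q3 / p$V5
  M[4, 3] <- p$Q2 / p$V3;            M[4, 4] <- -p$Q2 / p$V4
  M[5, 3] <- p$Q3 / p$V3;            M[5, 5] <- -p$Q3 / p$V5
  # NP-SN-38 (6 central, 7 peripheral): shared NP disposition V1/V2/Q1
  M[6, 6] <- -(p$K68 + p$Q1 / p$V1); M[6, 7] <- p$Q1 / p$V2
  M[7, 6] <- p$Q1 / p$V1;            M[7, 7] <- -p$Q1 / p$V2
  M[8, 6] <- p$K68                   # release enters S-SN-38 central
  # molar conversion of S-irinotecan to S-SN-38 within central cpts
  M[8, 3] <- p$fmet * (p$mw_sn38 / p$mw_iri) * p$CL1 / p$V3
  # S-SN-38 (8 central, 9 peripheral); elimination = glucuronidation only
  M[8, 8] <- -(p$CL2 + p$Q5) / p$V8; M[8, 9] <- p$Q5 / p$V9
  M[9, 8] <- p$Q5 / p$V8;            M[9, 9] <- -p$Q5 / p$V9
  # SN-38G (10 central, 11 peripheral); fed 1:1 (mass) by CL2 flux
  M[10, 8] <- p$CL2 / p$V8
  M[10, 10] <- -(p$CL3 + p$Q6) / p$V10; M[10, 11] <- p$Q6 / p$V9
  M[11, 10] <- p$Q6 / p$V10;            M[11, 11] <- -p$Q6 / p$V9
  M
}

# hot-path rate matrix: p must be in the canonical fixed_effects() order
# (CL1, V1, V2, Q1, K13, V3, V4, V5, Q2, Q3, K68, V8, V9, Q5, CL2, CL3,
#  Q6, V10, fnp_iri, fnp_sn38, fmet, mw_iri, mw_sn38); no validation, no
# dimnames -- used inside estimation and trial-simulation loops
.rate_matrix_fast <- function(p) {
  CL1 <- p[[1L]]; V1 <- p[[2L]]; V2 <- p[[3L]]; Q1 <- p[[4L]]; K13 <- p[[5L]]
  V3 <- p[[6L]]; V4 <- p[[7L]]; V5 <- p[[8L]]; Q2 <- p[[9L]]; Q3 <- p[[10L]]
  K68 <- p[[11L]]; V8 <- p[[12L]]; V9 <- p[[13L]]; Q5 <- p[[14L]]
  CL2 <- p[[15L]]; CL3 <- p[[16L]]; Q6 <- p[[17L]]; V10 <- p[[18L]]
  fmet <- p[[21L]]; mwr <- p[[23L]] / p[[22L]]
  M <- matrix(0, 11, 11)
  q1c <- Q1 / V1; q1p <- Q1 / V2
  M[1L] <- -(K13 + q1c); M[12L] <- q1p
  M[2L] <- q1c; M[13L] <- -q1p
  M[3L] <- K13
  M[25L] <- -(CL1 + Q2 + Q3) / V3; M[36L] <- Q2 / V4; M[47L] <- Q3 / V5
  M[26L] <- Q2 / V3; M[37L] <- -Q2 / V4
  M[27L] <- Q3 / V3; M[49L] <- -Q3 / V5
  M[61L] <- -(K68 + q1c); M[72L] <- q1p
  M[62L] <- q1c; M[73L] <- -q1p
  M[63L] <- K68
  M[30L] <- fmet * mwr * CL1 / V3
  M[85L] <- -(CL2 + Q5) / V8; M[96L] <- Q5 / V9
  M[86L] <- Q5 / V8; M[97L] <- -Q5 / V9
  M[87L] <- CL2 / V8
  M[109L] <- -(CL3 + Q6) / V10; M[120L] <- Q6 / V9
  M[110L] <- Q6 / V10; M[121L] <- -Q6 / V9
  M
}

# zero-order infusion rate vector (mg/h) implied by a regimen: the dose of
# each drug is split between NP and S central compartments
infusion_rates <- function(params, regimen) {
  u <- numeric(11)
  dur <- regimen$infusion_duration
  u[1] <- params[["fnp_iri"]] * regimen$dose_iri / dur
  u[3] <- (1 - params[["fnp_iri"]]) * regimen$dose_iri / dur
  u[6] <- params[["fnp_sn38"]] * regimen$dose_sn38 / dur
  u[8] <- (1 - params[["fnp_sn38"]]) * regimen$dose_sn38 / dur
  u
}
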