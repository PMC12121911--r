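# Independently coded CBS core (the 9-species cascade without DLC1).
#
# This implementation is deliberately written out long-hand, separate
# from `cbsd_rhs()`, so it can serve two roles: (i) the generator of the
# reference trajectories that the calibration dataset is built from, and
# (ii) an independent oracle for the reduction invariant (CBSD with all
# DLC1 edges zeroed must match it).

#' Species of the CBS core model
#' @return Character vector of the nine CBS-core species names.
#' @export
cbs_species <- function() {
  c("snail1_mRNA", "SNAIL1", "miR34", "zeb1_mRNA", "ZEB1", "miR200",
    "Ecad", "Ncad", "TGFb_auto")
}

#' CBS-core parameters implied by a CBSD parameter set
#'
#' Drops the DLC1 extension; `ks1` is the full TGFbeta-driven snail1
#' transcription rate of the core.
#'
#' @param params CBSD parameter vector; defaults to [cbsd_params()].
#' @return Named numeric vector of core parameters.
#' @export
cbs_core_params <- function(params = cbsd_params()) {
  drop <- c("ks2", "J2s", "n2s", "k0_d", "kd1", "J1d", "n1d",
            "kd2", "J2d", "n2d", "kd_dm", "kD_tl", "kd_D")
  params[setdiff(names(params), drop)]
}

#' CBS-core ODE right-hand side (independent implementation)
#'
#' @param state Named vector over [cbs_species()].
#' @param p Core parameter vector from [cbs_core_params()].
#' @param TGF0 Exogenous TGFbeta dose (ng/ml).
#' @return Named derivative vector (µM/h).
#' @export
cbs_rhs <- function(state, p, TGF0 = 0) {
  st <- pmax(state, 0)
  Tt <- st[["TGFb_auto"]] + p[["tgf_unit_scale"]] * TGF0
  S <- st[["SNAIL1"]]; Z <- st[["ZEB1"]]
  ds <- p[["k0_s"]] +
    p[["ks1"]] * Tt^p[["n1s"]] / (p[["J1s"]]^p[["n1s"]] + Tt^p[["n1s"]]) -
    p[["kd_s"]] * st[["snail1_mRNA"]]
  dS <- p[["kS_tl"]] * st[["snail1_mRNA"]] *
    p[["JS_34"]]^p[["nS_34"]] /
    (p[["JS_34"]]^p[["nS_34"]] + st[["miR34"]]^p[["nS_34"]]) -
    p[["kd_S"]] * S
  dR3 <- p[["k0_3"]] +
    p[["k3"]] / (1 + (S / p[["J1_3"]])^p[["n1_3"]] +
                   (Z / p[["J2_3"]])^p[["n2_3"]]) -
    p[["kd_3"]] * st[["miR34"]]
  dz <- p[["k0_z"]] +
    p[["kz"]] * S^p[["nz"]] / (p[["Jz"]]^p[["nz"]] + S^p[["nz"]]) -
    p[["kd_z"]] * st[["zeb1_mRNA"]]
  dZ <- p[["kZ_tl"]] * st[["zeb1_mRNA"]] *
    p[["JZ_200"]]^p[["nZ_200"]] /
    (p[["JZ_200"]]^p[["nZ_200"]] + st[["miR200"]]^p[["nZ_200"]]) -
    p[["kd_Z"]] * Z
  dR2 <- p[["k0_2"]] +
    p[["k2"]] / (1 + (S / p[["J1_2"]])^p[["n1_2"]] +
                   (Z / p[["J2_2"]])^p[["n2_2"]]) -
    p[["kd_2"]] * st[["miR200"]]
  dE <- p[["kE1"]] * p[["J1E"]]^p[["n1E"]] /
    (p[["J1E"]]^p[["n1E"]] + S^p[["n1E"]]) +
    p[["kE2"]] * p[["J2E"]]^p[["n2E"]] /
    (p[["J2E"]]^p[["n2E"]] + Z^p[["n2E"]]) -
    p[["kd_E"]] * st[["Ecad"]]
  dN <- p[["kN1"]] * S^p[["n1N"]] / (p[["J1N"]]^p[["n1N"]] + S^p[["n1N"]]) +
    p[["kN2"]] * Z^p[["n2N"]] / (p[["J2N"]]^p[["n2N"]] + Z^p[["n2N"]]) -
    p[["kd_N"]] * st[["Ncad"]]
  dT <- p[["k0_T"]] +
    p[["kT"]] * p[["JT"]]^p[["nT"]] /
    (p[["JT"]]^p[["nT"]] + st[["miR200"]]^p[["nT"]]) -
    p[["kd_T"]] * st[["TGFb_auto"]]
  c(snail1_mRNA = unname(ds), SNAIL1 = unname(dS), miR34 = unname(dR3),
    zeb1_mRNA = unname(dz), ZEB1 = unname(dZ), miR200 = unname(dR2),
    Ecad = unname(dE), Ncad = unname(dN), TGFb_auto = unname(dT))
}

#' Simulate the CBS core
#'
#' Equilibrates the core without exogenous TGFbeta and then applies the
#' dose, mirroring the equilibrate-then-stimulate protocol, using the
#' same stiff integrator contract as the CBSD simulator.
#'
#' @param p Core parameters from [cbs_core_params()].
#' @param TGF0 Dose (ng/ml) applied after equilibration.
#' @param t_grid Output time grid (h) for the stimulated phase.
#' @param equil_duration Equilibration time at TGF0 = 0 (h).
#' @return Matrix `time x (1 + species)` as returned by deSolve.
#' @export
cbs_simulate <- function(p, TGF0, t_grid, equil_duration = 100) {
  f <- function(t, y, parms, dose) list(cbs_rhs(y, p, dose))
  y0 <- stats::setNames(numeric(9), cbs_species())
  y0["Ecad"] <- (p[["kE1"]] + p[["kE2"]]) / p[["kd_E"]]
  y0["miR34"] <- (p[["k0_3"]] + p[["k3"]]) / p[["kd_3"]]
  y0["miR200"] <- (p[["k0_2"]] + p[["k2"]]) / p[["kd_2"]]
  eq <- deSolve::lsoda(y0, c(0, equil_duration), f, dose = 0,
                       rtol = 1e-8, atol = 1e-10)
  y1 <- pmax(eq[nrow(eq), -1], 0)
  deSolve::lsoda(y1, t_grid, f, dose = TGF0, rtol = 1e-8, atol = 1e-10)
}
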