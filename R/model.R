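# ODE right-hand side and explicit reaction network of the CBSD model.
#
# The same rate laws are written twice on purpose: `cbsd_rhs()` is the
# hand-optimised derivative used by the integrators, and
# `build_reaction_network()` lists every elementary process (each
# transcription source term, translation and degradation separately) for
# the stochastic simulator. A consistency test asserts that the
# stoichiometry-weighted sum of reaction rates reproduces the ODE.

# total TGFbeta signal (µM): autocrine pool plus unit-converted dose
total_tgf <- function(state, params, cond) {
  unname(state["TGFb_auto"] + params["tgf_unit_scale"] * cond$TGF0)
}

# multiplicative knockdown factor on dlc1 transcription: a constant
# fraction k_knockdown of dlc1 transcripts is removed by the stable
# knockdown, independent of the dlc1 level
knockdown_factor <- function(params, cond) {
  if (isTRUE(cond$knockdown)) 1 - cond$k_knockdown else 1
}

#' CBSD ODE right-hand side
#'
#' Time derivatives (µM/h) of the eleven CBSD species under a given
#' parameter set and condition. The CBS core follows the cascading
#' bistable switch wiring: TGFbeta activates snail1 transcription;
#' miR-34 represses SNAIL1 translation and is repressed by SNAIL1 and
#' ZEB1 (first switch); SNAIL1 activates zeb1 transcription; miR-200
#' represses ZEB1 translation and autocrine TGFbeta production and is
#' repressed by SNAIL1 and ZEB1 (second switch, locked in by the
#' autocrine loop); SNAIL1 and ZEB1 repress E-cad and activate N-cad
#' production. The DLC1 arm adds TGFbeta- and ZEB1-activated dlc1
#' transcription (scaled by `1 - k_knockdown` under knockdown) and an
#' additive DLC1-activated term on the snail1 promoter.
#'
#' @param state Named state vector from [cbsd_state()].
#' @param params Parameter vector from [cbsd_params()].
#' @param cond Condition from [cbsd_condition()].
#' @return Named numeric vector of derivatives (µM/h).
#' @export
cbsd_rhs <- function(state, params, cond) {
  if (any(state < -1e-6)) stop("negative species concentration")
  state <- pmax(state, 0)
  p <- params
  s  <- state[["snail1_mRNA"]]; S  <- state[["SNAIL1"]]
  R3 <- state[["miR34"]];       z  <- state[["zeb1_mRNA"]]
  Z  <- state[["ZEB1"]];        R2 <- state[["miR200"]]
  E  <- state[["Ecad"]];        N  <- state[["Ncad"]]
  Tt <- total_tgf(state, p, cond)
  d  <- state[["dlc1_mRNA"]];   D  <- state[["DLC1"]]

  ha <- function(x, J, n) { xn <- (x / J)^n; xn / (1 + xn) }
  hr <- function(x, J, n) 1 / (1 + (x / J)^n)

  kd_fac <- knockdown_factor(p, cond)
  d_prod <- kd_fac * (p[["k0_d"]] +
                        p[["kd1"]] * ha(Tt, p[["J1d"]], p[["n1d"]]) +
                        p[["kd2"]] * ha(Z,  p[["J2d"]], p[["n2d"]]))

  c(snail1_mRNA = p[["k0_s"]] +
      p[["ks1"]] * ha(Tt, p[["J1s"]], p[["n1s"]]) +
      p[["ks2"]] * ha(D,  p[["J2s"]], p[["n2s"]]) -
      p[["kd_s"]] * s,
    SNAIL1 = p[["kS_tl"]] * s * hr(R3, p[["JS_34"]], p[["nS_34"]]) -
      p[["kd_S"]] * S,
    miR34 = p[["k0_3"]] +
      p[["k3"]] * hill_repression2(S, p[["J1_3"]], p[["n1_3"]],
                                   Z, p[["J2_3"]], p[["n2_3"]]) -
      p[["kd_3"]] * R3,
    zeb1_mRNA = p[["k0_z"]] +
      p[["kz"]] * ha(S, p[["Jz"]], p[["nz"]]) -
      p[["kd_z"]] * z,
    ZEB1 = p[["kZ_tl"]] * z * hr(R2, p[["JZ_200"]], p[["nZ_200"]]) -
      p[["kd_Z"]] * Z,
    miR200 = p[["k0_2"]] +
      p[["k2"]] * hill_repression2(S, p[["J1_2"]], p[["n1_2"]],
                                   Z, p[["J2_2"]], p[["n2_2"]]) -
      p[["kd_2"]] * R2,
    Ecad = p[["kE1"]] * hr(S, p[["J1E"]], p[["n1E"]]) +
      p[["kE2"]] * hr(Z, p[["J2E"]], p[["n2E"]]) -
      p[["kd_E"]] * E,
    Ncad = p[["kN1"]] * ha(S, p[["J1N"]], p[["n1N"]]) +
      p[["kN2"]] * ha(Z, p[["J2N"]], p[["n2N"]]) -
      p[["kd_N"]] * N,
    TGFb_auto = p[["k0_T"]] +
      p[["kT"]] * hr(R2, p[["JT"]], p[["nT"]]) -
      p[["kd_T"]] * state[["TGFb_auto"]],
    dlc1_mRNA = d_prod - p[["kd_dm"]] * d,
    DLC1 = p[["kD_tl"]] * d - p[["kd_D"]] * D)
}

#' Explicit reaction network of the CBSD model
#'
#' Decomposes the CBSD dynamics into elementary processes, one reaction
#' per additive source term plus one first-order degradation per
#' species. Each reaction carries a human-readable name, a stoichiometry
#' change vector and a rate-law function of the (concentration) state;
#' the stochastic module converts these rate laws into propensities.
#'
#' @inheritParams cbsd_rhs
#' @return Object of class `cbsd_network`: list with `species` and
#'   `reactions` (each reaction a list of `name`, `stoich`, `rate`).
#' @export
build_reaction_network <- function(params, cond) {
  validate_params(params)
  p <- params
  sp <- cbsd_species()
  ha <- function(x, J, n) { xn <- (x / J)^n; xn / (1 + xn) }
  hr <- function(x, J, n) 1 / (1 + (x / J)^n)
  kd_fac <- knockdown_factor(p, cond)

  unit <- function(name) { v <- stats::setNames(numeric(length(sp)), sp); v[name] <- 1; v }
  rx <- function(name, species, sign, rate) {
    list(name = name, stoich = sign * unit(species), rate = rate)
  }
  Tt <- function(st) st[["TGFb_auto"]] + p[["tgf_unit_scale"]] * cond$TGF0

  reactions <- list(
    rx("snail1_transcription_basal", "snail1_mRNA", 1,
       function(st) p[["k0_s"]]),
    rx("snail1_transcription_tgf", "snail1_mRNA", 1,
       function(st) p[["ks1"]] * ha(Tt(st), p[["J1s"]], p[["n1s"]])),
    rx("snail1_transcription_dlc1", "snail1_mRNA", 1,
       function(st) p[["ks2"]] * ha(st[["DLC1"]], p[["J2s"]], p[["n2s"]])),
    rx("snail1_degradation", "snail1_mRNA", -1,
       function(st) p[["kd_s"]] * st[["snail1_mRNA"]]),
    rx("SNAIL1_translation", "SNAIL1", 1,
       function(st) p[["kS_tl"]] * st[["snail1_mRNA"]] *
         hr(st[["miR34"]], p[["JS_34"]], p[["nS_34"]])),
    rx("SNAIL1_degradation", "SNAIL1", -1,
       function(st) p[["kd_S"]] * st[["SNAIL1"]]),
    rx("miR34_production_basal", "miR34", 1,
       function(st) p[["k0_3"]]),
    rx("miR34_production_regulated", "miR34", 1,
       function(st) p[["k3"]] *
         hill_repression2(st[["SNAIL1"]], p[["J1_3"]], p[["n1_3"]],
                          st[["ZEB1"]], p[["J2_3"]], p[["n2_3"]])),
    rx("miR34_degradation", "miR34", -1,
       function(st) p[["kd_3"]] * st[["miR34"]]),
    rx("zeb1_transcription_basal", "zeb1_mRNA", 1,
       function(st) p[["k0_z"]]),
    rx("zeb1_transcription_snail1", "zeb1_mRNA", 1,
       function(st) p[["kz"]] * ha(st[["SNAIL1"]], p[["Jz"]], p[["nz"]])),
    rx("zeb1_degradation", "zeb1_mRNA", -1,
       function(st) p[["kd_z"]] * st[["zeb1_mRNA"]]),
    rx("ZEB1_translation", "ZEB1", 1,
       function(st) p[["kZ_tl"]] * st[["zeb1_mRNA"]] *
         hr(st[["miR200"]], p[["JZ_200"]], p[["nZ_200"]])),
    rx("ZEB1_degradation", "ZEB1", -1,
       function(st) p[["kd_Z"]] * st[["ZEB1"]]),
    rx("miR200_production_basal", "miR200", 1,
       function(st) p[["k0_2"]]),
    rx("miR200_production_regulated", "miR200", 1,
       function(st) p[["k2"]] *
         hill_repression2(st[["SNAIL1"]], p[["J1_2"]], p[["n1_2"]],
                          st[["ZEB1"]], p[["J2_2"]], p[["n2_2"]])),
    rx("miR200_degradation", "miR200", -1,
       function(st) p[["kd_2"]] * st[["miR200"]]),
    rx("Ecad_production_snail1_gate", "Ecad", 1,
       function(st) p[["kE1"]] * hr(st[["SNAIL1"]], p[["J1E"]], p[["n1E"]])),
    rx("Ecad_production_zeb1_gate", "Ecad", 1,
       function(st) p[["kE2"]] * hr(st[["ZEB1"]], p[["J2E"]], p[["n2E"]])),
    rx("Ecad_degradation", "Ecad", -1,
       function(st) p[["kd_E"]] * st[["Ecad"]]),
    rx("Ncad_production_snail1", "Ncad", 1,
       function(st) p[["kN1"]] * ha(st[["SNAIL1"]], p[["J1N"]], p[["n1N"]])),
    rx("Ncad_production_zeb1", "Ncad", 1,
       function(st) p[["kN2"]] * ha(st[["ZEB1"]], p[["J2N"]], p[["n2N"]])),
    rx("Ncad_degradation", "Ncad", -1,
       function(st) p[["kd_N"]] * st[["Ncad"]]),
    rx("TGFb_auto_production_basal", "TGFb_auto", 1,
       function(st) p[["k0_T"]]),
    rx("TGFb_auto_production_regulated", "TGFb_auto", 1,
       function(st) p[["kT"]] * hr(st[["miR200"]], p[["JT"]], p[["nT"]])),
    rx("TGFb_auto_turnover", "TGFb_auto", -1,
       function(st) p[["kd_T"]] * st[["TGFb_auto"]]),
    rx("dlc1_transcription_basal", "dlc1_mRNA", 1,
       function(st) kd_fac * p[["k0_d"]]),
    rx("dlc1_transcription_tgf", "dlc1_mRNA", 1,
       function(st) kd_fac * p[["kd1"]] * ha(Tt(st), p[["J1d"]], p[["n1d"]])),
    rx("dlc1_transcription_zeb1", "dlc1_mRNA", 1,
       function(st) kd_fac * p[["kd2"]] * ha(st[["ZEB1"]], p[["J2d"]], p[["n2d"]])),
    rx("dlc1_degradation", "dlc1_mRNA", -1,
       function(st) p[["kd_dm"]] * st[["dlc1_mRNA"]]),
    rx("DLC1_translation", "DLC1", 1,
       function(st) p[["kD_tl"]] * st[["dlc1_mRNA"]]),
    rx("DLC1_degradation", "DLC1", -1,
       function(st) p[["kd_D"]] * st[["DLC1"]])
  )
  structure(list(species = sp, reactions = reactions,
                 params = params, condition = cond),
            class = "cbsd_network")
}

#' Sum reaction rates into per-species net rates
#'
#' @param network A `cbsd_network` from [build_reaction_network()].
#' @param state Named concentration state.
#' @return Named numeric vector; equals [cbsd_rhs()] for the same inputs.
#' @export
network_rhs <- function(network, state) {
  out <- stats::setNames(numeric(length(network$species)), network$species)
  for (r in network$reactions) out <- out + r$stoich * r$rate(state)
  out
}
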