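# Species and parameter bookkeeping for the CBSD network.
#
# The CBSD model couples the cascading-bistable-switch (CBS) EMT core --
# the SNAIL1/miR-34 and ZEB1/miR-200 double-negative feedback switches
# driven by total (exogenous + autocrine) TGFbeta, with E-cadherin and
# N-cadherin readouts -- to a DLC1 arm: dlc1 mRNA is transcribed from a
# basal promoter, a TGFbeta-activated promoter (standing in for MAPK
# signalling downstream of the receptor) and a ZEB1-activated promoter;
# DLC1 protein feeds back by activating snail1 transcription.

#' Species names of the CBSD model
#'
#' Eleven species: the nine CBS-core species followed by the two DLC1
#' extension species. Concentrations are in µM, time in model hours.
#'
#' @return Character vector of species names in canonical order.
#' @export
cbsd_species <- function() {
  c("snail1_mRNA", "SNAIL1", "miR34", "zeb1_mRNA", "ZEB1", "miR200",
    "Ecad", "Ncad", "TGFb_auto", "dlc1_mRNA", "DLC1")
}

#' Construct a CBSD species state
#'
#' @param ... Named species concentrations (µM) overriding zeros.
#' @param values Optional named numeric vector used instead of `...`.
#' @return Named numeric vector over [cbsd_species()].
#' @export
cbsd_state <- function(..., values = NULL) {
  st <- stats::setNames(numeric(length(cbsd_species())), cbsd_species())
  ov <- if (is.null(values)) c(...) else values
  if (length(ov)) {
    bad <- setdiff(names(ov), names(st))
    if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
    st[names(ov)] <- ov
  }
  if (any(st < 0)) stop("species concentrations must be non-negative")
  st
}

#' Default CBSD parameter set
#'
#' Returns the full kinetic parameter vector: the CBS-core constants
#' (reconstructed so that the core shows the cascading bistable EMT
#' structure: reversible E/P switch, irreversible P/M switch locked in by
#' autocrine TGFbeta) and the DLC1-extension constants at their
#' calibrated maximum-likelihood values (see the calibration module and
#' the analysis scripts).
#'
#' Units: rates in µM/h (transcription) or 1/h (translation,
#' degradation), thresholds `J*` in µM, Hill coefficients `n*`
#' dimensionless, `tgf_unit_scale` in µM per ng/ml.
#'
#' @param ... Named overrides of individual parameters.
#' @return Named numeric parameter vector.
#' @export
cbsd_params <- function(...) {
  p <- c(
    ## --- CBS core: snail1 mRNA / SNAIL1 / miR-34 switch -------------
    k0_s  = 5e-4,   # basal snail1 transcription (µM/h)
    ks1   = 0.0047,  # TGFbeta-driven snail1 transcription (µM/h)
    J1s   = 5,      # TGFbeta threshold on snail1 promoter (µM)
    n1s   = 2,
    kd_s  = 0.1,    # snail1 mRNA degradation (1/h)
    kS_tl = 1.5,    # SNAIL1 translation (1/h)
    JS_34 = 0.0685,   # miR-34 threshold repressing SNAIL1 translation (µM)
    nS_34 = 2,
    kd_S  = 0.15,   # SNAIL1 degradation (1/h)
    k0_3  = 1e-3,   # basal miR-34 production (µM/h)
    k3    = 0.03,   # regulated miR-34 production (µM/h)
    J1_3  = 0.128,   # SNAIL1 threshold repressing miR-34 (µM)
    n1_3  = 2,
    J2_3  = 0.5,    # ZEB1 threshold repressing miR-34 (µM)
    n2_3  = 2,
    kd_3  = 0.1,    # miR-34 degradation (1/h)
    ## --- CBS core: zeb1 mRNA / ZEB1 / miR-200 switch -----------------
    k0_z  = 3e-4,   # basal zeb1 transcription (µM/h)
    kz    = 0.02,   # SNAIL1-driven zeb1 transcription (µM/h)
    Jz    = 1.2,    # SNAIL1 threshold on zeb1 promoter (µM)
    nz    = 2,
    kd_z  = 0.1,    # zeb1 mRNA degradation (1/h)
    kZ_tl = 1.5,    # ZEB1 translation (1/h)
    JZ_200 = 0.06,  # miR-200 threshold repressing ZEB1 translation (µM)
    nZ_200 = 2,
    kd_Z  = 0.15,   # ZEB1 degradation (1/h)
    k0_2  = 1e-3,   # basal miR-200 production (µM/h)
    k2    = 0.03,   # regulated miR-200 production (µM/h)
    J1_2  = 5,    # SNAIL1 threshold repressing miR-200 (µM)
    n1_2  = 2,
    J2_2  = 0.2,    # ZEB1 threshold repressing miR-200 (µM)
    n2_2  = 2,
    kd_2  = 0.1,    # miR-200 degradation (1/h)
    ## --- CBS core: autocrine TGFbeta ---------------------------------
    k0_T  = 0.001,   # basal autocrine TGFbeta production (µM/h)
    kT    = 0.6,    # regulated autocrine TGFbeta production (µM/h)
    JT    = 0.1,    # miR-200 threshold repressing autocrine TGFbeta (µM)
    nT    = 2,
    kd_T  = 0.1,    # autocrine TGFbeta turnover (1/h)
    ## --- CBS core: cadherin readouts ---------------------------------
    kE1   = 0.15,   # E-cad production repressed by SNAIL1 (µM/h)
    J1E   = 0.3,
    n1E   = 2,
    kE2   = 0.15,   # E-cad production repressed by ZEB1 (µM/h)
    J2E   = 0.4,
    n2E   = 2,
    kd_E  = 0.1,    # E-cad turnover (1/h)
    kN1   = 0.05,   # N-cad production activated by SNAIL1 (µM/h)
    J1N   = 0.3,
    n1N   = 2,
    kN2   = 0.25,   # N-cad production activated by ZEB1 (µM/h)
    J2N   = 0.4,
    n2N   = 2,
    kd_N  = 0.1,    # N-cad turnover (1/h)
    ## --- input conversion --------------------------------------------
    tgf_unit_scale = 2,  # µM TGFbeta signal per ng/ml exogenous dose
    ## --- DLC1 extension ----------------------------------------------
    ks2   = 4.6,    # DLC1-driven snail1 transcription (µM/h)
    J2s   = 2.09,   # DLC1 threshold on snail1 promoter (µM)
    n2s   = 6,
    k0_d  = 1.2e-3,  # basal dlc1 transcription (µM/h)
    kd1   = 0.1913, # TGFbeta-driven dlc1 transcription (µM/h)
    J1d   = 2.5,    # TGFbeta threshold on dlc1 promoter (µM)
    n1d   = 4,
    kd2   = 1.367e-4, # ZEB1-driven dlc1 transcription (µM/h)
    J2d   = 0.06,   # ZEB1 threshold on dlc1 promoter (µM)
    n2d   = 2,
    kd_dm = 0.4,    # dlc1 mRNA degradation (1/h)
    kD_tl = 3,      # DLC1 translation (1/h)
    kd_D  = 1.5     # DLC1 protein degradation (1/h)
  )
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  validate_params(p)
  p
}

validate_params <- function(p) {
  hills <- grepl("^n", names(p))
  thr <- grepl("^J", names(p)) | names(p) == "tgf_unit_scale"
  if (any(!is.finite(p))) stop("parameters must be finite")
  if (any(p[thr] <= 0)) stop("thresholds must be positive")
  if (any(p[!hills] < 0)) stop("rate constants must be non-negative")
  if (any(p[hills] < 1)) stop("Hill coefficients must be >= 1")
  invisible(p)
}

#' Construct an experimental condition
#'
#' @param TGF0 Exogenous TGFbeta dose (ng/ml), non-negative.
#' @param knockdown Logical; is the stable dlc1 knockdown active?
#' @param k_knockdown Fraction of dlc1 transcription removed by the
#'   knockdown, in `[0, 1]`. Ignored when `knockdown` is `FALSE`.
#' @return A list of class `cbsd_condition`.
#' @export
cbsd_condition <- function(TGF0 = 0, knockdown = FALSE, k_knockdown = 0) {
  stopifnot(is.numeric(TGF0), length(TGF0) == 1, TGF0 >= 0,
            is.logical(knockdown), length(knockdown) == 1)
  if (k_knockdown < 0 || k_knockdown > 1) {
    stop("k_knockdown must lie in [0, 1]")
  }
  structure(list(TGF0 = TGF0, knockdown = knockdown,
                 k_knockdown = k_knockdown),
            class = "cbsd_condition")
}

#' @export
print.cbsd_condition <- function(x, ...) {
  cat(sprintf("CBSD condition: TGF0 = %g ng/ml, knockdown = %s%s\n",
              x$TGF0, x$knockdown,
              if (x$knockdown) sprintf(" (k_knockdown = %g)", x$k_knockdown)
              else ""))
  invisible(x)
}

#' Maximum-likelihood knockdown fraction
#'
#' The calibrated estimate of the stable dlc1 knockdown strength (the
#' fraction of dlc1 transcription removed), produced by the calibration
#' workflow from the knockdown fold-change data.
#'
#' @return Numeric scalar in (0, 1).
#' @export
ml_knockdown_fraction <- function() 0.547

#' Names of the estimated DLC1-extension parameters
#'
#' The kinetic parameters of the DLC1 arm that the calibration module
#' estimates (the knockdown fraction is estimated too but lives in the
#' condition).
#'
#' @return Character vector of parameter names.
#' @export
dlc1_free_parameters <- function() {
  c("ks1", "J1s", "ks2", "J2s", "k0_d", "kd1", "J1d", "kd2", "J2d",
    "kd_dm", "kD_tl", "kd_D")
}
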