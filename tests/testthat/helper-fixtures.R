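# shared fixtures; expensive objects are computed once per test run

ml_params <- cbsd_params()

ctrl <- function(dose = 0) cbsd_condition(TGF0 = dose)
kd_ml <- function(dose = 10) cbsd_condition(dose, TRUE, ml_knockdown_fraction())

# cached epithelial equilibrium and mesenchymal state at the ML set
.fix <- new.env()
fix_eqE <- function() {
  if (is.null(.fix$eqE)) {
    .fix$eqE <- suppressWarnings(equilibrate(ml_params, duration = 2000))
  }
  .fix$eqE
}
fix_M <- function() {
  if (is.null(.fix$M)) {
    .fix$M <- cbsd:::phenotype_fixed_point(ml_params, ctrl(10), "M")
  }
  .fix$M
}
fix_thresholds <- function() {
  if (is.null(.fix$th)) .fix$th <- phenotype_thresholds(ml_params)
  .fix$th
}

# a mid/partial-like seed used to probe partial-state attractors
partial_seed <- function() {
  cbsd_state(snail1_mRNA = 0.06, SNAIL1 = 0.6, miR34 = 0.03,
             zeb1_mRNA = 0.005, ZEB1 = 0.02, miR200 = 0.28,
             Ecad = 1.5, Ncad = 0.45, TGFb_auto = 0.7,
             dlc1_mRNA = 0.2, DLC1 = 0.4)
}

random_state <- function() {
  cbsd_state(values = stats::setNames(stats::runif(11, 0, 3),
                                      cbsd_species()))
}

# forward-simulate a dataset's records under given parameters,
# mirroring the observable mapping of the likelihood (species
# concentrations plus the dlc1/snail1 ratio observable)
simulate_dataset_values <- function(params, k_knockdown, ds) {
  sims <- cbsd:::simulate_conditions(params, k_knockdown, ds)
  out <- ds$value
  for (cid in names(sims)) {
    sel <- ds$condition == cid
    tr <- sims[[cid]]
    idx <- match(ds$time[sel], tr$time)
    sp <- ds$observable[sel]
    isr <- sp == "dlc1_snail1_ratio"
    v <- numeric(sum(sel))
    v[!isr] <- tr$state[cbind(idx[!isr],
                              match(sp[!isr], colnames(tr$state)))]
    v[isr] <- tr$state[idx[isr], "dlc1_mRNA"] /
      tr$state[idx[isr], "snail1_mRNA"]
    out[sel] <- v
  }
  out
}
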