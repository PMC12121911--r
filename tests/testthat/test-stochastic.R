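# Propensity conversion, direct-method correctness, population
# summaries.

test_that("rate laws convert to propensities with the Omega scaling", {
  net <- build_reaction_network(ml_params, kd_ml())
  # degradation with zero count has zero propensity
  cnt0 <- as_counts(cbsd_state(), 500)
  a0 <- to_propensities(net, cnt0)
  deg <- grepl("degradation|turnover", vapply(net$reactions, `[[`, "",
                                              "name"))
  expect_true(all(a0[deg] == 0))
  # zeroth-order: k = 0.1 µM/h at Omega = 500 -> 50 events/h
  p <- cbsd_params(k0_s = 0.1)
  netb <- build_reaction_network(p, ctrl(0))
  ab <- to_propensities(netb, cnt0)
  nm <- vapply(netb$reactions, `[[`, "", "name")
  expect_equal(ab[[which(nm == "snail1_transcription_basal")]], 50)
  # propensity / Omega converges to the concentration rate law
  st <- random_state()
  rhs_ref <- cbsd_rhs(st, ml_params, kd_ml())
  for (om in c(1e4, 1e6)) {
    a <- to_propensities(net, as_counts(st, om))
    stoich <- t(vapply(net$reactions, function(r) r$stoich, numeric(11)))
    drift <- colSums(stoich * a) / om
    expect_equal(unname(drift), unname(rhs_ref),
                 tolerance = if (om == 1e4) 0.05 else 5e-3)
  }
})

test_that("compiled and R direct methods produce identical trajectories", {
  cnt <- as_counts(fix_M(), 300)
  tg <- seq(0, 1.5, length.out = 7)
  a <- ssa_run(ml_params, kd_ml(10), cnt, tg, seed = 5, engine = "r")
  b <- ssa_run(ml_params, kd_ml(10), cnt, tg, seed = 5,
               engine = "compiled")
  expect_identical(unname(a$state), unname(b$state))
  expect_identical(a$n_events, as.numeric(b$n_events))
})

test_that("birth-death stationary mean matches k*Omega/gamma", {
  # reduced network: snail1 mRNA with basal birth and linear death only
  p <- cbsd_params(k0_s = 0.2, kd_s = 0.5,
                   ks1 = 1e-12, ks2 = 1e-12)
  net <- build_reaction_network(p, ctrl(0))
  keep <- vapply(net$reactions, function(r) {
    r$name %in% c("snail1_transcription_basal", "snail1_degradation")
  }, logical(1))
  net$reactions <- net$reactions[keep]
  omega <- 50
  mean_target <- 0.2 * omega / 0.5   # 20 molecules
  tg <- seq(0, 400, by = 1)
  means <- vapply(1:20, function(i) {
    set.seed(100 + i)
    run <- cbsd:::ssa_run_r(p, ctrl(0),
                            as_counts(cbsd_state(snail1_mRNA = 0.4),
                                      omega),
                            tg, network = net)
    mean(run$state[tg > 50, "snail1_mRNA"])
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - mean_target), 3 * se + 1e-9)
})

test_that("zero counts with zero basal rates give an absorbed run", {
  p <- cbsd_params(k0_s = 0, k0_3 = 0, k0_z = 0, k0_2 = 0, k0_T = 0,
                   k0_d = 0, kE1 = 0, kE2 = 0, kN1 = 0, kN2 = 0,
                   kT = 0, ks1 = 0, ks2 = 0, kd1 = 0, kd2 = 0,
                   k3 = 0, k2 = 0)
  run <- ssa_run(p, ctrl(0), as_counts(cbsd_state(), 100),
                 seq(0, 10, 1), seed = 1)
  expect_true(run$absorbed)
  expect_lt(run$n_events, 5)
  expect_true(all(run$state == 0))
})

test_that("population fractions are one-hot for a single cell and sum to 1", {
  pop <- population_fractions(ml_params, ctrl(10), "M", n_cells = 1,
                              t_end = 20, omega = 200, seed = 3,
                              thresholds = fix_thresholds())
  expect_equal(sum(pop$fractions), 1, tolerance = 1e-12)
  expect_setequal(as.numeric(pop$fractions), c(0, 0, 1))
})

test_that("population summaries are reproducible for identical seeds", {
  a <- population_fractions(ml_params, kd_ml(10), "M", n_cells = 4,
                            t_end = 50, omega = 300, seed = 17,
                            thresholds = fix_thresholds())
  b <- population_fractions(ml_params, kd_ml(10), "M", n_cells = 4,
                            t_end = 50, omega = 300, seed = 17,
                            thresholds = fix_thresholds())
  expect_identical(a$fractions, b$fractions)
  expect_identical(a$per_cell$Ncad_window, b$per_cell$Ncad_window)
  expect_error(population_fractions(ml_params, ctrl(0), "Q"),
               "arg")
})

test_that("knockdown cells started in E remain epithelial", {
  eq <- suppressWarnings(equilibrate(ml_params, kd_ml(0),
                                     duration = 2000))
  pop <- population_fractions(ml_params, kd_ml(10), n_cells = 6,
                              t_end = 500, omega = 1000, seed = 9,
                              start_state = eq,
                              thresholds = fix_thresholds())
  expect_equal(pop$fractions[["E"]], 1)
})

test_that("tau-leaping tracks the exact kernel at large system size", {
  tg <- seq(0, 60, by = 10)
  ex <- ssa_run(ml_params, ctrl(0), as_counts(fix_eqE(), 5000), tg,
                seed = 30)
  tl <- ssa_run(ml_params, ctrl(0), as_counts(fix_eqE(), 5000), tg,
                seed = 30, engine = "tau", tau = 0.05)
  # both hover around the epithelial state: compare E-cad levels
  expect_lt(abs(mean(tl$state[, "Ecad"]) - mean(ex$state[, "Ecad"])) /
              mean(ex$state[, "Ecad"]), 0.05)
})
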