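# The network definition: rhs structure, reduction to the CBS core,
# knockdown mechanism, and ODE/reaction-network equivalence.

zero_dlc1 <- function(p = ml_params) {
  p[c("ks2", "kd1", "kd2", "k0_d")] <- 1e-12
  p
}

test_that("with DLC1 edges zeroed the rhs reduces to the CBS core", {
  p <- zero_dlc1(cbsd_params(ks1 = 0.05))
  core <- cbs_core_params(cbsd_params(ks1 = 0.05))
  set.seed(1)
  for (dose in c(0, 1.5, 10)) {
    st <- random_state()
    st[c("dlc1_mRNA", "DLC1")] <- 0
    full <- cbsd_rhs(st, p, ctrl(dose))
    red <- cbs_rhs(st[cbs_species()], core, dose)
    expect_equal(unname(full[cbs_species()]), unname(red),
                 tolerance = 1e-9)
  }
})

test_that("CBS reduction holds along whole trajectories", {
  # simulated CBSD (edges zeroed) against the independently coded core
  p <- zero_dlc1(cbsd_params(ks1 = 0.05))
  core <- cbs_core_params(cbsd_params(ks1 = 0.05))
  tg <- seq(0, 400, by = 20)
  eq <- suppressWarnings(equilibrate(p, duration = 100, tol = Inf))
  tr <- simulate(eq, p, ctrl(10), tg)
  ref <- cbs_simulate(core, 10, tg, equil_duration = 100)
  for (sp in cbs_species()) {
    expect_equal(unname(tr$state[, sp]), unname(ref[, sp]),
                 tolerance = 1e-5)
  }
})

test_that("total knockdown removes dlc1 production entirely", {
  st <- random_state()
  d <- cbsd_rhs(st, ml_params, cbsd_condition(10, TRUE, 1))
  expect_equal(d[["dlc1_mRNA"]],
               -ml_params[["kd_dm"]] * st[["dlc1_mRNA"]])
  # knockdown = FALSE ignores k_knockdown
  d0 <- cbsd_rhs(st, ml_params, cbsd_condition(10, FALSE, 1))
  d1 <- cbsd_rhs(st, ml_params, cbsd_condition(10, FALSE, 0))
  expect_equal(d0, d1)
})

test_that("at the origin all purely-activated species have non-negative rates", {
  d <- cbsd_rhs(cbsd_state(), ml_params, ctrl(0))
  expect_equal(d[["dlc1_mRNA"]], unname(ml_params["k0_d"]))
  expect_true(all(d >= 0))
})

test_that("negative states are rejected", {
  st <- cbsd_state(); st["SNAIL1"] <- -0.5
  expect_error(cbsd_rhs(st, ml_params, ctrl(0)), "negative")
})

test_that("summed reaction rates reproduce the ODE right-hand side", {
  set.seed(42)
  for (i in 1:10) {
    cond <- cbsd_condition(runif(1, 0, 10), i %% 2 == 0, runif(1))
    net <- build_reaction_network(ml_params, cond)
    st <- random_state()
    expect_equal(network_rhs(net, st), cbsd_rhs(st, ml_params, cond),
                 tolerance = 1e-12)
  }
})

test_that("the network decomposes dlc1 transcription into elementary processes", {
  net <- build_reaction_network(ml_params, kd_ml())
  touching <- vapply(net$reactions,
                     function(r) r$stoich[["dlc1_mRNA"]] != 0, logical(1))
  expect_gte(sum(touching), 4)
  # every rate law non-negative at random non-negative states
  set.seed(7)
  for (i in 1:10) {
    st <- random_state()
    rates <- vapply(net$reactions, function(r) r$rate(st), numeric(1))
    expect_true(all(rates >= 0))
  }
})

test_that("trajectories from random non-negative starts stay non-negative", {
  set.seed(99)
  for (i in 1:100) {
    mult <- stats::setNames(exp(runif(length(ml_params), log(0.8),
                                      log(1.25))), names(ml_params))
    mult[grepl("^n", names(ml_params))] <- 1
    p <- validate_params(ml_params * mult)
    tr <- simulate(random_state(), p,
                   cbsd_condition(runif(1, 0, 10), i %% 3 == 0, runif(1)),
                   c(0, 30))
    expect_true(all(tr$state >= 0))
  }
})

test_that("parameter validation enforces positivity and Hill bounds", {
  expect_error(cbsd_params(kd_s = -1), "non-negative")
  expect_error(cbsd_params(J2s = 0), "positive")
  expect_error(cbsd_params(n2s = 0.5), "Hill")
  expect_error(cbsd_params(nonsense = 1), "unknown")
  expect_error(cbsd_condition(k_knockdown = 1.2), "0, 1")
})
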