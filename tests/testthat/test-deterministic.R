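# Equilibrate-then-stimulate protocol, steady states, classification.

test_that("equilibration yields an epithelial steady state", {
  eq <- fix_eqE()
  expect_s3_class(classify_phenotype(eq[["Ncad"]], fix_thresholds()),
                  "factor")
  expect_equal(as.character(classify_phenotype(eq[["Ncad"]],
                                               fix_thresholds())), "E")
  # steady: residual below tolerance
  expect_lt(max(abs(cbsd_rhs(eq, ml_params, ctrl(0)))), 1e-6)
  # idempotent: equilibrating again moves nothing
  eq2 <- suppressWarnings(equilibrate(ml_params, duration = 500,
                                      start = eq))
  expect_equal(eq2, eq, tolerance = 1e-6)
})

test_that("control stimulation shows the two-step E-P-M transition", {
  tg <- seq(0, 1500, by = 5)
  tr <- simulate(fix_eqE(), ml_params, ctrl(10), tg)
  labs <- as.character(classify_phenotype(tr$state[, "Ncad"],
                                          fix_thresholds()))
  # phenotype sequence visits E, then P, then M, in order
  expect_equal(unique(labs), c("E", "P", "M"))
  # the intermediate plateau is visible: P is held for a while
  expect_gt(sum(labs == "P"), 5)
  expect_equal(labs[length(labs)], "M")
})

test_that("knockdown at the ML fraction traps stimulated cells in E", {
  eq <- suppressWarnings(equilibrate(ml_params, kd_ml(), duration = 2000))
  tr <- simulate(eq, ml_params, kd_ml(10), seq(0, 1500, by = 10))
  labs <- classify_phenotype(tr$state[, "Ncad"], fix_thresholds())
  expect_true(all(labs == "E"))
})

test_that("knockdown reverses the mesenchymal state at TGF0 = 0", {
  tr <- simulate(fix_M(), ml_params, cbsd_condition(0, TRUE, ml_knockdown_fraction()),
                 seq(0, 3000, by = 10))
  lab_end <- classify_phenotype(final_state(tr)[["Ncad"]],
                                fix_thresholds())
  expect_equal(as.character(lab_end), "E")
})

test_that("steady-state finder returns verified fixed points", {
  fps <- find_steady_states(ml_params, ctrl(0))
  expect_gt(length(fps), 0)
  for (fp in fps) {
    expect_lt(max(abs(cbsd_rhs(fp$state, ml_params, ctrl(0)))), 1e-8)
  }
  # an epithelial stable state exists at rest
  stable_labs <- vapply(Filter(function(g) g$stable, fps), function(g) {
    as.character(classify_phenotype(g$state[["Ncad"]], fix_thresholds()))
  }, "")
  expect_true("E" %in% stable_labs)
  # a stable mesenchymal fixed point exists under full stimulation
  fps10 <- find_steady_states(ml_params, ctrl(10))
  labs10 <- vapply(Filter(function(g) g$stable, fps10), function(g) {
    as.character(classify_phenotype(g$state[["Ncad"]], fix_thresholds()))
  }, "")
  expect_true("M" %in% labs10)
})

test_that("phenotype classification respects the boundary convention", {
  th <- c(0.3, 1.5)
  expect_equal(as.character(classify_phenotype(0, th)), "E")
  expect_equal(as.character(classify_phenotype(0.3, th)), "P")
  expect_equal(as.character(classify_phenotype(1.5, th)), "M")
  expect_error(classify_phenotype(-0.1, th), "non-negative")
})

test_that("derived thresholds separate the control branches cleanly", {
  th <- fix_thresholds()
  expect_lt(th[1], th[2])
  # representative branch levels from the three attractors
  eq <- fix_eqE(); M <- fix_M()
  P <- final_state(simulate(partial_seed(), ml_params, ctrl(1.25),
                            c(0, 6000)))
  expect_equal(as.character(classify_phenotype(
    c(eq[["Ncad"]], P[["Ncad"]], M[["Ncad"]]), th)), c("E", "P", "M"))
})

test_that("hysteresis: M persists at rest, the E/P switch reverses", {
  # quasi-static downsweep from the mesenchymal state
  st <- fix_M()
  for (dose in c(6, 3, 1, 0)) {
    st <- final_state(simulate(st, ml_params, ctrl(dose), c(0, 2000)))
  }
  expect_equal(as.character(classify_phenotype(st[["Ncad"]],
                                               fix_thresholds())), "M")
  # the partial state collapses back to E when the dose is removed
  P <- final_state(simulate(partial_seed(), ml_params, ctrl(1.25),
                            c(0, 4000)))
  back <- final_state(simulate(P, ml_params, ctrl(0), c(0, 4000)))
  expect_equal(as.character(classify_phenotype(back[["Ncad"]],
                                               fix_thresholds())), "E")
})

test_that("halving integrator tolerances leaves the endpoint unchanged", {
  tg <- c(0, 800)
  a <- simulate(fix_eqE(), ml_params, ctrl(10), tg)
  b <- simulate(fix_eqE(), ml_params, ctrl(10), tg,
                rtol = 5e-9, atol = 5e-11)
  na <- final_state(a)[["Ncad"]]; nb <- final_state(b)[["Ncad"]]
  expect_lt(abs(na - nb) / na, 1e-3)
})

test_that("simulate validates its time grid and reports failures", {
  expect_error(simulate(fix_eqE(), ml_params, ctrl(0), c(3, 2, 1)),
               "increasing")
})
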