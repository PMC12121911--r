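# Parameter-ensemble sampling and deterministic heterogeneity analysis.

test_that("ensemble draws are centred on the ML set and positive", {
  sets <- sample_parameter_sets(ml_params, 10000, cv = 0.2, seed = 21,
                                which = c("kd1", "kd_s"))
  kd1 <- vapply(sets, function(p) p[["kd1"]], numeric(1))
  expect_true(all(kd1 > 0))
  se <- sd(kd1) / sqrt(length(kd1))
  expect_lt(abs(mean(kd1) - ml_params[["kd1"]]), 2 * se)
  expect_equal(sd(kd1) / ml_params[["kd1"]], 0.2, tolerance = 0.05)
  # unvaried parameters keep their ML values
  expect_true(all(vapply(sets, function(p) p[["ks2"]], 1) ==
                    ml_params[["ks2"]]))
})

test_that("a vanishing spread returns the ML set for every cell", {
  sets <- sample_parameter_sets(ml_params, 5, cv = 1e-12, seed = 1)
  for (p in sets) expect_equal(p, ml_params, tolerance = 1e-9)
  expect_error(sample_parameter_sets(ml_params, 5, cv = 0), "cv")
})

test_that("single-cell ensembles reproduce the deterministic phenotypes", {
  ml_only <- list(ml_params)
  attr(ml_only, "seed") <- 0
  # control cell from E under full stimulation transitions to M
  popM <- ensemble_fractions(ml_only, ctrl(10), "E", t_end = 1500,
                             thresholds = fix_thresholds())
  expect_equal(popM$fractions[["M"]], 1)
  # knockdown cell from E stays epithelial
  popE <- ensemble_fractions(ml_only, kd_ml(10), "E", t_end = 1500,
                             thresholds = fix_thresholds())
  expect_equal(popE$fractions[["E"]], 1)
  expect_equal(sum(popE$fractions), 1, tolerance = 1e-12)
})

test_that("knockdown ensembles keep more cells out of the M state", {
  sets <- sample_parameter_sets(ml_params, 12, cv = 0.15, seed = 33)
  ctl <- ensemble_fractions(sets, ctrl(10), "E", t_end = 1200,
                            thresholds = fix_thresholds())
  kd <- ensemble_fractions(sets, kd_ml(10), "E", t_end = 1200,
                           thresholds = fix_thresholds())
  ep_ctl <- ctl$fractions[["E"]] + ctl$fractions[["P"]]
  ep_kd <- kd$fractions[["E"]] + kd$fractions[["P"]]
  expect_gt(ep_kd, ep_ctl)
})

test_that("washout removes the stimulus at the switch time", {
  ml_only <- list(ml_params); attr(ml_only, "seed") <- 0
  # control M cell: washout cannot revert it (irreversible switch)
  wo_ctl <- ensemble_fractions(ml_only, ctrl(10), "M", t_end = 2000,
                               washout = TRUE, washout_time = 700,
                               thresholds = fix_thresholds())
  expect_equal(wo_ctl$fractions[["M"]], 1)
  # knockdown M cell under washout reverts to E
  wo_kd <- ensemble_fractions(ml_only, kd_ml(10), "M", t_end = 4000,
                              washout = TRUE, washout_time = 700,
                              thresholds = fix_thresholds())
  expect_equal(wo_kd$fractions[["E"]], 1)
})
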