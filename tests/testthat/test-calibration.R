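# Dataset construction, likelihood, fitting and sensitivity analysis.

coarse_dataset <- function(...) {
  build_dataset(t_grid = seq(0, 1000, by = 100), ...)
}

test_that("the dataset carries the printed constraints", {
  ds <- coarse_dataset()
  # 14 knockdown dlc1 records, one per listed fitting time point
  kd_d <- ds[ds$condition == "knockdown_10" &
               ds$observable == "dlc1_mRNA", ]
  expect_equal(nrow(kd_d), 14)
  expect_setequal(kd_d$time, c(180, 200, 220, 240, 260, 280, 300, 350,
                               400, 500, 600, 700, 800, 1000))
  # printed dlc1/snail1 ratios enter as ratio observables
  r0 <- ds[ds$observable == "dlc1_snail1_ratio" & ds$time == 0, ]
  expect_equal(r0$value, 0.77)
  r1 <- ds[ds$observable == "dlc1_snail1_ratio" & ds$time >= 800, ]
  expect_true(all(r1$value == 0.99))
  # fold changes of 1 reproduce the control steady values
  ds1 <- coarse_dataset(fc_dlc1_kd = 1, fc_snail1_kd = 1)
  kd_s <- ds1[ds1$condition == "knockdown_10" &
                ds1$observable == "snail1_mRNA", ]
  s_steady <- ds1$value[ds1$observable == "snail1_mRNA" &
                          ds1$condition == "control_10" &
                          ds1$time == 1000][1]
  expect_equal(unique(kd_s$value), s_steady)
  expect_error(build_dataset(fc_dlc1_kd = 0), "0, 1")
})

test_that("the objective is the Gaussian negative log-likelihood", {
  ds <- coarse_dataset()
  # replace the data by an exact model simulation: residuals vanish and
  # the objective equals the sd normalisation term
  ds2 <- ds
  ds2$value <- simulate_dataset_values(ml_params,
                                       ml_knockdown_fraction(), ds)
  o <- objective(ml_params, ds2)
  expect_equal(o, sum(0.5 * log(2 * pi * ds2$sd^2)), tolerance = 1e-6)
  # doubling all sd reduces the quadratic misfit term by 4
  quad <- function(d) objective(ml_params, d) -
    sum(0.5 * log(2 * pi * d$sd^2))
  ds4 <- ds; ds4$sd <- 2 * ds4$sd
  expect_equal(quad(ds4), quad(ds) / 4, tolerance = 1e-6)
  # +30% on an extension parameter strictly increases the exact-data fit
  p_pert <- ml_params; p_pert["kd1"] <- 1.3 * p_pert["kd1"]
  expect_gt(objective(p_pert, ds2), o)
})

test_that("zero-width bounds pin the fit to the given value", {
  ds <- coarse_dataset()
  th0 <- log10(ml_params[["kd1"]])
  fr <- fit(ds, base_params = ml_params, free = "kd1",
            lower = th0, upper = th0, n_starts = 1, pop_size = 4,
            n_gen = 1, seed = 2)
  expect_equal(unname(fr$params[["kd1"]]), unname(ml_params[["kd1"]]))
  expect_equal(fr$objective, objective(ml_params, ds),
               tolerance = 1e-6)
})

test_that("the fit recovers generating parameters from noisy data", {
  # forward-simulate data from known parameters, perturb 5%, refit two
  # identifiable extension parameters
  true_p <- ml_params
  ds <- coarse_dataset()
  set.seed(31)
  mv <- simulate_dataset_values(true_p, ml_knockdown_fraction(), ds)
  ds$value <- mv * exp(rnorm(length(mv), 0, 0.05))
  start_off <- log10(c(k0_d = unname(true_p[["k0_d"]]) * 3,
                       k_knockdown = 0.3))
  fr <- fit(ds, base_params = true_p, free = c("k0_d", "k_knockdown"),
            lower = -3, upper = 0.5, n_starts = 1, pop_size = 12,
            n_gen = 15, seed = 4, init = start_off)
  expect_lt(abs(fr$params[["k0_d"]] - true_p[["k0_d"]]) /
              true_p[["k0_d"]], 0.2)
  expect_lt(abs(fr$k_knockdown - ml_knockdown_fraction()) /
              ml_knockdown_fraction(), 0.2)
  # fit is deterministic under a fixed seed
  fr2 <- fit(ds, base_params = true_p, free = c("k0_d", "k_knockdown"),
             lower = -3, upper = 0.5, n_starts = 1, pop_size = 12,
             n_gen = 15, seed = 4, init = start_off)
  expect_identical(fr$theta_log10, fr2$theta_log10)
})

test_that("local sensitivity envelopes behave and rank as expected", {
  sens0 <- local_sensitivity(ml_params, param_names = c("kd_s", "k0_d"),
                             rel_range = 0, n_steps = 3,
                             t_grid = seq(0, 400, by = 50))
  expect_true(all(sens0$width < 1e-8))
  # nested-interval property over growing ranges
  w <- vapply(c(0.1, 0.2, 0.3), function(r) {
    local_sensitivity(ml_params, param_names = "kd_s", rel_range = r,
                      n_steps = 5,
                      t_grid = seq(0, 400, by = 50))$width[["kd_s"]]
  }, numeric(1))
  expect_true(all(diff(w) >= -1e-10))
  expect_error(local_sensitivity(ml_params, n_steps = 2), "n_steps")
})
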