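# Pseudo-arclength continuation against closed-form normal forms and
# structural checks on CBSD diagrams.

test_that("saddle-node of x' = r - x^2 is located at r = 0", {
  br <- continue_path(function(x, r) r - x^2, start_x = 1, start_lam = 1,
                      range = c(-1, 1), direction = -1, clamp = -Inf)
  expect_equal(nrow(br$folds), 1)
  expect_lt(abs(br$folds$param[1]), 1e-4)
  up <- br$points$x1 > 1e-3
  dn <- br$points$x1 < -1e-3
  expect_true(all(br$points$stable[up]))
  expect_true(all(!br$points$stable[dn]))
})

test_that("cusp normal form folds match the discriminant +-2/(3*sqrt(3))", {
  br <- continue_path(function(x, r) r + x - x^3, start_x = -1.2,
                      start_lam = -1, range = c(-1, 1), direction = 1,
                      clamp = -Inf)
  expect_equal(nrow(br$folds), 2)
  expect_equal(sort(br$folds$param), c(-2, 2) / (3 * sqrt(3)),
               tolerance = 1e-6 / 0.385)
  expect_false(br$truncated)
})

test_that("fold positions are stable under halved continuation steps", {
  br1 <- continue_path(function(x, r) r + x - x^3, start_x = -1.2,
                       start_lam = -1, range = c(-1, 1), direction = 1,
                       h0 = 0.02, h_max = 0.08, clamp = -Inf)
  br2 <- continue_path(function(x, r) r + x - x^3, start_x = -1.2,
                       start_lam = -1, range = c(-1, 1), direction = 1,
                       h0 = 0.01, h_max = 0.04, clamp = -Inf)
  expect_equal(sort(br1$folds$param), sort(br2$folds$param),
               tolerance = 0.01)
})

test_that("a monostable linear system yields one branch and no folds", {
  br <- continue_path(function(x, r) r - x, start_x = 0, start_lam = 0,
                      range = c(0, 1), direction = 1, clamp = -Inf)
  expect_equal(nrow(br$folds), 0)
  expect_true(all(br$points$stable))
  expect_equal(br$points$x1, br$points$param, tolerance = 1e-8)
})

test_that("the knockdown E branch is stable across the full dose range", {
  eq <- suppressWarnings(equilibrate(ml_params, kd_ml(0),
                                     duration = 3000))
  br <- continue_branch(ml_params, kd_ml(0), "TGF0", c(0, 10), eq,
                        start_lam = 0, direction = 1)
  expect_gte(max(br$points$param), 10 - 1e-6)
  expect_true(all(br$points$stable))
  expect_true(all(br$points$Ncad < fix_thresholds()[1]))
})

test_that("continuation rejects a non-fixed-point start", {
  expect_error(
    continue_branch(ml_params, ctrl(0), "TGF0", c(0, 10),
                    random_state() + 1),
    "fixed point")
})

test_that("every stable-labelled point re-verifies its eigenvalues", {
  eq <- suppressWarnings(equilibrate(ml_params, duration = 2000))
  br <- continue_branch(ml_params, ctrl(0), "TGF0", c(0, 2), eq,
                        start_lam = 0, direction = 1)
  idx <- round(seq(1, nrow(br$points), length.out = 5))
  for (i in idx) {
    st <- stats::setNames(as.numeric(br$points[i, cbsd_species()]),
                          cbsd_species())
    J <- cbsd:::cbsd_jacobian(st, ml_params,
                              ctrl(br$points$param[i]))
    expect_equal(all(Re(eigen(J, only.values = TRUE)$values) < 0),
                 br$points$stable[i])
  }
})
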