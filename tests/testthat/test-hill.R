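test_that("Hill activation matches closed-form values and limits", {
  expect_equal(hill_activation(0, 1.3, 2), 0)
  expect_equal(hill_activation(1.3, 1.3, 4), 0.5)
  expect_equal(hill_activation(2, 1, 4), 16 / 17)
  # monotone increasing, bounded in [0, 1)
  x <- seq(0, 50, by = 0.5)
  v <- hill_activation(x, 2, 3)
  expect_true(all(diff(v) > 0))
  expect_true(all(v >= 0 & v < 1))
})

test_that("Hill repression complements activation for random inputs", {
  expect_equal(hill_repression(0, 0.7, 2), 1)
  expect_equal(hill_repression(0.7, 0.7, 6), 0.5)
  set.seed(11)
  for (i in 1:25) {
    x <- runif(1, 0, 10); J <- runif(1, 0.01, 5); n <- sample(1:6, 1)
    expect_equal(hill_activation(x, J, n) + hill_repression(x, J, n), 1)
  }
})

test_that("invalid Hill parameters are rejected", {
  expect_error(hill_activation(1, 0, 2), "J")
  expect_error(hill_activation(1, -2, 2), "J")
  expect_error(hill_activation(1, 1, 0.5), "coefficient")
  expect_error(hill_repression(-1, 1, 2), "non-negative")
})
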