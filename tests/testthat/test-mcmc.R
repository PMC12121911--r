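# Adaptive-Metropolis sampler, convergence diagnostics, model
# reduction.

test_that("the sampler recovers a correlated 2-D Gaussian target", {
  S <- matrix(c(1, 0.6, 0.6, 0.5), 2)
  Si <- solve(S)
  lp <- function(th) -0.5 * drop(t(th) %*% Si %*% th)
  post <- mcmc_sample(lp, c(a = 0, b = 0), n_iter = 50000, seed = 8,
                      prop_scale = 0.5)
  kept <- post$chain[(post$burn_in + 1):nrow(post$chain), ]
  Shat <- stats::cov(kept)
  expect_lt(max(abs(Shat - S) / max(abs(S))), 0.10)
  expect_gt(post$acceptance, 0.1)
  expect_true(all(post$ess > 100))
})

test_that("ESS of an i.i.d. chain is close to its length", {
  set.seed(5)
  x <- rnorm(20000)
  expect_lt(abs(ess_autocorr(x) - length(x)) / length(x), 0.1)
  # strongly autocorrelated chain has much smaller ESS
  y <- as.numeric(stats::filter(rnorm(20000), 0.95, method = "recursive"))
  expect_lt(ess_autocorr(y), length(y) / 10)
})

test_that("Geweke burn-in flags a drifting prefix", {
  set.seed(6)
  clean <- rnorm(5000)
  expect_equal(geweke_burn_in(cbind(clean)), 0)
  drift <- c(seq(8, 0, length.out = 1500) + rnorm(1500), rnorm(3500))
  expect_gt(geweke_burn_in(cbind(drift)), 0)
})

test_that("zero acceptance raises an informative error", {
  lp <- function(th) if (any(th != 0)) -Inf else 0
  expect_error(mcmc_sample(lp, c(a = 0), n_iter = 2000, seed = 1,
                           prop_scale = 1),
               "acceptance")
})

test_that("model reduction ties correlated pairs and refuses others", {
  set.seed(9)
  n <- 4000
  a <- rnorm(n)
  chain <- cbind(ks1 = a, J1s = a + rnorm(n, 0, 0.05),
                 kd1 = rnorm(n))
  post <- structure(list(chain = chain, burn_in = 0,
                         log_post = -rowSums(chain^2)),
                    class = "cbsd_posterior")
  red <- reduce_model(post, list(c("ks1", "J1s")))
  expect_setequal(red$free, c("ks1", "kd1"))
  th <- expand_reduced(c(ks1 = 0.3, kd1 = -1), red)
  expect_equal(unname(th[["J1s"]] - th[["ks1"]]),
               unname(red$fixed_ratios[[1]]))
  # idempotent: expanding twice changes nothing
  expect_identical(expand_reduced(th[red$free], red), th[names(th)])
  expect_error(reduce_model(post, list(c("ks1", "kd1"))), "refusing")
})

test_that("the likelihood surface ties ks2 and J2s into a ridge", {
  # the DLC1->snail1 drive enters through ks2 * (D/J2s)^n, so the
  # posterior over (ks2, J2s) concentrates on a power-law ridge with
  # near-perfect rank correlation
  ds <- build_dataset(t_grid = seq(0, 1000, by = 200))
  base <- ml_params
  lp <- function(th) {
    p <- base
    p["ks2"] <- 10^th[["ks2"]]; p["J2s"] <- 10^th[["J2s"]]
    -objective(p, ds)
  }
  post <- mcmc_sample(lp, log10(c(ks2 = base[["ks2"]],
                                  J2s = base[["J2s"]])),
                      n_iter = 600, seed = 12, prop_scale = 0.08,
                      adapt_start = 150)
  kept <- post$chain[(post$burn_in + 1):nrow(post$chain), ]
  rho <- stats::cor(kept[, "ks2"], kept[, "J2s"], method = "spearman")
  expect_gt(abs(rho), 0.9)
})
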