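# qPCR-style fold-change generators and phenotype mixtures.

test_that("noiseless qPCR replicates equal the true fold changes", {
  fc <- data.frame(gene = c("dlc1", "snail1", "dlc1"),
                   condition = c("untreated", "tgf", "tgf"),
                   fold = c(1, 4.2, 2.5))
  out <- gen_qpcr(fc, n_reps = 3, noise_cv = 0, seed = 2)
  expect_equal(nrow(out), 9)
  expect_equal(out$fold_change[out$gene == "snail1"], rep(4.2, 3))
  expect_error(gen_qpcr(data.frame(gene = "x", condition = "c",
                                   fold = -1)),
               "positive")
})

test_that("replicate geometric means converge to the true fold", {
  fc <- data.frame(gene = "dlc1", condition = "tgf", fold = 3)
  out <- gen_qpcr(fc, n_reps = 10000, noise_cv = 0.2, seed = 3)
  gm <- exp(mean(log(out$fold_change)))
  se <- 0.2 / sqrt(10000)
  expect_lt(abs(log(gm) - log(3)), 2 * se)
  # identical seeds give identical datasets
  out2 <- gen_qpcr(fc, n_reps = 10000, noise_cv = 0.2, seed = 3)
  expect_identical(out$fold_change, out2$fold_change)
})

test_that("knockdown time courses are stable in time by construction", {
  tc <- gen_knockdown_timecourse(0.44, 0.12, n_reps = 1, noise_cv = 0,
                                 seed = 1)
  for (g in c("dlc1", "snail1")) {
    v <- tc$fold_change[tc$gene == g]
    expect_equal(diff(range(v)), 0)
  }
  expect_error(gen_knockdown_timecourse(1.5, 0.5), "0, 1")
})

test_that("noiseless knockdown folds reproduce the calibration block", {
  tc <- gen_knockdown_timecourse(0.44, 0.12, n_reps = 1, noise_cv = 0)
  ds <- build_dataset(t_grid = seq(0, 1000, by = 100),
                      fc_dlc1_kd = unique(tc$fold_change[tc$gene ==
                                                           "dlc1"]),
                      fc_snail1_kd = unique(tc$fold_change[tc$gene ==
                                                             "snail1"]))
  kd <- ds[ds$condition == "knockdown_10", ]
  s_steady <- ds$value[ds$observable == "snail1_mRNA" &
                         ds$condition == "control_10" &
                         ds$time == 1000][1]
  expect_equal(sort(unique(kd$time)), sort(unique(tc$time[tc$gene ==
                                                            "dlc1"])))
  expect_equal(unique(kd$value[kd$observable == "snail1_mRNA"]),
               0.12 * s_steady)
})

test_that("phenotype mixtures carry the requested composition", {
  mix <- gen_phenotype_mixture(c(E = 1, P = 0, M = 0), 50, seed = 4)
  expect_true(all(mix$true_label == "E"))
  mix2 <- gen_phenotype_mixture(c(E = 0.3, P = 0.2, M = 0.5), 1e5,
                                seed = 7)
  fr <- table(mix2$true_label) / nrow(mix2)
  for (lab in c("E", "P", "M")) {
    p0 <- c(E = 0.3, P = 0.2, M = 0.5)[[lab]]
    se <- sqrt(p0 * (1 - p0) / 1e5)
    expect_lt(abs(fr[[lab]] - p0), 3 * se)
  }
  expect_error(gen_phenotype_mixture(c(E = 0.5, P = 0.2, M = 0.2), 10),
               "summing")
})

test_that("noiseless marker levels are classified back perfectly", {
  lv <- list(medians = rbind(E = c(Ecad = 3, Ncad = 0.01),
                             P = c(Ecad = 1.5, Ncad = 0.5),
                             M = c(Ecad = 0.1, Ncad = 2.8)),
             log_sd = 1e-12)
  mix <- gen_phenotype_mixture(c(E = 0.4, P = 0.3, M = 0.3), 300,
                               level_params = lv, seed = 6)
  pred <- as.character(classify_phenotype(mix$Ncad, fix_thresholds()))
  expect_equal(pred, mix$true_label)
})
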