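# Synthetic-data generators shaped like the study's measurements:
# qPCR-style fold-change replicates (the 2^-ddCt pipeline yields ratio-
# scale data, so replicate noise is multiplicative lognormal),
# stable-knockdown time courses, and single-cell phenotype mixtures.

#' Generate qPCR-style fold-change replicates
#'
#' Replicate fold change = true fold x lognormal noise with median 1 and
#' log-sd `noise_cv`. Untreated-control entries have true fold 1 by
#' construction, so their per-gene geometric mean is ~1.
#'
#' @param true_fc Data.frame with columns `gene`, `condition`, `fold`
#'   (> 0), or a named numeric vector (names "gene.condition").
#' @param n_reps Replicates per gene x condition.
#' @param noise_cv Lognormal log-sd (0 = noiseless).
#' @param seed Integer seed.
#' @return Data.frame of class `cbsd_qpcr`: `gene`, `condition`,
#'   `replicate`, `fold_change`; attributes `n_reps`, `noise_cv`.
#' @export
gen_qpcr <- function(true_fc, n_reps = 4, noise_cv = 0.2, seed = 1) {
  if (is.numeric(true_fc)) {
    parts <- strsplit(names(true_fc), ".", fixed = TRUE)
    true_fc <- data.frame(gene = vapply(parts, `[`, "", 1),
                          condition = vapply(parts, `[`, "", 2),
                          fold = as.numeric(true_fc))
  }
  if (any(true_fc$fold <= 0)) stop("fold changes must be positive")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(nrow(true_fc)), function(i) {
    noise <- if (noise_cv == 0) rep(1, n_reps)
    else stats::rlnorm(n_reps, 0, noise_cv)
    data.frame(gene = true_fc$gene[i], condition = true_fc$condition[i],
               replicate = seq_len(n_reps),
               fold_change = true_fc$fold[i] * noise)
  }))
  structure(out, n_reps = n_reps, noise_cv = noise_cv, seed = seed,
            class = c("cbsd_qpcr", "data.frame"))
}

#' Generate a stable-knockdown qPCR time course
#'
#' The study's stable-knockdown assumption: the true knockdown fold
#' change is constant over all time points; only replicate noise varies.
#' With `noise_cv = 0` the output reproduces the exact fold-change block
#' that [build_dataset()] turns into pseudo-observations.
#'
#' @param fc_dlc1,fc_snail1 Knockdown fold changes in (0, 1].
#' @param timepoints Measurement times (default the 14 fitting points).
#' @param n_reps Replicates per time point.
#' @param noise_cv Lognormal log-sd.
#' @param seed Integer seed.
#' @return `cbsd_qpcr` data.frame with an extra `time` column.
#' @export
gen_knockdown_timecourse <- function(fc_dlc1, fc_snail1,
                                     timepoints = knockdown_timepoints(),
                                     n_reps = 3, noise_cv = 0.2, seed = 1) {
  for (f in c(fc_dlc1, fc_snail1)) {
    if (f <= 0 || f > 1) stop("knockdown folds must lie in (0, 1]")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  genes <- c(dlc1 = fc_dlc1, snail1 = fc_snail1)
  out <- do.call(rbind, lapply(names(genes), function(g) {
    do.call(rbind, lapply(timepoints, function(tp) {
      noise <- if (noise_cv == 0) rep(1, n_reps)
      else stats::rlnorm(n_reps, 0, noise_cv)
      data.frame(gene = g, condition = "knockdown", time = tp,
                 replicate = seq_len(n_reps),
                 fold_change = genes[[g]] * noise)
    }))
  }))
  structure(out, n_reps = n_reps, noise_cv = noise_cv, seed = seed,
            class = c("cbsd_qpcr", "data.frame"))
}

#' Generate a single-cell phenotype mixture
#'
#' Draws cell labels from the requested E/P/M fractions, then lognormal
#' E-cad / N-cad marker levels around label-specific medians (by default
#' the calibrated model's phenotype fixed-point levels).
#'
#' @param fracs Named numeric `c(E=,P=,M=)` summing to 1.
#' @param n_cells Number of cells.
#' @param level_params Optional list with `medians` (3x2 matrix,
#'   rows E/P/M, columns Ecad/Ncad) and `log_sd`; defaults from the
#'   package's calibrated fixed points with `log_sd = 0.15`.
#' @param seed Integer seed.
#' @return Data.frame: `cell`, `true_label`, `Ecad`, `Ncad`.
#' @export
gen_phenotype_mixture <- function(fracs, n_cells, level_params = NULL,
                                  seed = 1) {
  if (abs(sum(fracs) - 1) > 1e-8 || any(fracs < 0) ||
        !all(c("E", "P", "M") %in% names(fracs))) {
    stop("fracs must be named E/P/M fractions summing to 1")
  }
  if (is.null(level_params)) level_params <- default_mixture_levels()
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  labs <- sample(c("E", "P", "M"), n_cells, replace = TRUE,
                 prob = fracs[c("E", "P", "M")])
  med <- level_params$medians
  lsd <- level_params$log_sd
  ecad <- med[labs, "Ecad"] * stats::rlnorm(n_cells, 0, lsd)
  ncad <- med[labs, "Ncad"] * stats::rlnorm(n_cells, 0, lsd)
  data.frame(cell = seq_len(n_cells), true_label = labs,
             Ecad = ecad, Ncad = ncad)
}

# marker medians of the three phenotypes; cached on first use
.mixture_cache <- new.env(parent = emptyenv())
default_mixture_levels <- function(params = cbsd_params()) {
  key <- digest_params(params)
  hit <- .mixture_cache[[key]]
  if (!is.null(hit)) return(hit)
  eqE <- suppressWarnings(equilibrate(params, duration = 2000, tol = Inf))
  M <- phenotype_fixed_point(params, cbsd_condition(TGF0 = 10), "M")
  ctl15 <- cbsd_condition(TGF0 = 1.25)
  pseed <- cbsd_state(snail1_mRNA = 0.06, SNAIL1 = 0.6, miR34 = 0.03,
                      zeb1_mRNA = 0.005, ZEB1 = 0.02, miR200 = 0.28,
                      Ecad = 1.5, Ncad = 0.45, TGFb_auto = 0.7,
                      dlc1_mRNA = 0.2, DLC1 = 0.4)
  P <- final_state(simulate(pseed, params, ctl15, c(0, 4000)))
  med <- rbind(E = c(Ecad = eqE[["Ecad"]], Ncad = max(eqE[["Ncad"]], 1e-3)),
               P = c(Ecad = P[["Ecad"]], Ncad = P[["Ncad"]]),
               M = c(Ecad = max(M[["Ecad"]], 1e-3), Ncad = M[["Ncad"]]))
  out <- list(medians = med, log_sd = 0.15)
  .mixture_cache[[key]] <- out
  out
}
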