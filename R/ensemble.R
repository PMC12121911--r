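# RACIPE-style heterogeneity analysis: ensembles of parameter sets
# drawn around the maximum-likelihood set, deterministic simulation per
# "cell", phenotype-fraction summaries.

#' Sample a parameter ensemble around the ML set
#'
#' Each parameter is drawn independently from a normal distribution
#' centred on its ML value with standard deviation `cv` times that
#' value, truncated to positive values (redrawn until positive). Hill
#' coefficients are held fixed: they define the model structure, not a
#' cell-to-cell kinetic quantity.
#'
#' @param ml ML parameter vector.
#' @param n_cells Number of parameter sets.
#' @param cv Relative spread (default 0.20).
#' @param seed Integer seed.
#' @param which Names of parameters to vary; default all non-Hill
#'   parameters (set e.g. `dlc1_free_parameters()` to restrict to the
#'   extension).
#' @return List of parameter vectors, with the draw seed as attribute.
#' @export
sample_parameter_sets <- function(ml, n_cells, cv = 0.20, seed = 1,
                                  which = NULL) {
  stopifnot(cv > 0, n_cells >= 1)
  if (is.null(which)) which <- names(ml)[!grepl("^n", names(ml))]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sets <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    p <- ml
    for (nm in which) {
      repeat {
        v <- stats::rnorm(1, ml[[nm]], cv * ml[[nm]])
        if (v > 0) break
      }
      p[nm] <- v
    }
    sets[[i]] <- p
  }
  attr(sets, "seed") <- seed
  sets
}

#' Phenotype fractions of a deterministic parameter ensemble
#'
#' Simulates every parameter set from the fixed point of the start
#' phenotype under `condition` and classifies the endpoint by
#' N-cadherin. For washout runs, exogenous TGFbeta is removed at
#' `washout_time` and the simulation continues to `t_end`.
#'
#' @param param_sets List of parameter vectors from
#'   [sample_parameter_sets()].
#' @param condition A [cbsd_condition()].
#' @param start_label `"E"` or `"M"`.
#' @param t_end Horizon (h).
#' @param washout Logical: switch `TGF0` to 0 at `washout_time`?
#' @param washout_time Time of TGFbeta removal (default 7 experimental
#'   days, matching the knockdown-after-EMT protocol).
#' @param thresholds Classification thresholds (derived from the first
#'   parameter set by default).
#' @return `cbsd_population` with fractions over non-failed cells and a
#'   count of failed cells.
#' @export
ensemble_fractions <- function(param_sets, condition, start_label = "E",
                               t_end = 1000, washout = FALSE,
                               washout_time = 7 * time_units_per_day(),
                               thresholds = NULL) {
  stopifnot(length(param_sets) >= 1)
  if (is.null(thresholds)) thresholds <- phenotype_thresholds(cbsd_params())
  labs <- character(0); ncads <- numeric(0); failed <- 0
  for (p in param_sets) {
    res <- tryCatch({
      start <- phenotype_fixed_point(p, condition, start_label)
      if (washout && washout_time < t_end) {
        tr1 <- simulate(start, p, condition, c(0, washout_time))
        c0 <- cbsd_condition(0, condition$knockdown, condition$k_knockdown)
        tr2 <- simulate(final_state(tr1), p, c0,
                        c(0, t_end - washout_time))
        final_state(tr2)
      } else {
        final_state(simulate(start, p, condition, c(0, t_end)))
      }
    }, error = function(e) NULL)
    if (is.null(res)) { failed <- failed + 1; next }
    ncads <- c(ncads, res[["Ncad"]])
    labs <- c(labs, as.character(classify_phenotype(res[["Ncad"]],
                                                    thresholds)))
  }
  if (!length(labs)) stop("all ensemble cells failed")
  fr <- c(E = mean(labs == "E"), P = mean(labs == "P"),
          M = mean(labs == "M"))
  structure(list(n_cells = length(labs), n_failed = failed,
                 fractions = fr, t_end = t_end, omega = Inf,
                 seed = attr(param_sets, "seed"),
                 condition = condition, start_label = start_label,
                 per_cell = data.frame(cell = seq_along(labs),
                                       Ncad_window = ncads, label = labs)),
            class = "cbsd_population")
}
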