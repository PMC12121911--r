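# Deterministic simulation: equilibrate-then-stimulate protocol,
# steady-state search, and E/P/M phenotype classification.

# default starting point for equilibration: an entirely epithelial cell.
# Mesenchymal-arm species start at zero; the epithelial species (E-cad
# and both microRNAs) start at their basal production/degradation
# ratios so the equilibration converges quickly onto the E state.
default_initial_state <- function(params) {
  y0 <- cbsd_state()
  y0["Ecad"]   <- (params[["kE1"]] + params[["kE2"]]) / params[["kd_E"]]
  y0["miR34"]  <- (params[["k0_3"]] + params[["k3"]]) / params[["kd_3"]]
  y0["miR200"] <- (params[["k0_2"]] + params[["k2"]]) / params[["kd_2"]]
  y0
}

#' Number of model time units per experimental day
#'
#' The model's hour-scaled time unit maps onto experimental days through
#' a single conversion constant. 100 time units per day places the
#' 180-1000 calibration window at roughly days 2-10 of a TGFbeta
#' time-course experiment; the mapping is a modelling convention, not a
#' measured quantity.
#'
#' @return Numeric scalar (default 100).
#' @export
time_units_per_day <- function() 100

#' Equilibrate the CBSD model without exogenous TGFbeta
#'
#' Integrates from the default epithelial initial state with `TGF0 = 0`
#' for `duration` time units; warns if the end point is not yet a
#' steady state (max |derivative| above `tol`).
#'
#' @param params Parameter vector from [cbsd_params()].
#' @param cond Condition; its `TGF0` is ignored (forced to 0) during
#'   equilibration, the knockdown flag is honoured.
#' @param duration Equilibration time (default 100 time units).
#' @param start Optional starting state overriding the default.
#' @param tol Steady-state warning tolerance on |rhs| (µM/h).
#' @return Named species state at the end of equilibration.
#' @export
equilibrate <- function(params, cond = cbsd_condition(), duration = 100,
                        start = NULL, tol = 1e-6) {
  stopifnot(duration > 0)
  cond0 <- cbsd_condition(0, cond$knockdown, cond$k_knockdown)
  y0 <- if (is.null(start)) default_initial_state(params) else start
  tr <- simulate(y0, params, cond0, c(0, duration))
  st <- final_state(tr)
  resid <- max(abs(cbsd_rhs(st, params, cond0)))
  if (resid > tol) {
    warning(sprintf(
      "equilibration not converged: max |rhs| = %.3g after %g time units",
      resid, duration))
  }
  st
}

#' Simulate the CBSD model deterministically
#'
#' Stiff integration (deSolve lsoda) of [cbsd_rhs()] on a time grid.
#'
#' @param start Named initial state.
#' @param params Parameter vector.
#' @param cond Condition.
#' @param t_grid Strictly increasing time grid (h).
#' @param rtol,atol Integrator tolerances.
#' @return Object of class `cbsd_trajectory`: list with `time` (vector),
#'   `state` (time x species matrix), `condition` and `params_digest`.
#' @export
simulate <- function(start, params, cond, t_grid,
                     rtol = 1e-8, atol = 1e-10) {
  if (is.unsorted(t_grid, strictly = TRUE)) {
    stop("t_grid must be strictly increasing")
  }
  f <- function(t, y, parms) list(unname(cbsd_rhs(y, params, cond)))
  out <- deSolve::lsoda(start[cbsd_species()], t_grid, f,
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0 || nrow(out) < length(t_grid)) {
    worst <- cbsd_species()[which.max(abs(cbsd_rhs(
      pmax(out[nrow(out), -1], 0), params, cond)))]
    stop(sprintf(
      "integration failed near t = %g (largest local rate: %s)",
      out[nrow(out), 1], worst))
  }
  st <- pmax(out[, -1, drop = FALSE], 0)
  colnames(st) <- cbsd_species()
  structure(list(time = out[, 1], state = st, condition = cond,
                 params_digest = digest_params(params)),
            class = "cbsd_trajectory")
}

#' @export
print.cbsd_trajectory <- function(x, ...) {
  cat(sprintf("CBSD trajectory: %d time points on [%g, %g]\n",
              length(x$time), min(x$time), max(x$time)))
  print(x$condition)
  invisible(x)
}

#' Final state of a trajectory
#' @param traj A `cbsd_trajectory`.
#' @return Named species state at the last time point.
#' @export
final_state <- function(traj) {
  stats::setNames(traj$state[nrow(traj$state), ], colnames(traj$state))
}

digest_params <- function(params) {
  paste0("p", format(sum(seq_along(params) * params), digits = 12))
}

# ---------------------------------------------------------------------
# steady states

# finite-difference Jacobian of the rhs (central differences; step
# scaled to the state magnitude)
cbsd_jacobian <- function(state, params, cond, h_rel = 1e-6) {
  n <- length(state)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- h_rel * max(abs(state[j]), 1e-4)
    up <- state; up[j] <- up[j] + h
    dn <- state; dn[j] <- max(dn[j] - h, 0)
    J[, j] <- (cbsd_rhs(up, params, cond) - cbsd_rhs(dn, params, cond)) /
      (up[j] - dn[j])
  }
  dimnames(J) <- list(cbsd_species(), cbsd_species())
  J
}

# damped Newton refinement of a fixed point; returns NULL on failure
newton_fixed_point <- function(seed, params, cond, tol = 1e-10,
                               max_iter = 60) {
  x <- pmax(seed, 0)
  for (i in seq_len(max_iter)) {
    f <- cbsd_rhs(x, params, cond)
    if (max(abs(f)) < tol) return(x)
    J <- cbsd_jacobian(x, params, cond)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lam <- 1
    repeat {
      xn <- pmax(x + lam * step, 0)
      fn <- cbsd_rhs(xn, params, cond)
      if (sum(fn^2) < sum(f^2) || lam < 1e-4) break
      lam <- lam / 2
    }
    if (max(abs(xn - x)) < 1e-14) return(if (max(abs(fn)) < 1e-8) xn else NULL)
    x <- xn
  }
  if (max(abs(cbsd_rhs(x, params, cond))) < 1e-8) x else NULL
}

#' Find steady states of the CBSD model
#'
#' Newton-refines candidate fixed points from a list of seed states,
#' deduplicates them by relative distance, and labels stability from
#' the real parts of the finite-difference Jacobian eigenvalues.
#'
#' @param params Parameter vector.
#' @param cond Condition.
#' @param seeds List of named seed states; by default, endpoints of
#'   relaxations from a small library of epithelial/partial/mesenchymal
#'   starting points.
#' @param dedup_tol Relative distance below which two fixed points are
#'   considered identical.
#' @return List of entries `list(state, stable, eigenvalues)`, ordered
#'   by increasing N-cad.
#' @export
find_steady_states <- function(params, cond, seeds = NULL,
                               dedup_tol = 1e-3) {
  if (is.null(seeds)) seeds <- default_seed_states(params, cond)
  if (!length(seeds)) stop("at least one seed state is required")
  fps <- list()
  for (sd in seeds) {
    fp <- newton_fixed_point(sd, params, cond)
    if (is.null(fp)) next
    dup <- any(vapply(fps, function(g) {
      max(abs(g$state - fp)) / (1 + max(abs(fp))) < dedup_tol
    }, logical(1)))
    if (dup) next
    ev <- eigen(cbsd_jacobian(fp, params, cond), only.values = TRUE)$values
    fps[[length(fps) + 1]] <- list(state = fp,
                                   stable = all(Re(ev) < 0),
                                   eigenvalues = ev)
  }
  if (!length(fps)) {
    warning("no steady state converged from any seed")
    return(list())
  }
  fps[order(vapply(fps, function(g) g$state[["Ncad"]], numeric(1)))]
}

# relax from epithelial, intermediate and mesenchymal starting points
# to harvest candidate attractor-basin representatives
default_seed_states <- function(params, cond, t_relax = 4000) {
  starts <- list(default_initial_state(params))
  mid <- cbsd_state(SNAIL1 = 0.5, snail1_mRNA = 0.05, Ncad = 0.5,
                    Ecad = 1.5, miR200 = 0.3, dlc1_mRNA = 0.05,
                    DLC1 = 0.1)
  mes <- cbsd_state(SNAIL1 = 3, snail1_mRNA = 0.3, ZEB1 = 2,
                    zeb1_mRNA = 0.2, Ncad = 2.5, TGFb_auto = 5,
                    dlc1_mRNA = 0.2, DLC1 = 0.4)
  mes2 <- mes; mes2["ZEB1"] <- 0.05; mes2["zeb1_mRNA"] <- 0.005
  mes2["miR200"] <- 0.2
  starts <- c(starts, list(mid, mes, mes2))
  lapply(starts, function(y0) {
    final_state(simulate(y0, params, cond, c(0, t_relax)))
  })
}

# ---------------------------------------------------------------------
# phenotype classification

#' Classify a cell state by its N-cadherin level
#'
#' E for `Ncad < low_cut`, P for `low_cut <= Ncad < high_cut`, M
#' otherwise (boundaries belong to the upper class).
#'
#' @param Ncad N-cadherin concentration (µM), non-negative. Vectorised.
#' @param thresholds Numeric `c(low_cut, high_cut)` with
#'   `low_cut < high_cut`; defaults to [phenotype_thresholds()].
#' @return Factor with levels E, P, M.
#' @export
classify_phenotype <- function(Ncad, thresholds = phenotype_thresholds()) {
  if (any(Ncad < 0)) stop("N-cad concentration must be non-negative")
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  lab <- ifelse(Ncad < thresholds[1], "E",
                ifelse(Ncad < thresholds[2], "P", "M"))
  factor(lab, levels = c("E", "P", "M"))
}

.threshold_cache <- new.env(parent = emptyenv())

#' Phenotype classification thresholds on N-cadherin
#'
#' The E/P and P/M cuts are data-derived: the control-condition TGF0
#' bifurcation diagram is computed, the N-cad ranges of its three stable
#' branches are collected, and the cuts are placed at the midpoints of
#' the gaps between consecutive branch ranges. The result is cached per
#' parameter digest.
#'
#' @param params Parameter vector (default package defaults).
#' @return Numeric `c(low_cut, high_cut)` in µM.
#' @export
phenotype_thresholds <- function(params = cbsd_params()) {
  key <- digest_params(params)
  hit <- .threshold_cache[[key]]
  if (!is.null(hit)) return(hit)
  th <- derive_thresholds(params)
  .threshold_cache[[key]] <- th
  th
}

# branch N-cad ranges from stable attractors over a TGF0 grid: relax a
# small E/partial/M seed library at each dose and pool the endpoint
# N-cad values; the two widest gaps that exceed 10% of the total range
# separate the three branch clusters
derive_thresholds <- function(params) {
  grid <- c(0, 0.5, 1, 1.25, 1.4, 1.5, 2, 3, 5, 10)
  pseed <- cbsd_state(snail1_mRNA = 0.06, SNAIL1 = 0.6, miR34 = 0.03,
                      zeb1_mRNA = 0.005, ZEB1 = 0.02, miR200 = 0.28,
                      Ecad = 1.5, Ncad = 0.45, TGFb_auto = 0.7,
                      dlc1_mRNA = 0.2, DLC1 = 0.4)
  mseed <- cbsd_state(snail1_mRNA = 0.4, SNAIL1 = 4, zeb1_mRNA = 0.2,
                      ZEB1 = 1.6, Ncad = 2.8, TGFb_auto = 5.9,
                      miR34 = 0.01, miR200 = 0.02, Ecad = 0.1,
                      dlc1_mRNA = 0.5, DLC1 = 1)
  seeds <- list(default_initial_state(params), pseed, mseed)
  v <- unlist(lapply(grid, function(d) {
    cond <- cbsd_condition(TGF0 = d)
    vapply(seeds, function(y0) {
      final_state(simulate(y0, params, cond, c(0, 4000)))[["Ncad"]]
    }, numeric(1))
  }))
  v <- sort(v)
  if (length(v) < 3) stop("could not derive thresholds: too few attractors")
  gaps <- diff(v)
  big <- which(gaps > 0.1 * diff(range(v)))
  if (length(big) < 2) {
    stop("could not derive thresholds: fewer than three N-cad clusters")
  }
  top2 <- sort(big[order(gaps[big], decreasing = TRUE)][1:2])
  sort(c(mean(v[c(top2[1], top2[1] + 1)]),
         mean(v[c(top2[2], top2[2] + 1)])))
}
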