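# Exact stochastic simulation (Gillespie direct method) of the CBSD
# reaction network, for single cells and populations.
#
# Two interchangeable engines: a pure-R direct method driven by the
# explicit reaction network (reference implementation, any network) and
# a compiled kernel for the CBSD network (used for populations). Both
# consume R's RNG in the same order, so identical seeds give identical
# jump trajectories.

#' Construct a molecule-count state
#'
#' @param conc Named concentration state (µM).
#' @param omega System size (molecules per µM), > 0.
#' @return List of class `cbsd_counts` with integer `counts` and `omega`.
#' @export
as_counts <- function(conc, omega = 1000) {
  stopifnot(omega > 0)
  counts <- round(conc * omega)
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = counts, omega = omega), class = "cbsd_counts")
}

#' Convert reaction rate laws to propensities
#'
#' Evaluates every rate law of `network` at the concentration state
#' implied by `counts` (count / Omega) and scales by Omega, so a
#' zeroth-order rate k (µM/h) becomes k*Omega events/h and a first-order
#' rate k*x becomes k*count.
#'
#' @param network A `cbsd_network` from [build_reaction_network()].
#' @param counts A `cbsd_counts` state.
#' @return Numeric vector of propensities (events/h), one per reaction.
#' @export
to_propensities <- function(network, counts) {
  conc <- counts$counts / counts$omega
  vapply(network$reactions, function(r) {
    a <- r$rate(conc) * counts$omega
    # first-order laws must be exactly proportional to the count: rate
    # k*(n/omega)*omega == k*n up to floating point
    max(a, 0)
  }, numeric(1))
}

#' Run one exact stochastic trajectory
#'
#' Gillespie direct method for the CBSD network. With
#' `engine = "compiled"` (default) the compiled kernel is used; with
#' `engine = "r"` a plain-R loop over [to_propensities()] runs instead
#' (identical trajectories for identical seeds, but much slower --
#' intended for cross-checks on short horizons).
#'
#' @param params Parameter vector.
#' @param cond Condition.
#' @param counts0 Initial `cbsd_counts`.
#' @param t_grid Recording time grid (h); the trajectory is sampled at
#'   these times (piecewise-constant interpolation of the jump process).
#' @param seed Integer seed; no hidden global state is consumed.
#' @param engine `"compiled"`, `"r"`, or `"tau"` (approximate
#'   tau-leaping with fixed step `tau`; intended only for large-Omega
#'   cross-checks, not for production runs).
#' @param tau Leap size (h) for `engine = "tau"`.
#' @return List of class `cbsd_ssa`: `time`, `state` (counts matrix),
#'   `omega`, `absorbed` flag (all propensities hit zero), `n_events`.
#' @export
ssa_run <- function(params, cond, counts0, t_grid, seed,
                    engine = c("compiled", "r", "tau"), tau = 0.05) {
  engine <- match.arg(engine)
  stopifnot(inherits(counts0, "cbsd_counts"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (engine == "tau") {
    out <- tau_leap_run(params, cond, counts0, t_grid, tau)
  } else if (engine == "compiled") {
    res <- .ssa_run_cpp(params, cond$TGF0, isTRUE(cond$knockdown),
                        cond$k_knockdown,
                        as.numeric(counts0$counts[cbsd_species()]),
                        counts0$omega, t_grid)
    st <- res$state
    colnames(st) <- cbsd_species()
    out <- list(time = t_grid, state = st, omega = counts0$omega,
                absorbed = res$absorbed, n_events = res$n_events)
  } else {
    out <- ssa_run_r(params, cond, counts0, t_grid)
  }
  structure(out, class = "cbsd_ssa")
}

# reference direct method in R; consumes the RNG in the same order as
# the compiled kernel (one rexp per step, one runif per fired reaction).
# Works for any reaction network following the cbsd_network layout.
ssa_run_r <- function(params, cond, counts0, t_grid, network = NULL) {
  if (is.null(network)) network <- build_reaction_network(params, cond)
  n <- counts0$counts[network$species]
  omega <- counts0$omega
  ng <- length(t_grid)
  out <- matrix(0, ng, length(n), dimnames = list(NULL, network$species))
  stoich <- t(vapply(network$reactions, function(r) r$stoich,
                     numeric(length(n))))
  t <- t_grid[1]; gi <- 1; absorbed <- FALSE; nev <- 0
  repeat {
    a <- to_propensities(network, structure(list(counts = n, omega = omega),
                                            class = "cbsd_counts"))
    a0 <- sum(a)
    tnext <- if (a0 <= 0) { absorbed <- TRUE; Inf } else t + stats::rexp(1, a0)
    while (gi <= ng && t_grid[gi] <= tnext) { out[gi, ] <- n; gi <- gi + 1 }
    if (gi > ng || absorbed) break
    r <- findInterval(stats::runif(1) * a0, cumsum(a)) + 1
    n <- pmax(n + stoich[r, ], 0)
    t <- tnext; nev <- nev + 1
  }
  if (absorbed && gi <= ng) for (g in gi:ng) out[g, ] <- n
  list(time = t_grid, state = out, omega = omega, absorbed = absorbed,
       n_events = nev)
}

# fixed-step tau-leaping: Poisson reaction counts per leap, clamped at
# zero; an approximation used to cross-check the exact kernel at large
# system sizes
tau_leap_run <- function(params, cond, counts0, t_grid, tau) {
  network <- build_reaction_network(params, cond)
  n <- counts0$counts[network$species]
  omega <- counts0$omega
  stoich <- t(vapply(network$reactions, function(r) r$stoich,
                     numeric(length(n))))
  ng <- length(t_grid)
  out <- matrix(0, ng, length(n), dimnames = list(NULL, network$species))
  t <- t_grid[1]; gi <- 1; nev <- 0
  repeat {
    while (gi <= ng && t_grid[gi] <= t + 1e-12) {
      out[gi, ] <- n; gi <- gi + 1
    }
    if (gi > ng) break
    a <- to_propensities(network,
                         structure(list(counts = n, omega = omega),
                                   class = "cbsd_counts"))
    k <- stats::rpois(length(a), a * tau)
    n <- pmax(n + colSums(stoich * k), 0)
    nev <- nev + sum(k)
    t <- t + tau
  }
  list(time = t_grid, state = out, omega = omega, absorbed = FALSE,
       n_events = nev)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.cbsd_ssa <- function(x, ...) {
  cat(sprintf(
    "CBSD SSA trajectory: %d sample times on [%g, %g], %g events%s\n",
    length(x$time), min(x$time), max(x$time), x$n_events,
    if (x$absorbed) " (absorbing state reached)" else ""))
  invisible(x)
}

#' Stochastic population simulation with phenotype fractions
#'
#' Runs `n_cells` independent Gillespie realisations from the
#' deterministic fixed point of the requested start phenotype,
#' classifies each endpoint by N-cadherin (time-averaged over the last
#' `window_frac` of the horizon to suppress shot noise), and returns the
#' E/P/M fractions.
#'
#' @param params Parameter vector.
#' @param cond Condition.
#' @param start_label `"E"` or `"M"`: phenotype whose deterministic
#'   fixed point (under `cond` for E; under the control/`TGF0 = 10`
#'   mesenchymal attractor for M) seeds every cell.
#' @param n_cells Number of cells (>= 1).
#' @param t_end Simulation horizon (h).
#' @param omega System size (molecules/µM); default 1250, calibrated
#'   once so the knockdown MET split matches the reported population
#'   split (see the methods vignette).
#' @param seed Master seed; cell i uses `seed + i`.
#' @param window_frac Endpoint classification window as a fraction of
#'   `t_end` (default 0.05).
#' @param thresholds Classification thresholds (µM).
#' @param start_state Optional explicit starting concentration state
#'   overriding `start_label`.
#' @return List of class `cbsd_population`: `n_cells`, `fractions`
#'   (named E/P/M, sums to 1), `t_end`, `seed`, `per_cell` data.frame
#'   (cell, seed, Ncad_window, label).
#' @export
population_fractions <- function(params, cond, start_label = c("M", "E"),
                                 n_cells = 1000, t_end = 1000,
                                 omega = 1250, seed = 1,
                                 window_frac = 0.05,
                                 thresholds = phenotype_thresholds(params),
                                 start_state = NULL) {
  stopifnot(n_cells >= 1)
  if (is.null(start_state)) {
    start_label <- match.arg(start_label)
    start_state <- phenotype_fixed_point(params, cond, start_label)
  }
  counts0 <- as_counts(start_state, omega)
  n_rec <- 101
  t_grid <- seq(0, t_end, length.out = n_rec)
  win <- t_grid >= (1 - window_frac) * t_end
  labs <- character(n_cells)
  ncads <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    run <- ssa_run(params, cond, counts0, t_grid, seed = seed + i)
    ncads[i] <- mean(run$state[win, "Ncad"]) / omega
    labs[i] <- as.character(classify_phenotype(ncads[i], thresholds))
  }
  fr <- c(E = mean(labs == "E"), P = mean(labs == "P"),
          M = mean(labs == "M"))
  structure(list(n_cells = n_cells, fractions = fr, t_end = t_end,
                 omega = omega, seed = seed,
                 condition = cond, start_label = start_label,
                 per_cell = data.frame(cell = seq_len(n_cells),
                                       seed = seed + seq_len(n_cells),
                                       Ncad_window = ncads, label = labs)),
            class = "cbsd_population")
}

#' @export
print.cbsd_population <- function(x, ...) {
  cat(sprintf(
    "CBSD population: %d cells to t = %g (Omega = %g)\n  E %.1f%%  P %.1f%%  M %.1f%%\n",
    x$n_cells, x$t_end, x$omega, 100 * x$fractions[["E"]],
    100 * x$fractions[["P"]], 100 * x$fractions[["M"]]))
  invisible(x)
}

# deterministic fixed point used to seed population runs: E from the
# equilibrated epithelial state under `cond`; M from the mesenchymal
# attractor (reached under control 10 ng/ml stimulation, then refined
# as a start point -- under knockdown conditions M need not be a fixed
# point of `cond` itself, matching the knockdown-after-EMT protocol)
phenotype_fixed_point <- function(params, cond, label) {
  if (label == "E") {
    suppressWarnings(equilibrate(params, cond, duration = 2000, tol = Inf))
  } else if (label == "M") {
    ctl <- cbsd_condition(TGF0 = 10)
    eq <- suppressWarnings(equilibrate(params, ctl, duration = 2000,
                                       tol = Inf))
    final_state(simulate(eq, params, ctl, c(0, 4000)))
  } else {
    stop("unknown start_label: ", label)
  }
}
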