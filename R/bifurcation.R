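# Fixed-point continuation over one parameter with stability labelling
# and saddle-node (fold) detection, plus simulation-based two-parameter
# phenotype state matrices.
#
# Continuation is pseudo-arclength: an Euler predictor along the unit
# tangent of the branch in (state, parameter) space followed by a Newton
# corrector on the bordered system, so branches are traversed through
# turning points. The continuation parameter is rescaled by the range
# width so arclength treats state and parameter comparably.

# set the continuation parameter (model parameter or condition field)
set_bif_param <- function(params, cond, name, value) {
  if (name %in% names(params)) {
    params[name] <- value
  } else if (name %in% c("TGF0", "k_knockdown")) {
    cond[[name]] <- value
    if (name == "k_knockdown") cond$knockdown <- TRUE
  } else {
    stop("unknown bifurcation parameter: ", name)
  }
  list(params = params, cond = cond)
}

#' Continue a CBSD fixed-point branch over one parameter
#'
#' CBSD front end to [continue_path()]: the continuation parameter may
#' be any kinetic parameter (e.g. `"ks1"`) or the condition fields
#' `"TGF0"` / `"k_knockdown"`; setting the latter activates the
#' knockdown flag.
#'
#' @param params Parameter vector.
#' @param cond Condition.
#' @param bif_param Continuation parameter name.
#' @param range Numeric length-2 parameter interval.
#' @param start_fp Named fixed point at `start_lam`.
#' @param start_lam Parameter value of `start_fp` (default `range[1]`).
#' @param direction +1 / -1 initial direction.
#' @param ... Step controls passed to [continue_path()].
#' @return A `cbsd_branch` (see [continue_path()]); state columns carry
#'   species names.
#' @export
continue_branch <- function(params, cond, bif_param, range, start_fp,
                            start_lam = range[1], direction = 1, ...) {
  F <- function(x, lam) {
    pc <- set_bif_param(params, cond, bif_param, max(lam, 0))
    unname(cbsd_rhs(stats::setNames(x, cbsd_species()),
                    pc$params, pc$cond))
  }
  pc0 <- set_bif_param(params, cond, bif_param, start_lam)
  x0 <- newton_fixed_point(start_fp, pc0$params, pc0$cond)
  if (is.null(x0) ||
        max(abs(x0 - start_fp)) > 0.1 * (1 + max(abs(start_fp)))) {
    stop("start_fp is not a fixed point within tolerance")
  }
  br <- continue_path(F, unname(x0), start_lam, range,
                      direction = direction,
                      x_names = cbsd_species(), clamp = 0, ...)
  br$bif_param <- bif_param
  br
}

#' Assemble a full bifurcation diagram
#'
#' Finds fixed points at several anchor values of the continuation
#' parameter (from E/P/M-covering seed relaxations), continues every
#' distinct fixed point in both directions, merges branches that
#' duplicate each other (proximity in (param, N-cad) space), and
#' collects fold points.
#'
#' @inheritParams continue_branch
#' @param anchors Parameter values at which seeds are harvested.
#' @param seed_grid Optional list of seed states replacing the default
#'   E/P/M relaxation library.
#' @return Object of class `cbsd_diagram`: `branches` (list of
#'   `cbsd_branch`), `folds` data.frame, `n_folds`.
#' @export
assemble_diagram <- function(params, cond, bif_param, range,
                             anchors = NULL, seed_grid = NULL) {
  if (is.null(anchors)) {
    anchors <- seq(range[1], range[2], length.out = 5)
  }
  branches <- list()
  covered <- function(lam, ncad) {
    for (br in branches) {
      pts <- br$points
      near <- abs(pts$param - lam) < 0.03 * diff(range)
      if (any(near) && min(abs(pts$Ncad[near] - ncad)) <
            0.05 * (1 + abs(ncad))) {
        return(TRUE)
      }
    }
    FALSE
  }
  for (a in anchors) {
    pc <- set_bif_param(params, cond, bif_param, a)
    fps <- tryCatch(
      find_steady_states(pc$params, pc$cond, seeds = seed_grid),
      warning = function(w) list(), error = function(e) list())
    for (fp in fps) {
      if (covered(a, fp$state[["Ncad"]])) next
      for (dir in c(1, -1)) {
        if ((a <= range[1] && dir < 0) || (a >= range[2] && dir > 0)) next
        br <- tryCatch(
          continue_branch(params, cond, bif_param, range, fp$state,
                          start_lam = a, direction = dir),
          error = function(e) NULL)
        if (!is.null(br) && nrow(br$points) > 1) {
          branches[[length(branches) + 1]] <- br
        }
      }
    }
  }
  if (!length(branches)) stop("no fixed points found at any anchor")
  branches <- merge_duplicate_branches(branches, range)
  folds <- do.call(rbind, c(list(data.frame()),
                            lapply(branches, function(b) b$folds)))
  folds <- dedup_folds(folds, range)
  structure(list(branches = branches, folds = folds,
                 n_folds = nrow(folds), bif_param = bif_param,
                 range = range),
            class = "cbsd_diagram")
}

#' @export
print.cbsd_diagram <- function(x, ...) {
  cat(sprintf(
    "CBSD bifurcation diagram in %s over [%g, %g]: %d branches, %d folds\n",
    x$bif_param, x$range[1], x$range[2], length(x$branches), x$n_folds))
  invisible(x)
}

# two branches duplicate each other when each point of the shorter one
# has a close partner on the longer one (discrete Hausdorff distance in
# normalised (param, Ncad) space below tol)
merge_duplicate_branches <- function(branches, range, tol = 0.03) {
  width <- diff(range)
  nscale <- max(1, max(vapply(branches,
                              function(b) max(b$points$Ncad), numeric(1))))
  key <- function(b) cbind(b$points$param / width, b$points$Ncad / nscale)
  keep <- rep(TRUE, length(branches))
  ord <- order(vapply(branches, function(b) -nrow(b$points), numeric(1)))
  for (i in seq_along(ord)) {
    if (!keep[ord[i]]) next
    for (j in seq_along(ord)) {
      if (j <= i || !keep[ord[j]]) next
      A <- key(branches[[ord[i]]]); B <- key(branches[[ord[j]]])
      dh <- max(apply(B, 1, function(pt) {
        min(sqrt((A[, 1] - pt[1])^2 + (A[, 2] - pt[2])^2))
      }))
      if (dh < tol) keep[ord[j]] <- FALSE
    }
  }
  branches[keep]
}

dedup_folds <- function(folds, range, tol = 0.01) {
  if (!nrow(folds)) return(folds)
  keep <- rep(TRUE, nrow(folds))
  for (i in seq_len(nrow(folds))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(folds))) {
      if (j <= i || !keep[j]) next
      if (abs(folds$param[i] - folds$param[j]) < tol * diff(range) &&
            abs(folds$Ncad[i] - folds$Ncad[j]) <
              0.05 * (1 + abs(folds$Ncad[i]))) {
        keep[j] <- FALSE
      }
    }
  }
  folds[keep, , drop = FALSE]
}

#' Two-parameter phenotype state matrix
#'
#' For every cell of the `grid1` x `grid2` lattice: equilibrate without
#' exogenous TGFbeta, apply the condition given by the two parameter
#' values, simulate to `t_end`, classify the endpoint phenotype.
#'
#' @param params Parameter vector.
#' @param grid1,grid2 Lists `list(name = , values = )`; names as in
#'   [continue_branch()] `bif_param`.
#' @param t_end Simulation horizon (default 5 experimental days).
#' @param cond Base condition modified per cell.
#' @param thresholds Classification thresholds.
#' @return Character matrix (values "E", "P", "M" or NA on integration
#'   failure) with `grid1$values` rows and `grid2$values` columns.
#' @export
state_matrix <- function(params, grid1, grid2,
                         t_end = 5 * time_units_per_day(),
                         cond = cbsd_condition(),
                         thresholds = phenotype_thresholds(params)) {
  out <- matrix(NA_character_, length(grid1$values), length(grid2$values),
                dimnames = list(signif(grid1$values, 6),
                                signif(grid2$values, 6)))
  for (i in seq_along(grid1$values)) {
    for (j in seq_along(grid2$values)) {
      pc <- set_bif_param(params, cond, grid1$name, grid1$values[i])
      pc <- set_bif_param(pc$params, pc$cond, grid2$name, grid2$values[j])
      lab <- tryCatch({
        eq <- suppressWarnings(
          equilibrate(pc$params,
                      cbsd_condition(0, pc$cond$knockdown,
                                     pc$cond$k_knockdown),
                      tol = Inf))
        tr <- simulate(eq, pc$params, pc$cond, c(0, t_end))
        as.character(classify_phenotype(final_state(tr)[["Ncad"]],
                                        thresholds))
      }, error = function(e) NA_character_)
      out[i, j] <- lab
    }
  }
  out
}
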