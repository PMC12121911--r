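# Generic pseudo-arclength continuation engine for autonomous vector
# fields x' = F(x, lambda). Used by the CBSD bifurcation module and
# directly testable on scalar normal forms with closed-form folds.

#' Pseudo-arclength continuation of a fixed-point branch
#'
#' Traces fixed points of `F(x, lambda) = 0` through `range`, traversing
#' saddle-node turning points. An Euler predictor along the branch
#' tangent (computed in coordinates scaled by `x_scale` and the range
#' width) is followed by a Newton corrector on the bordered system; the
#' arclength step adapts between `h_min` and `h_max`. Stability is
#' labelled from the Jacobian eigenvalues at every accepted point; folds
#' are detected from sign changes of `det(J)` and refined by step
#' bisection until the fold parameter is localised to `1e-4` of the
#' range width.
#'
#' @param F Function `F(x, lam)` returning the vector field (length n).
#' @param start_x Fixed point (within Newton tolerance) at `start_lam`.
#' @param start_lam Parameter value of the starting point.
#' @param range Numeric length-2 parameter interval.
#' @param direction +1 / -1 initial direction of parameter change.
#' @param Jx Optional Jacobian function `Jx(x, lam)`; finite differences
#'   by default.
#' @param x_scale Per-component state scale (default from `start_x`).
#' @param x_names Optional state names for the output columns.
#' @param h0,h_max,h_min Arclength step controls (scaled units).
#' @param max_steps Maximum number of accepted points.
#' @param clamp Lower state bound enforced after each corrector step
#'   (`-Inf` for unconstrained problems; 0 for concentrations).
#' @return Object of class `cbsd_branch`: `points` data.frame with
#'   `param`, state columns, `stable`, `det`; `folds` data.frame;
#'   `truncated` flag (corrector gave up before leaving `range`).
#' @export
continue_path <- function(F, start_x, start_lam, range, direction = 1,
                          Jx = NULL, x_scale = NULL, x_names = NULL,
                          h0 = 0.02, h_max = 0.08, h_min = 1e-6,
                          max_steps = 2000, clamp = 0) {
  stopifnot(length(range) == 2, range[1] < range[2])
  n <- length(start_x)
  width <- range[2] - range[1]
  if (is.null(x_names)) {
    x_names <- if (!is.null(names(start_x))) names(start_x)
    else paste0("x", seq_len(n))
  }
  if (is.null(x_scale)) x_scale <- pmax(abs(start_x), 0.05)
  hfd <- 1e-6 * width
  cl <- function(x) pmax(x, clamp)

  if (is.null(Jx)) {
    Jx <- function(x, lam) {
      J <- matrix(0, n, n)
      for (j in seq_len(n)) {
        h <- 1e-6 * max(abs(x[j]), 1e-4)
        up <- x; up[j] <- up[j] + h
        dn <- x; dn[j] <- dn[j] - h
        J[, j] <- (F(cl(up), lam) - F(cl(dn), lam)) / (2 * h)
      }
      J
    }
  }
  Flam <- function(x, lam) (F(x, lam + hfd) - F(x, lam - hfd)) / (2 * hfd)

  tangent <- function(x, lam, prev = NULL) {
    J <- Jx(x, lam)
    Fl <- Flam(x, lam)
    dx <- tryCatch(solve(J, -Fl), error = function(e) NULL)
    if (!is.null(dx) && all(is.finite(dx))) {
      v <- c(dx / x_scale, 1 / width)
    } else {
      A <- cbind(J %*% diag(x_scale, n), Fl * width)
      sv <- svd(A)
      v <- sv$v[, n + 1]
    }
    v <- v / sqrt(sum(v^2))
    if (!is.null(prev) && sum(v * prev) < 0) v <- -v
    v
  }

  corrector <- function(xp, lp, t_vec, tol = 1e-9, max_iter = 25) {
    xx <- xp; ll <- lp
    for (i in seq_len(max_iter)) {
      Fv <- F(cl(xx), ll)
      g <- sum(t_vec * c((xx - xp) / x_scale, (ll - lp) / width))
      if (max(abs(Fv)) < tol && abs(g) < tol) {
        return(list(x = cl(xx), lam = ll))
      }
      A <- rbind(cbind(Jx(cl(xx), ll), Flam(cl(xx), ll)),
                 c(t_vec[1:n] / x_scale, t_vec[n + 1] / width))
      dd <- tryCatch(solve(A, -c(Fv, g)), error = function(e) NULL)
      if (is.null(dd) || any(!is.finite(dd))) return(NULL)
      xx <- xx + dd[1:n]; ll <- ll + dd[n + 1]
      if (ll < range[1] - 0.05 * width || ll > range[2] + 0.05 * width) {
        return(list(x = cl(xx), lam = ll))
      }
    }
    NULL
  }

  pts_param <- numeric(0); pts_state <- NULL
  pts_stable <- logical(0); pts_det <- numeric(0)
  add_point <- function(x, lam) {
    J <- Jx(x, lam)
    ev <- eigen(J, only.values = TRUE)$values
    pts_param[length(pts_param) + 1] <<- lam
    pts_state <<- rbind(pts_state, x)
    pts_stable[length(pts_stable) + 1] <<- all(Re(ev) < 0)
    pts_det[length(pts_det) + 1] <<- det(J)
  }

  x <- start_x; lam <- start_lam
  t_prev <- tangent(x, lam)
  if (sign(t_prev[n + 1]) != sign(direction)) t_prev <- -t_prev
  add_point(x, lam)

  folds <- list()
  h <- h0
  truncated <- FALSE
  for (step in seq_len(max_steps)) {
    t_vec <- tangent(x, lam, t_prev)
    xp <- x + h * t_vec[1:n] * x_scale
    lp <- lam + h * t_vec[n + 1] * width
    sol <- corrector(xp, lp, t_vec)
    if (is.null(sol)) {
      h <- h / 2
      if (h < h_min) { truncated <- TRUE; break }
      next
    }
    if (sol$lam < range[1] - 1e-12 || sol$lam > range[2] + 1e-12) {
      bl <- if (sol$lam < range[1]) range[1] else range[2]
      # land on the boundary: Newton in x at fixed lambda
      xb <- sol$x
      ok <- FALSE
      for (i in 1:40) {
        Fv <- F(cl(xb), bl)
        if (max(abs(Fv)) < 1e-9) { ok <- TRUE; break }
        dd <- tryCatch(solve(Jx(cl(xb), bl), -Fv), error = function(e) NULL)
        if (is.null(dd) || any(!is.finite(dd))) break
        xb <- xb + dd
      }
      if (ok) add_point(cl(xb), bl)
      break
    }
    d_new <- det(Jx(sol$x, sol$lam))
    d_old <- pts_det[length(pts_det)]
    if (is.finite(d_new) && is.finite(d_old) && d_old * d_new < 0) {
      fold <- NULL
      a <- 0; b <- h
      for (i in 1:40) {
        m <- (a + b) / 2
        sm <- corrector(x + m * t_vec[1:n] * x_scale,
                        lam + m * t_vec[n + 1] * width, t_vec)
        if (is.null(sm)) break
        dm <- det(Jx(sm$x, sm$lam))
        if (sign(dm) == sign(d_old)) a <- m else b <- m
        fold <- sm
        if ((b - a) * max(abs(t_vec[n + 1]), 0.05) * width < 1e-4 * width) break
      }
      if (!is.null(fold)) folds[[length(folds) + 1]] <- fold
    }
    x <- sol$x; lam <- sol$lam; t_prev <- t_vec
    add_point(x, lam)
    h <- min(h * 1.3, h_max)
  }

  colnames(pts_state) <- x_names
  pts <- data.frame(param = pts_param, pts_state,
                    stable = pts_stable, det = pts_det,
                    row.names = NULL, check.names = FALSE)
  folds_df <- if (length(folds)) {
    fd <- do.call(rbind, lapply(folds, function(f) {
      stats::setNames(data.frame(f$lam, t(f$x), check.names = FALSE),
                      c("param", x_names))
    }))
    fd
  } else {
    data.frame()
  }
  structure(list(points = pts, folds = folds_df, truncated = truncated,
                 range = range),
            class = "cbsd_branch")
}

#' @export
print.cbsd_branch <- function(x, ...) {
  cat(sprintf("continuation branch: %d points, param in [%g, %g], %d folds%s\n",
              nrow(x$points), min(x$points$param), max(x$points$param),
              nrow(x$folds), if (x$truncated) " (truncated)" else ""))
  invisible(x)
}
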