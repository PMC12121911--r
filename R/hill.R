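#' Hill activation function
#'
#' Fraction of maximal activation of a target by an effector at
#' concentration `x`, with half-saturation threshold `J` and Hill
#' coefficient `n`: `x^n / (J^n + x^n)`.
#'
#' @param x Effector concentration (µM), non-negative. Vectorised.
#' @param J Half-saturation threshold (µM), strictly positive.
#' @param n Hill coefficient (dimensionless), at least 1.
#' @return Activation fraction in `[0, 1)`, monotone increasing in `x`.
#' @examples
#' hill_activation(2, 1, 4)  # 16/17
#' @export
hill_activation <- function(x, J, n) {
  check_hill_args(x, J, n)
  xn <- (x / J)^n
  xn / (1 + xn)
}

#' Hill repression function
#'
#' Fraction of residual activity of a target repressed by an effector at
#' concentration `x`: `J^n / (J^n + x^n)`, the complement of
#' [hill_activation()].
#'
#' @inheritParams hill_activation
#' @return Repression factor in `(0, 1]`, monotone decreasing in `x`.
#' @export
hill_repression <- function(x, J, n) {
  check_hill_args(x, J, n)
  1 / (1 + (x / J)^n)
}

check_hill_args <- function(x, J, n) {
  if (any(!is.finite(J)) || any(J <= 0)) {
    stop("Hill threshold J must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(n)) || any(n < 1)) {
    stop("Hill coefficient n must be finite and >= 1", call. = FALSE)
  }
  if (any(x < 0)) {
    stop("effector concentration must be non-negative", call. = FALSE)
  }
  invisible(TRUE)
}

# two-input competitive repression 1 / (1 + (x1/J1)^n1 + (x2/J2)^n2),
# used for the miR-34 and miR-200 promoters which are repressed by both
# SNAIL1 and ZEB1
hill_repression2 <- function(x1, J1, n1, x2, J2, n2) {
  1 / (1 + (x1 / J1)^n1 + (x2 / J2)^n2)
}
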