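#' Wrap an angle to the interval (-pi, pi]
#'
#' The package-wide phase convention: every continuous gait phase lives in
#' the half-open interval (-pi, pi].
#'
#' @param x numeric vector of angles in radians.
#' @return numeric vector with every element in (-pi, pi].
#' @export
#' @examples
#' wrap_phase(c(-pi, 0, pi, 3 * pi))
wrap_phase <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

#' Circular root-mean-square error between two phase series
#'
#' Differences are wrapped to (-pi, pi] before squaring, so a constant
#' offset of 2*pi contributes nothing.
#'
#' @param est,truth numeric vectors of phases in radians (equal length).
#' @return scalar circular RMSE in radians.
#' @export
circular_rmse <- function(est, truth) {
  stopifnot(length(est) == length(truth))
  d <- wrap_phase(est - truth)
  sqrt(mean(d^2))
}

# shared validation helper: positive finite scalar
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("invalid parameter: `%s` must be a positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

# unwrap a wrapped phase series (inverse of wrap_phase up to the starting turn)
unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  cumsum(c(p[1], dp))
}
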