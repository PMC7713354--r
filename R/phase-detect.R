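# Real-time gait-phase estimation from a thigh IMU: causal Butterworth
# bandpass, amplitude normalization, unit-sine Levenberg-Marquardt fitting on
# a sliding window, atan2 phase extraction, 20-segment discretization.

#' Bandpass filter specification
#'
#' Defaults follow the gait band used on the platform: a single-pass
#' (causal) second-order Butterworth bandpass with cutoffs 0.4 Hz and 3 Hz,
#' bracketing stride frequencies from very slow to fast walking.
#'
#' @param order Butterworth order (per band edge; default 2).
#' @param f_lo,f_hi lower/upper cutoff frequencies, Hz.
#' @return object of class `bandpass_spec`.
#' @export
bandpass_spec <- function(order = 2, f_lo = 0.4, f_hi = 3.0) {
  if (order < 1) stop("invalid parameter: `order` must be >= 1", call. = FALSE)
  if (!(0 < f_lo && f_lo < f_hi)) {
    stop("invalid parameter: need 0 < f_lo < f_hi", call. = FALSE)
  }
  structure(list(order = order, f_lo = f_lo, f_hi = f_hi,
                 pass_mode = "single_pass"),
            class = "bandpass_spec")
}

#' Design the digital Butterworth bandpass
#'
#' @param spec a [bandpass_spec()].
#' @param rate sampling rate, Hz; both edges must lie below the Nyquist
#'   frequency.
#' @return object of class `bandpass_filter` with coefficient vectors `b`
#'   (numerator) and `a` (denominator), the spec, and the design rate.
#' @export
design_bandpass <- function(spec, rate) {
  stopifnot(inherits(spec, "bandpass_spec"))
  check_positive(rate, "rate")
  if (spec$f_hi >= rate / 2) {
    stop("invalid parameter: cutoff at or above Nyquist frequency", call. = FALSE)
  }
  bt <- signal::butter(spec$order, c(spec$f_lo, spec$f_hi) / (rate / 2),
                       type = "pass")
  structure(list(b = as.numeric(bt$b), a = as.numeric(bt$a), spec = spec,
                 rate = rate),
            class = "bandpass_filter")
}

#' Complex frequency response of a designed digital filter
#'
#' @param filt a `bandpass_filter` (or any list with `b`, `a`, `rate`).
#' @param f frequencies in Hz.
#' @param squared if `TRUE`, return the response of the dual-pass
#'   (forward-backward) application, i.e. `|H|^2` with zero phase.
#' @return complex vector `H(f)`.
#' @export
freq_response <- function(filt, f, squared = FALSE) {
  z <- exp(-1i * 2 * pi * f / filt$rate)
  num <- vapply(z, function(zz) sum(filt$b * zz^(seq_along(filt$b) - 1)),
                complex(1))
  den <- vapply(z, function(zz) sum(filt$a * zz^(seq_along(filt$a) - 1)),
                complex(1))
  H <- num / den
  if (squared) Mod(H)^2 + 0i else H
}

# warm-up duration (s) required before filtering: three periods of the
# geometric mid-band frequency
filter_warmup_s <- function(spec) 3 / sqrt(spec$f_lo * spec$f_hi)

# resample an imu_series to a uniform grid at nominal_rate if timestamp
# jitter exceeds 5% of the nominal interval
ensure_uniform <- function(series, jitter_tol = 0.05) {
  dt0 <- 1 / series$nominal_rate
  dts <- diff(series$t)
  if (length(dts) == 0 || all(abs(dts - dt0) <= jitter_tol * dt0)) {
    return(series)
  }
  tu <- seq(series$t[1], series$t[length(series$t)], by = dt0)
  interp <- function(y) stats::approx(series$t, y, xout = tu)$y
  imu_series(tu, interp(series$hip_flexion), interp(series$hip_angvel),
             if (is.null(series$torso_yaw)) NULL else interp(series$torso_yaw),
             series$nominal_rate)
}

#' Causally bandpass-filter an IMU series
#'
#' Single-pass (forward-only) filtering of the flexion and angular-velocity
#' channels, as run on the platform in real time. The bandpass removes the
#' DC flexion offset. Non-uniform timestamps are resampled to the nominal
#' rate by linear interpolation first.
#'
#' @param series an [imu_series()].
#' @param spec a [bandpass_spec()].
#' @return the filtered `imu_series` (torso yaw passed through), with the
#'   designed filter attached as attribute `"filter"`.
#' @export
filter_single_pass <- function(series, spec = bandpass_spec()) {
  stopifnot(inherits(series, "imu_series"))
  series <- ensure_uniform(series)
  span <- series$t[length(series$t)] - series$t[1]
  if (span < filter_warmup_s(spec)) {
    stop(sprintf(
      "insufficient data: %.2f s given, >= %.2f s (three mid-band periods) required",
      span, filter_warmup_s(spec)), call. = FALSE)
  }
  filt <- design_bandpass(spec, series$nominal_rate)
  run <- function(y) as.numeric(signal::filter(filt$b, filt$a, y))
  out <- imu_series(series$t, run(series$hip_flexion), run(series$hip_angvel),
                    series$torso_yaw, series$nominal_rate)
  attr(out, "filter") <- filt
  out
}

#' Fit a unit sine wave to a flexion/velocity window
#'
#' Joint Levenberg-Marquardt least squares over frequency and phase offset of
#' the model `flexion ~ sin(2*pi*f*(t - t_ref) + phi)`,
#' `velocity ~ cos(2*pi*f*(t - t_ref) + phi)`, both channels already
#' amplitude-normalized to unit scale. The shared parameters make the
#' atan2-based phase of the two channels mutually consistent.
#'
#' @param t window time stamps, seconds.
#' @param flexion,velocity normalized window samples.
#' @param init list with starting `freq` (Hz) and `phase_offset` (radians,
#'   referred to `t[1]`); typically the previous window's fit.
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @return object of class `sine_fit`: `freq`, `phase_offset` (radians in
#'   (-pi, pi], referred to `t_ref = t[1]`), `residual_rms`, `window_span`,
#'   `converged`. Non-convergence and degenerate windows return
#'   `converged = FALSE` with the last iterate, never an error.
#' @export
fit_unit_sine <- function(t, flexion, velocity,
                          init = list(freq = 1, phase_offset = 0),
                          max_iter = 50) {
  t_ref <- t[1]
  tc <- t - t_ref
  span <- tc[length(tc)]
  degenerate <- stats::sd(flexion) < 1e-9 && stats::sd(velocity) < 1e-9
  if (degenerate) {
    return(structure(list(freq = init$freq, phase_offset = init$phase_offset,
                          residual_rms = sqrt(mean(flexion^2 + velocity^2) / 1),
                          window_span = span, t_ref = t_ref,
                          converged = FALSE),
                     class = "sine_fit"))
  }
  resid_fn <- function(p) {
    arg <- 2 * pi * p[1] * tc + p[2]
    c(flexion - sin(arg), velocity - cos(arg))
  }
  jac_fn <- function(p) {
    arg <- 2 * pi * p[1] * tc + p[2]
    ca <- cos(arg); sa <- sin(arg)
    rbind(cbind(-ca * 2 * pi * tc, -ca), cbind(sa * 2 * pi * tc, sa))
  }
  fit <- minpack.lm::nls.lm(
    par = c(init$freq, wrap_phase(init$phase_offset)),
    fn = resid_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(maxiter = max_iter))
  p <- fit$par
  ok <- fit$info %in% 1:3 && p[1] > 0
  structure(list(freq = abs(p[1]), phase_offset = wrap_phase(p[2]),
                 residual_rms = sqrt(mean(resid_fn(p)^2)),
                 window_span = span, t_ref = t_ref, converged = ok),
            class = "sine_fit")
}

#' @export
print.sine_fit <- function(x, ...) {
  cat(sprintf("sine_fit: f = %.4f Hz, phi0 = %.4f rad, rms = %.4g, %s\n",
              x$freq, x$phase_offset, x$residual_rms,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# initial stride-frequency guess from up-crossings of the filtered velocity
# within the first `init_s` seconds (causal, cheap)
initial_frequency <- function(t, vel, spec, init_s = 4) {
  keep <- t - t[1] <= init_s
  tv <- t[keep]; v <- vel[keep]
  up <- which(v[-length(v)] < 0 & v[-1] >= 0)
  if (length(up) >= 2) {
    tc <- tv[up] + (tv[up + 1] - tv[up]) * (-v[up]) / (v[up + 1] - v[up])
    1 / mean(diff(tc))
  } else {
    sqrt(spec$f_lo * spec$f_hi)
  }
}

#' Phase-estimator configuration
#'
#' @param window_periods sliding-window length in estimated fundamental
#'   periods (default 1.5).
#' @param refit_interval_s how often the unit-sine fit is refreshed (s);
#'   between refits the phase is advanced at the fitted frequency.
#' @param method `"fit"` evaluates the phase from the fitted unit sine
#'   (atan2 of the fitted sine and cosine, i.e. the model phase);
#'   `"atan2"` applies atan2 to the normalized filtered signals directly.
#' @param compensate_lag subtract the designed filter's known phase response
#'   at the fitted frequency (both channels share it, so it appears as a
#'   pure phase offset).
#' @param norm_quantile robust amplitude = this quantile of |window samples|.
#' @param warmup_periods periods of the initial frequency guess to discard
#'   before the first fit.
#' @return list of class `phase_fit_config`.
#' @export
phase_fit_config <- function(window_periods = 1.5, refit_interval_s = 0.05,
                             method = c("fit", "atan2"),
                             compensate_lag = TRUE, norm_quantile = 0.9,
                             warmup_periods = 2) {
  structure(list(window_periods = window_periods,
                 refit_interval_s = refit_interval_s,
                 method = match.arg(method),
                 compensate_lag = compensate_lag,
                 norm_quantile = norm_quantile,
                 warmup_periods = warmup_periods),
            class = "phase_fit_config")
}

#' Estimate continuous gait phase from an IMU series
#'
#' Causal pipeline: bandpass filter both channels, normalize amplitudes with
#' a running robust scale, fit a unit sine (shared frequency and phase
#' offset, flexion -> sine, angular velocity -> cosine) on a trailing window
#' by Levenberg-Marquardt, and emit the four-quadrant inverse tangent of the
#' fitted flexion over the angular velocity, wrapped to (-pi, pi]. Each
#' output sample uses only past samples.
#'
#' @param series an [imu_series()].
#' @param spec a [bandpass_spec()].
#' @param config a [phase_fit_config()].
#' @return object of class `phase_series`: `t`, `phase` (radians, (-pi, pi],
#'   `NA` during warm-up), `segment` (0-19, `NA` during warm-up), `freq`
#'   (per-sample fitted frequency), `fits` (data frame of window fits),
#'   `warmup_n`, and the config used.
#' @export
estimate_phase <- function(series, spec = bandpass_spec(),
                           config = phase_fit_config()) {
  filtered <- filter_single_pass(series, spec)
  filt <- attr(filtered, "filter")
  t <- filtered$t
  n <- length(t)
  rate <- filtered$nominal_rate
  flex <- filtered$hip_flexion
  vel <- filtered$hip_angvel

  f0 <- initial_frequency(t, vel, spec)
  f0 <- min(max(f0, spec$f_lo), spec$f_hi)
  win_n <- max(8L, round(config$window_periods / f0 * rate))
  warm_n <- max(win_n, round(config$warmup_periods / f0 * rate))
  if (warm_n >= n) {
    stop("insufficient data: series shorter than estimator warm-up", call. = FALSE)
  }
  stride <- max(1L, round(config$refit_interval_s * rate))
  fit_idx <- seq(warm_n, n, by = stride)
  if (fit_idx[length(fit_idx)] < n) fit_idx <- c(fit_idx, n)

  phase <- rep(NA_real_, n)
  freq <- rep(NA_real_, n)
  fits <- vector("list", length(fit_idx))
  prev <- list(freq = f0, phase_offset = 0)
  prev_fit <- NULL

  for (k in seq_along(fit_idx)) {
    i <- fit_idx[k]
    wi <- max(1L, i - win_n + 1L):i
    tw <- t[wi]
    a_flex <- stats::quantile(abs(flex[wi]), config$norm_quantile, names = FALSE)
    a_vel <- stats::quantile(abs(vel[wi]), config$norm_quantile, names = FALSE)
    a_flex <- max(a_flex, 1e-12); a_vel <- max(a_vel, 1e-12)
    fw <- flex[wi] / a_flex
    vw <- vel[wi] / a_vel
    # warm start: previous fit propagated to the new window origin
    init <- if (is.null(prev_fit)) {
      list(freq = prev$freq,
           phase_offset = atan2(fw[1], vw[1]))
    } else {
      list(freq = prev_fit$freq,
           phase_offset = 2 * pi * prev_fit$freq * (tw[1] - prev_fit$t_ref) +
             prev_fit$phase_offset)
    }
    ft <- fit_unit_sine(tw, fw, vw, init = init)
    if (!ft$converged && !is.null(prev_fit)) ft <- prev_fit  # fall back
    fits[[k]] <- ft

    # emit phase for samples from the previous fit index (exclusive) to i
    lo <- if (k == 1) max(1L, i - stride + 1L) else fit_idx[k - 1] + 1L
    out_i <- lo:i
    lag <- if (config$compensate_lag) Arg(freq_response(filt, ft$freq)) else 0
    if (config$method == "fit") {
      raw <- 2 * pi * ft$freq * (t[out_i] - ft$t_ref) + ft$phase_offset
    } else {
      raw <- atan2(flex[out_i] / a_flex, vel[out_i] / a_vel)
    }
    phase[out_i] <- wrap_phase(raw - lag)
    freq[out_i] <- ft$freq
    prev_fit <- ft
  }

  fits_df <- data.frame(
    i = fit_idx,
    t = t[fit_idx],
    freq = vapply(fits, `[[`, numeric(1), "freq"),
    phase_offset = vapply(fits, `[[`, numeric(1), "phase_offset"),
    residual_rms = vapply(fits, `[[`, numeric(1), "residual_rms"),
    converged = vapply(fits, `[[`, logical(1), "converged"))

  structure(list(t = t, phase = phase,
                 segment = discretize_phase(phase),
                 freq = freq, fits = fits_df,
                 warmup_n = warm_n, config = config, spec = spec),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  ok <- !is.na(x$phase)
  cat(sprintf(
    "phase_series: %d samples (%d warm-up), median f = %.3f Hz, %d window fits\n",
    length(x$t), x$warmup_n, stats::median(x$freq[ok]), nrow(x$fits)))
  invisible(x)
}

#' Discretize a continuous gait phase into 20 equal segments
#'
#' The interval (-pi, pi] is partitioned into twenty equal half-open bins
#' `[lo, hi)` of width pi/10; segment `0` starts at `-pi` and the single
#' point `phase = pi` closes the last bin (segment 19). Inputs outside
#' (-pi, pi] are wrapped first, never an error.
#'
#' @param phase numeric vector of phases in radians.
#' @return integer vector of segment indices 0-19.
#' @export
discretize_phase <- function(phase) {
  p <- wrap_phase(phase)
  seg <- as.integer(floor((p + pi) / (pi / 10)))
  seg[which(seg > 19L)] <- 19L
  seg
}

#' Centre phase of a discretization segment
#'
#' @param segment integer 0-19.
#' @return wrapped phase at the centre of the segment.
#' @export
segment_centre <- function(segment) {
  stopifnot(all(segment %in% 0:19))
  wrap_phase(-pi + (segment + 0.5) * pi / 10)
}

#' Phase-portrait circularity score
#'
#' Ratio of the minimum to the maximum radial distance of the normalized
#' (flexion, angular velocity) trajectory from its centroid: 1 for a perfect
#' circle, 0 for a collapsed (straight-line) portrait. A circular portrait
#' is what makes the atan2 phase progress linearly in time.
#'
#' @param flexion,velocity filtered channel samples covering at least one
#'   full cycle.
#' @param norm_quantile robust amplitude-normalization quantile.
#' @return score in `[0, 1]`.
#' @export
phase_portrait_circularity <- function(flexion, velocity,
                                       norm_quantile = 0.9) {
  if (stats::sd(flexion) < 1e-12 && stats::sd(velocity) < 1e-12) return(0)
  x <- flexion / max(stats::quantile(abs(flexion), norm_quantile), 1e-12)
  y <- velocity / max(stats::quantile(abs(velocity), norm_quantile), 1e-12)
  r <- sqrt((x - mean(x))^2 + (y - mean(y))^2)
  if (max(r) < 1e-12) return(0)
  min(r) / max(r)
}

#' Remove torso heading from a thigh IMU series
#'
#' Re-expresses the thigh angular quantities in the torso-referenced
#' sagittal plane by subtracting the torso yaw excursion (and its rate) from
#' the flexion (and angular-velocity) channels. Identity when the torso yaw
#' is constant. If no torso yaw channel is present the series is passed
#' through with a warning.
#'
#' @param series an [imu_series()].
#' @return the compensated `imu_series` (torso yaw retained).
#' @export
heading_compensate <- function(series) {
  stopifnot(inherits(series, "imu_series"))
  if (is.null(series$torso_yaw)) {
    warning("no torso_yaw channel; returning series unchanged")
    return(series)
  }
  yaw_exc <- series$torso_yaw - series$torso_yaw[1]
  dt <- diff(series$t)
  yaw_rate <- c(0, diff(series$torso_yaw) / dt)
  imu_series(series$t, series$hip_flexion - yaw_exc,
             series$hip_angvel - yaw_rate,
             series$torso_yaw, series$nominal_rate)
}
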