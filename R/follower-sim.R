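# Kinematic simulation of the subject follower: pinhole depth-centroid
# observation, two PD loops (distance hold at 50 cm and re-centring), and
# differential-drive mixing. Validates setpoint behaviour without hardware.

#' Pinhole camera model for the follower's depth sensor
#'
#' @param fov_deg horizontal field of view, degrees (default 86).
#' @param n_cols number of pixel columns (default 848).
#' @param quantize round the subject's image position to whole pixel
#'   columns.
#' @return object of class `camera_model` (focal length in pixels derived
#'   from the field of view).
#' @export
camera_model <- function(fov_deg = 86, n_cols = 848, quantize = TRUE) {
  check_positive(fov_deg, "fov_deg")
  check_positive(n_cols, "n_cols")
  fx <- (n_cols / 2) / tan(fov_deg / 2 * pi / 180)
  structure(list(fov_deg = fov_deg, n_cols = n_cols, fx = fx,
                 cx = (n_cols + 1) / 2, quantize = quantize),
            class = "camera_model")
}

#' PD controller gains for the follower
#'
#' Two decoupled loops: the forward loop holds the camera-to-subject
#' distance at the 50 cm setpoint, the turning loop re-centres the subject
#' by driving the wheels differentially. Default gains give a smooth
#' non-oscillatory closed loop at the 30 Hz camera rate.
#'
#' @param kp_d,kd_d forward-loop proportional (1/s) and derivative gains.
#' @param kp_th,kd_th turning-loop gains.
#' @param setpoint_d distance setpoint, metres (default 0.50).
#' @param v_max,omega_max command saturation limits (m/s, rad/s).
#' @return object of class `pd_gains`.
#' @export
pd_gains <- function(kp_d = 2.0, kd_d = 0.2, kp_th = 1.5, kd_th = 0.1,
                     setpoint_d = 0.50, v_max = 2.0, omega_max = 2.0) {
  if (any(c(kp_d, kd_d, kp_th, kd_th) < 0)) {
    stop("invalid parameter: gains must be >= 0", call. = FALSE)
  }
  check_positive(setpoint_d, "setpoint_d")
  structure(list(kp_d = kp_d, kd_d = kd_d, kp_th = kp_th, kd_th = kd_th,
                 setpoint_d = setpoint_d, v_max = v_max,
                 omega_max = omega_max),
            class = "pd_gains")
}

#' Platform state of the differential-drive follower
#'
#' @param x,y position, metres.
#' @param heading radians.
#' @param v forward speed, m/s.
#' @param omega turn rate, rad/s.
#' @param track_width wheel separation, metres.
#' @return object of class `platform_state`; wheel speeds are kept
#'   consistent with `v = (left + right)/2`,
#'   `omega = (right - left)/track_width`.
#' @export
platform_state <- function(x = 0, y = 0, heading = 0, v = 0, omega = 0,
                           track_width = 0.6) {
  structure(list(x = x, y = y, heading = heading, v = v, omega = omega,
                 track_width = track_width,
                 wheel_speeds = mix_drive(v, omega, track_width)),
            class = "platform_state")
}

#' Observe the subject through the depth camera
#'
#' The (point) subject is projected through the pinhole model; `d` is the
#' depth along the platform's forward axis (the mean depth of the subject's
#' pixels — exact for a point subject) and `theta` the angle of the
#' subject's mean pixel column off the forward axis, recovered through the
#' camera's angular resolution.
#'
#' @param subject_xy numeric length-2, subject position in world frame.
#' @param state a [platform_state()].
#' @param cam a [camera_model()].
#' @return list `d` (m), `theta` (rad), `visible` (logical); when the
#'   subject is out of view `d` and `theta` are `NA` and `visible = FALSE`.
#' @export
observe_subject <- function(subject_xy, state, cam = camera_model()) {
  dx <- subject_xy[1] - state$x
  dy <- subject_xy[2] - state$y
  fwd <- cos(state$heading) * dx + sin(state$heading) * dy
  lat <- -sin(state$heading) * dx + cos(state$heading) * dy
  ang <- atan2(lat, fwd)
  half_fov <- cam$fov_deg / 2 * pi / 180
  if (fwd <= 0 || abs(ang) > half_fov) {
    return(list(d = NA_real_, theta = NA_real_, visible = FALSE))
  }
  u <- cam$cx + cam$fx * (lat / fwd)
  if (cam$quantize) u <- round(u)
  theta <- atan((u - cam$cx) / cam$fx)
  list(d = fwd, theta = theta, visible = TRUE)
}

#' One PD control step
#'
#' `forward_cmd = kp_d (d - setpoint) + kd_d * d(d)/dt`;
#' `turn_cmd = kp_th * theta + kd_th * d(theta)/dt` (derivatives on the
#' measurements). Commands are saturated at the configured limits. A
#' positive forward command advances the platform (issued when the subject
#' is farther than the setpoint).
#'
#' @param obs,prev_obs current and previous observations (lists with `d`,
#'   `theta`); `prev_obs` may be `NULL` (derivative terms drop out).
#' @param gains a [pd_gains()].
#' @param dt control interval, seconds.
#' @return list `forward_cmd` (m/s), `turn_cmd` (rad/s).
#' @export
pd_step <- function(obs, prev_obs, gains, dt) {
  check_positive(dt, "dt")
  dd <- if (is.null(prev_obs) || is.na(prev_obs$d)) 0 else (obs$d - prev_obs$d) / dt
  dth <- if (is.null(prev_obs) || is.na(prev_obs$theta)) 0 else
    (obs$theta - prev_obs$theta) / dt
  fwd <- gains$kp_d * (obs$d - gains$setpoint_d) + gains$kd_d * dd
  trn <- gains$kp_th * obs$theta + gains$kd_th * dth
  list(forward_cmd = max(-gains$v_max, min(gains$v_max, fwd)),
       turn_cmd = max(-gains$omega_max, min(gains$omega_max, trn)))
}

#' Mix forward and turn commands into wheel speeds
#'
#' `left = forward - turn * track/2`, `right = forward + turn * track/2`:
#' a pure turn command yields equal-and-opposite wheel speeds (rotation
#' with zero turning radius), and the mixing is a linear bijection.
#'
#' @param forward_cmd m/s.
#' @param turn_cmd rad/s.
#' @param track_width wheel separation, metres.
#' @return named numeric `c(left, right)` in m/s.
#' @export
mix_drive <- function(forward_cmd, turn_cmd, track_width = 0.6) {
  c(left = forward_cmd - turn_cmd * track_width / 2,
    right = forward_cmd + turn_cmd * track_width / 2)
}

#' Recover forward/turn commands from wheel speeds
#'
#' @param wheel_speeds named numeric `c(left, right)`.
#' @param track_width wheel separation, metres.
#' @return list `forward_cmd`, `turn_cmd`.
#' @export
unmix_drive <- function(wheel_speeds, track_width = 0.6) {
  list(forward_cmd = unname((wheel_speeds[1] + wheel_speeds[2]) / 2),
       turn_cmd = unname((wheel_speeds[2] - wheel_speeds[1]) / track_width))
}

#' Simulate the closed-loop subject follower
#'
#' Forward-Euler integration of the platform kinematics under the two PD
#' loops at the camera rate. If the subject leaves the field of view the
#' last command is held for `hold_s` seconds, after which the platform
#' stops. Divergence (the distance error tripling over a trailing window)
#' raises an instability flag on the returned trace.
#'
#' @param subject_trajectory data frame `t`, `x`, `y` (subject position in
#'   the world frame), or a single `c(x, y)` for a stationary subject.
#' @param gains a [pd_gains()].
#' @param dt integration/control interval, s (default 1/30, the camera
#'   frame interval).
#' @param duration simulated time, s.
#' @param state0 initial [platform_state()].
#' @param cam a [camera_model()].
#' @param hold_s lost-target command-hold time, s.
#' @return data frame trace (`t`, `x`, `y`, `heading`, `d`, `theta`,
#'   `forward_cmd`, `turn_cmd`, `left`, `right`, `visible`) with attributes
#'   `"unstable"` and `"lost_target"`.
#' @export
simulate_follower <- function(subject_trajectory, gains = pd_gains(),
                              dt = 1 / 30, duration = 20,
                              state0 = platform_state(x = -1.5),
                              cam = camera_model(), hold_s = 0.5) {
  check_positive(duration, "duration")
  if (is.numeric(subject_trajectory) && length(subject_trajectory) == 2) {
    subj_at <- function(tt) subject_trajectory
  } else {
    st <- subject_trajectory
    subj_at <- function(tt) {
      c(stats::approx(st$t, st$x, xout = tt, rule = 2)$y,
        stats::approx(st$t, st$y, xout = tt, rule = 2)$y)
    }
  }
  n <- floor(duration / dt) + 1L
  tr <- data.frame(t = (seq_len(n) - 1) * dt, x = NA_real_, y = NA_real_,
                   heading = NA_real_, d = NA_real_, theta = NA_real_,
                   forward_cmd = 0, turn_cmd = 0, left = 0, right = 0,
                   visible = TRUE)
  s <- state0
  prev_obs <- NULL
  last_cmd <- list(forward_cmd = 0, turn_cmd = 0)
  lost_since <- NA_real_
  lost_any <- FALSE
  for (i in seq_len(n)) {
    tt <- tr$t[i]
    obs <- observe_subject(subj_at(tt), s, cam)
    if (obs$visible) {
      cmd <- pd_step(obs, prev_obs, gains, dt)
      prev_obs <- obs
      last_cmd <- cmd
      lost_since <- NA_real_
    } else {
      lost_any <- TRUE
      if (is.na(lost_since)) lost_since <- tt
      cmd <- if (tt - lost_since <= hold_s) last_cmd else
        list(forward_cmd = 0, turn_cmd = 0)
    }
    ws <- mix_drive(cmd$forward_cmd, cmd$turn_cmd, s$track_width)
    tr[i, c("x", "y", "heading", "d", "theta")] <-
      c(s$x, s$y, s$heading, obs$d, obs$theta)
    tr$forward_cmd[i] <- cmd$forward_cmd
    tr$turn_cmd[i] <- cmd$turn_cmd
    tr$left[i] <- ws[1]; tr$right[i] <- ws[2]
    tr$visible[i] <- obs$visible
    # kinematic update
    s$x <- s$x + cmd$forward_cmd * cos(s$heading) * dt
    s$y <- s$y + cmd$forward_cmd * sin(s$heading) * dt
    s$heading <- s$heading + cmd$turn_cmd * dt
    s$v <- cmd$forward_cmd
    s$omega <- cmd$turn_cmd
  }
  err <- abs(tr$d - gains$setpoint_d)
  win <- max(10L, round(2 / dt))
  unstable <- FALSE
  if (n > 2 * win) {
    e0 <- stats::median(err[seq_len(win)], na.rm = TRUE)
    e1 <- stats::median(err[(n - win + 1):n], na.rm = TRUE)
    unstable <- is.finite(e0) && is.finite(e1) && e0 > 1e-6 && e1 > 3 * e0
  }
  attr(tr, "unstable") <- unstable
  attr(tr, "lost_target") <- lost_any
  tr
}
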