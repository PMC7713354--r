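# Synthetic gait generation: multi-speed quasi-sinusoidal hip kinematics with
# ground-truth phase and events, stylized perturbation responses, and smooth
# Gaussian null waveform datasets.

# Phase convention used throughout the generator: the continuous gait phase
# advances by 2*pi per stride; heel strike of the instrumented (left) leg is
# pinned at wrapped phase +pi/2, toe-off follows 60% of a cycle later.
PHASE_AT_HS <- pi / 2
STANCE_FRACTION <- 0.6

# run expr-free deterministic RNG: returns a restore closure for on.exit()
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Walking-trial generator parameters
#'
#' Bundles the knobs of the synthetic walking generator. Defaults describe a
#' healthy adult at self-selected speed: cadence 55 strides/min, forward speed
#' 1.25 m/s, hip flexion oscillating 30 deg about a 5 deg offset with a mild
#' second harmonic (the phase portrait is deliberately non-circular, as real
#' hip kinematics are).
#'
#' @param speed_label one of `"slow"`, `"normal"`, `"fast"`; sets cadence and
#'   speed defaults (40/55/70 strides per minute, 0.90/1.25/1.60 m/s).
#' @param cadence strides per minute (one stride = one full gait cycle of a
#'   leg). Overrides the label default if given.
#' @param speed forward walking speed in m/s.
#' @param duration trial length in seconds.
#' @param sample_rate IMU sampling rate in Hz (default 333).
#' @param flexion_amplitude fundamental hip-flexion amplitude in degrees.
#' @param flexion_offset mean hip-flexion angle in degrees.
#' @param noise_sd additive Gaussian noise SD on the flexion channel, degrees.
#'   Velocity-channel noise is scaled by the fundamental angular frequency so
#'   both channels keep a comparable signal-to-noise ratio.
#' @param harmonic_weights relative weights of the sine harmonics; the first
#'   entry (fundamental) is normalized to 1.
#' @param heading_profile function of time (s) returning torso heading in
#'   degrees; default constant 0 (straight walking).
#' @param phase0 unwrapped phase at t = 0 in radians; defaults to the
#'   heel-strike phase so trials start at a left heel strike.
#' @param seed integer RNG seed; the generator is a pure function of
#'   (params, seed).
#' @return object of class `walk_params`.
#' @export
walk_params <- function(speed_label = c("normal", "slow", "fast"),
                        cadence = NULL,
                        speed = NULL,
                        duration = 30,
                        sample_rate = 333,
                        flexion_amplitude = 30,
                        flexion_offset = 5,
                        noise_sd = 1.0,
                        harmonic_weights = c(1, 0.15),
                        heading_profile = function(t) rep(0, length(t)),
                        phase0 = PHASE_AT_HS,
                        seed = 1L) {
  speed_label <- match.arg(speed_label)
  defaults <- list(slow = c(40, 0.90), normal = c(55, 1.25), fast = c(70, 1.60))
  if (is.null(cadence)) cadence <- defaults[[speed_label]][1]
  if (is.null(speed)) speed <- defaults[[speed_label]][2]
  check_positive(cadence, "cadence")
  check_positive(duration, "duration")
  check_positive(sample_rate, "sample_rate")
  check_positive(speed, "speed")
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("invalid parameter: `noise_sd` must be >= 0", call. = FALSE)
  }
  if (length(harmonic_weights) < 1 || harmonic_weights[1] <= 0) {
    stop("invalid parameter: `harmonic_weights[1]` (fundamental) must be > 0",
         call. = FALSE)
  }
  structure(list(
    speed_label = speed_label, cadence = cadence, speed = speed,
    duration = duration, sample_rate = sample_rate,
    flexion_amplitude = flexion_amplitude, flexion_offset = flexion_offset,
    noise_sd = noise_sd,
    harmonic_weights = harmonic_weights / harmonic_weights[1],
    heading_profile = heading_profile, phase0 = phase0,
    seed = as.integer(seed)
  ), class = "walk_params")
}

#' @export
print.walk_params <- function(x, ...) {
  cat(sprintf("walk_params: %s walk, %.0f strides/min, %.2f m/s, %.1f s @ %.0f Hz\n",
              x$speed_label, x$cadence, x$speed, x$duration, x$sample_rate))
  cat(sprintf("  flexion %g deg about %g deg, noise sd %g deg, %d harmonic(s), seed %d\n",
              x$flexion_amplitude, x$flexion_offset, x$noise_sd,
              length(x$harmonic_weights), x$seed))
  invisible(x)
}

#' IMU series container
#'
#' A timestamped stream of sagittal hip flexion angle and hip angular
#' velocity, optionally with torso yaw for heading compensation.
#'
#' @param t time stamps in seconds, strictly increasing.
#' @param hip_flexion sagittal hip flexion angle, degrees.
#' @param hip_angvel hip angular velocity, deg/s.
#' @param torso_yaw optional torso heading, degrees.
#' @param nominal_rate nominal sampling rate, Hz.
#' @return object of class `imu_series`.
#' @export
imu_series <- function(t, hip_flexion, hip_angvel, torso_yaw = NULL,
                       nominal_rate) {
  n <- length(t)
  if (length(hip_flexion) != n || length(hip_angvel) != n ||
      (!is.null(torso_yaw) && length(torso_yaw) != n)) {
    stop("imu_series: all channels must share the time base", call. = FALSE)
  }
  if (n > 1 && any(diff(t) <= 0)) {
    stop("imu_series: `t` must be strictly increasing", call. = FALSE)
  }
  check_positive(nominal_rate, "nominal_rate")
  structure(list(t = as.numeric(t), hip_flexion = as.numeric(hip_flexion),
                 hip_angvel = as.numeric(hip_angvel),
                 torso_yaw = if (is.null(torso_yaw)) NULL else as.numeric(torso_yaw),
                 nominal_rate = nominal_rate),
            class = "imu_series")
}

#' @export
print.imu_series <- function(x, ...) {
  cat(sprintf("imu_series: %d samples @ %.0f Hz nominal, %.2f s span%s\n",
              length(x$t), x$nominal_rate, diff(range(x$t)),
              if (is.null(x$torso_yaw)) "" else ", with torso yaw"))
  invisible(x)
}

#' Gait-event table
#'
#' @param leg character vector, `"L"` or `"R"`.
#' @param event character vector, `"HS"` (heel strike) or `"TO"` (toe off).
#' @param time_s event times in seconds.
#' @return a `data.frame` of class `gait_events`, ordered by time.
#' @export
gait_events <- function(leg, event, time_s) {
  stopifnot(all(leg %in% c("L", "R")), all(event %in% c("HS", "TO")))
  ev <- data.frame(leg = leg, event = event, time_s = as.numeric(time_s),
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$time_s), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("gait_events", "data.frame")
  ev
}

# event times of one leg/type
event_times <- function(events, leg, type) {
  events$time_s[events$leg == leg & events$event == type]
}

# periodic Gaussian bump in cycle fraction p (period 1), centre c, width w
cycle_bump <- function(p, centre, width) {
  d <- (p - centre) %% 1
  d <- ifelse(d > 0.5, d - 1, d)
  exp(-0.5 * (d / width)^2)
}

# stylized joint-angle templates as functions of cycle fraction (HS at p = 0,
# TO at p = 0.6); amplitudes in degrees, shapes qualitative sagittal gait
joint_templates <- function(p, flexion_amplitude, flexion_offset, weights) {
  theta <- 2 * pi * p + PHASE_AT_HS
  hip <- flexion_offset + flexion_amplitude *
    Reduce(`+`, lapply(seq_along(weights),
                       function(k) weights[k] * sin(k * theta)))
  knee <- 4 + 14 * cycle_bump(p, 0.15, 0.07) + 58 * cycle_bump(p, 0.73, 0.09)
  ankle <- -3 + 8 * cycle_bump(p, 0.45, 0.10) - 12 * cycle_bump(p, 0.63, 0.05) +
    3 * cycle_bump(p, 0.85, 0.08)
  data.frame(hip = hip, knee = knee, ankle = ankle)
}

# heel forward velocity (m/s) as a function of cycle fraction: zero in stance,
# raised-cosine bump over the 40% swing window, integrating to one stride
# length (speed / stride frequency) per cycle
heel_velocity <- function(p, speed) {
  swing <- p >= STANCE_FRACTION
  u <- (p - STANCE_FRACTION) / (1 - STANCE_FRACTION)
  ifelse(swing, (speed / (1 - STANCE_FRACTION)) * (1 - cos(2 * pi * u)), 0)
}

#' Generate a synthetic walking trial
#'
#' Produces a noisy quasi-sinusoidal hip-flexion/angular-velocity IMU stream,
#' the ground-truth continuous gait phase, heel-strike/toe-off events tied to
#' fixed phase values (stance = 60% of the stride by construction), per-leg
#' hip/knee/ankle joint trajectories, and heel forward positions.
#'
#' The angular-velocity channel is the analytic time derivative of the
#' noiseless flexion signal plus independent Gaussian noise. When the heading
#' profile is non-constant, the measured IMU channels are contaminated by
#' additive yaw leakage (the single-thigh-IMU failure mode that torso-yaw
#' compensation removes).
#'
#' @param params a [walk_params()] object.
#' @param condition trial condition label (`"NW"`, `"SW"`, `"MS"`, `"TS"`,
#'   `"SL"`); purely a label at generation time.
#' @param subject_id subject label.
#' @return object of class `synthetic_trial` with elements `imu`,
#'   `truth_phase` (wrapped, radians), `truth_phase_unwrapped`, `events`,
#'   `joints` (list `L`/`R` of data frames `t`, `hip`, `knee`, `ankle`),
#'   `heel_pos` (data frame `t`, `L`, `R`, metres), `condition`,
#'   `subject_id`, `params`, `perturbation` (`NULL` until injected).
#' @export
generate_walk <- function(params, condition = "NW", subject_id = "S1") {
  stopifnot(inherits(params, "walk_params"))
  restore <- local_seed(params$seed)
  on.exit(restore())

  f <- params$cadence / 60                       # stride frequency, Hz
  dt <- 1 / params$sample_rate
  t <- seq(0, params$duration, by = dt)
  n <- length(t)
  w <- params$harmonic_weights
  A <- params$flexion_amplitude

  theta <- 2 * pi * f * t + params$phase0        # unwrapped truth phase
  flex_true <- params$flexion_offset +
    A * Reduce(`+`, lapply(seq_along(w), function(k) w[k] * sin(k * theta)))
  vel_true <- A * 2 * pi * f *
    Reduce(`+`, lapply(seq_along(w), function(k) k * w[k] * cos(k * theta)))

  yaw <- params$heading_profile(t)
  if (length(yaw) == 1) yaw <- rep(yaw, n)
  yaw_leak <- yaw - yaw[1]
  yaw_rate <- c(0, diff(yaw)) / dt

  flex_meas <- flex_true + yaw_leak + stats::rnorm(n, 0, params$noise_sd)
  vel_meas <- vel_true + yaw_rate +
    stats::rnorm(n, 0, params$noise_sd * 2 * pi * f)
  yaw_meas <- yaw + stats::rnorm(n, 0, 0.1)

  imu <- imu_series(t, flex_meas, vel_meas, yaw_meas, params$sample_rate)

  # events at fixed truth-phase values; left HS at p = 0, stance 60%
  p_left <- ((theta - PHASE_AT_HS) / (2 * pi)) %% 1
  cyc0 <- (params$phase0 - PHASE_AT_HS) / (2 * pi)   # cycles at t = 0
  times_at_fraction <- function(frac, leg_offset) {
    m <- seq(ceiling(cyc0 + leg_offset - frac - 1e-12),
             floor(cyc0 + leg_offset - frac + f * params$duration + 1e-12))
    tt <- (m + frac - leg_offset - cyc0) / f
    tt[tt >= 0 & tt <= params$duration]
  }
  ev <- gait_events(
    leg = c(rep("L", length(times_at_fraction(0, 0))),
            rep("L", length(times_at_fraction(STANCE_FRACTION, 0))),
            rep("R", length(times_at_fraction(0, 0.5))),
            rep("R", length(times_at_fraction(STANCE_FRACTION, 0.5)))),
    event = c(rep("HS", length(times_at_fraction(0, 0))),
              rep("TO", length(times_at_fraction(STANCE_FRACTION, 0))),
              rep("HS", length(times_at_fraction(0, 0.5))),
              rep("TO", length(times_at_fraction(STANCE_FRACTION, 0.5)))),
    time_s = c(times_at_fraction(0, 0), times_at_fraction(STANCE_FRACTION, 0),
               times_at_fraction(0, 0.5),
               times_at_fraction(STANCE_FRACTION, 0.5)))

  p_right <- (p_left + 0.5) %% 1
  joints <- list(
    L = cbind(data.frame(t = t),
              joint_templates(p_left, A, params$flexion_offset, w) +
                matrix(stats::rnorm(3 * n, 0, 0.2), ncol = 3)),
    R = cbind(data.frame(t = t),
              joint_templates(p_right, A, params$flexion_offset, w) +
                matrix(stats::rnorm(3 * n, 0, 0.2), ncol = 3)))

  stride_len <- params$speed / f
  heel <- data.frame(
    t = t,
    L = cumsum(heel_velocity(p_left, params$speed)) * dt,
    R = -stride_len / 2 + cumsum(heel_velocity(p_right, params$speed)) * dt)

  structure(list(imu = imu,
                 truth_phase = wrap_phase(theta),
                 truth_phase_unwrapped = theta,
                 events = ev, joints = joints, heel_pos = heel,
                 condition = condition, subject_id = subject_id,
                 params = params, perturbation = NULL),
            class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("synthetic_trial: %s/%s, %.1f s, %d samples, %d events%s\n",
              x$subject_id, x$condition, x$params$duration, length(x$imu$t),
              nrow(x$events),
              if (is.null(x$perturbation)) "" else
                if (isTRUE(x$perturbation$fired))
                  sprintf(", %s perturbation at %.2f s",
                          x$perturbation$fall_type, x$perturbation$t_on)
                else ", perturbation requested but never fired"))
  invisible(x)
}

#' Inject a stylized perturbation response into a synthetic trial
#'
#' Brake-type falls (elevating, skipping, lowering) arrest the ipsilateral
#' (left) joint kinematics: trajectories are held at their onset values for
#' the activation duration starting at the first sample whose ground-truth
#' phase enters the onset segment, then blended into a recovery template
#' (lowered perturbed leg, widened contralateral swing). The slip fall adds a
#' forward velocity impulse to the perturbed heel with a flat-foot ankle hold
#' and shortens the contralateral recovery step.
#'
#' These are stylized kinematic shapes, not dynamics simulations: the intent
#' is trajectories whose statistics the analysis stack can detect, not
#' biofidelic falls.
#'
#' @param trial a `synthetic_trial`.
#' @param fall a [fall_config()] (or one row of [default_fall_table()]).
#' @param onset_phase wrapped phase (radians, in (-pi, pi]) whose segment
#'   gates the onset; defaults to the segment centre implied by
#'   `fall$target_segment`.
#' @param after_time only segment entries at or after this time (s) are
#'   considered, mirroring a trigger request issued mid-trial.
#' @return the modified `synthetic_trial`; `$perturbation` records onset and
#'   window. If the onset segment is never entered, the trial is returned
#'   unmodified with `perturbation$fired = FALSE` and a warning.
#' @export
inject_perturbation <- function(trial, fall, onset_phase = NULL,
                                after_time = 0) {
  stopifnot(inherits(trial, "synthetic_trial"))
  if (is.null(onset_phase)) onset_phase <- segment_centre(fall$target_segment)
  if (onset_phase <= -pi || onset_phase > pi) {
    stop("invalid parameter: `onset_phase` must lie in (-pi, pi]", call. = FALSE)
  }
  dur_s <- fall$activation_ms / 1000
  if (dur_s < 0) stop("invalid parameter: negative activation", call. = FALSE)
  if (dur_s == 0) {
    trial$perturbation <- list(fired = FALSE, reason = "zero duration")
    return(trial)
  }

  seg <- discretize_phase(onset_phase)
  segs <- discretize_phase(trial$truth_phase)
  entries <- which(segs[-1] == seg & segs[-length(segs)] != seg) + 1L
  entries <- entries[trial$imu$t[entries] >= after_time]
  if (length(entries) == 0) {
    warning("onset segment never entered within trial; perturbation not injected")
    trial$perturbation <- list(fired = FALSE, reason = "segment never entered")
    return(trial)
  }
  i0 <- entries[1]
  rate <- trial$params$sample_rate
  n_hold <- round(dur_s * rate)
  n <- length(trial$imu$t)
  i1 <- min(i0 + n_hold - 1L, n)
  t <- trial$imu$t
  t0 <- t[i0]

  if (fall$mechanism == "brake") {
    hold_idx <- i0:i1
    for (jj in c("hip", "knee", "ankle")) {
      trial$joints$L[[jj]][hold_idx] <- trial$joints$L[[jj]][i0]
    }
    # recovery: exponential return toward nominal with a lowered-leg bias on
    # the perturbed side and a widened contralateral swing
    if (i1 < n) {
      rec <- (i1 + 1L):n
      decay <- exp(-(t[rec] - t[i1]) / 0.4)
      held_gap_knee <- trial$joints$L$knee[i1] - trial$joints$L$knee[rec[1]]
      trial$joints$L$knee[rec] <- trial$joints$L$knee[rec] +
        (held_gap_knee - 8) * decay
      held_gap_hip <- trial$joints$L$hip[i1] - trial$joints$L$hip[rec[1]]
      trial$joints$L$hip[rec] <- trial$joints$L$hip[rec] +
        (held_gap_hip - 5) * decay
      trial$joints$R$hip[rec] <- trial$joints$R$hip[rec] + 6 * decay
    }
  } else {  # slip: forward velocity impulse on the perturbed heel, flat foot
    dt <- 1 / rate
    impulse_v <- 1.5                         # m/s peak slide velocity
    extra_v <- numeric(n)
    act <- i0:i1
    extra_v[act] <- impulse_v * sin(pi * seq_along(act) / length(act))^2
    if (i1 < n) {                            # slide bleeds off over 0.3 s
      rec <- (i1 + 1L):n
      extra_v[rec] <- extra_v[i1] * exp(-(t[rec] - t[i1]) / 0.15)
    }
    trial$heel_pos$L <- trial$heel_pos$L + cumsum(extra_v) * dt
    # flat-foot hold on the perturbed ankle during the slide
    hold <- i0:min(n, i0 + round(0.5 * rate))
    blend <- exp(-seq(0, length.out = length(hold)) / (0.2 * rate))
    trial$joints$L$ankle[hold] <- trial$joints$L$ankle[hold] * (1 - blend) +
      0 * blend
    # contralateral step shortened: scale the right heel's advance until its
    # next heel strike after onset
    hs_r <- event_times(trial$events, "R", "HS")
    t_next <- hs_r[hs_r > t0][1]
    if (!is.na(t_next)) {
      win <- which(t >= t0 & t <= t_next)
      v_r <- c(0, diff(trial$heel_pos$R)) / dt
      v_r[win] <- 0.8 * v_r[win]
      trial$heel_pos$R <- trial$heel_pos$R[1] + cumsum(v_r) * dt
    }
  }

  trial$perturbation <- list(fired = TRUE, fall_type = fall$fall_type,
                             mechanism = fall$mechanism,
                             onset_segment = seg, t_on = t0, t_off = t[i1],
                             i_on = i0, i_off = i1,
                             n_held = i1 - i0 + 1L)
  trial
}

#' Null waveform dataset specification
#'
#' @param n_subjects,n_conditions,n_replicates design counts (defaults 7
#'   subjects, 3 conditions, 1 replicate per cell).
#' @param n_nodes waveform length (default 101 gait-cycle nodes).
#' @param fwhm smoothness of the Gaussian noise, in nodes (full width at half
#'   maximum of the smoothing kernel).
#' @param subject_offset_sd SD of the per-subject constant offset (shared
#'   across conditions and nodes, hence exchangeable under the null).
#' @param seed integer RNG seed.
#' @return object of class `null_dataset_spec`.
#' @export
null_dataset_spec <- function(n_subjects = 7, n_conditions = 3,
                              n_replicates = 1, n_nodes = 101, fwhm = 15,
                              subject_offset_sd = 0.3, seed = 1L) {
  if (n_subjects < 2 || n_conditions < 2 || n_replicates < 1 || n_nodes < 2) {
    stop("invalid parameter: counts must be >= 2 (replicates >= 1)", call. = FALSE)
  }
  if (!(fwhm > 0 && fwhm < n_nodes)) {
    stop("invalid parameter: need 0 < fwhm < n_nodes", call. = FALSE)
  }
  structure(list(n_subjects = n_subjects, n_conditions = n_conditions,
                 n_replicates = n_replicates, n_nodes = n_nodes, fwhm = fwhm,
                 subject_offset_sd = subject_offset_sd,
                 seed = as.integer(seed)),
            class = "null_dataset_spec")
}

# Gaussian smoothing matrix mapping (Q + 2 pad) white-noise nodes to Q
# smoothed nodes with exactly unit pointwise variance
smoothing_operator <- function(n_nodes, fwhm) {
  sd_k <- fwhm / (2 * sqrt(2 * log(2)))
  pad <- ceiling(3 * sd_k)
  len <- n_nodes + 2 * pad
  kern <- stats::dnorm(seq(-pad, pad), sd = max(sd_k, 1e-12))
  kern <- kern / sqrt(sum(kern^2))          # unit output variance
  K <- matrix(0, len, n_nodes)
  for (q in seq_len(n_nodes)) K[q:(q + 2 * pad), q] <- kern
  list(K = K, n_in = len)
}

#' Generate a smooth Gaussian null waveform dataset
#'
#' Each waveform is Gaussian white noise convolved with a Gaussian kernel of
#' the stated FWHM, normalized to unit pointwise variance, with a constant
#' per-subject random offset added (no condition effect anywhere). Used to
#' validate familywise error control of the waveform-field statistics.
#'
#' @param spec a [null_dataset_spec()].
#' @return numeric array `subjects x conditions x replicates x nodes`.
#' @export
generate_null_dataset <- function(spec) {
  stopifnot(inherits(spec, "null_dataset_spec"))
  restore <- local_seed(spec$seed)
  on.exit(restore())
  op <- smoothing_operator(spec$n_nodes, spec$fwhm)
  m <- spec$n_subjects * spec$n_conditions * spec$n_replicates
  white <- matrix(stats::rnorm(m * op$n_in), m, op$n_in)
  smooth <- white %*% op$K
  offs <- stats::rnorm(spec$n_subjects, 0, spec$subject_offset_sd)
  out <- array(0, dim = c(spec$n_subjects, spec$n_conditions,
                          spec$n_replicates, spec$n_nodes))
  row <- 1L
  for (i in seq_len(spec$n_subjects)) {
    for (j in seq_len(spec$n_conditions)) {
      for (r in seq_len(spec$n_replicates)) {
        out[i, j, r, ] <- smooth[row, ] + offs[i]
        row <- row + 1L
      }
    }
  }
  out
}
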