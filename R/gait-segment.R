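# Offline preprocessing of kinematic trajectories: zero-phase low-pass
# filtering, stride segmentation bookended by heel strikes, stance/swing
# split at toe-off, and 60/40 time normalization onto 101 nodes.

N_NODES <- 101L
STANCE_NODE <- 60L

# forward-backward filtering with odd-reflection padding (zero phase)
dual_pass <- function(x, b, a, pad_n) {
  n <- length(x)
  pad_n <- min(pad_n, n - 1L)
  xp <- c(2 * x[1] - x[(pad_n + 1):2],
          x,
          2 * x[n] - x[(n - 1):(n - pad_n)])
  y <- as.numeric(signal::filter(b, a, xp))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(pad_n + 1):(pad_n + n)]
}

#' Zero-phase low-pass filter for motion-capture trajectories
#'
#' Dual-pass (forward-backward) first-order Butterworth at 6 Hz: the
#' squared-magnitude response of the single pass, with no phase lag.
#'
#' @param traj data frame with a time column `t` and one numeric column per
#'   signal, uniformly sampled.
#' @param rate sampling rate, Hz (default 200).
#' @param cutoff low-pass cutoff, Hz (default 6).
#' @param order Butterworth order of each pass (default 1).
#' @return `traj` with every non-time column filtered.
#' @export
lowpass_mocap <- function(traj, rate = 200, cutoff = 6, order = 1) {
  stopifnot(is.data.frame(traj), "t" %in% names(traj))
  check_positive(rate, "rate")
  if (cutoff >= rate / 2) {
    stop("invalid parameter: cutoff at or above Nyquist frequency", call. = FALSE)
  }
  bt <- signal::butter(order, cutoff / (rate / 2), type = "low")
  pad_n <- round(3 * rate / cutoff)
  if (nrow(traj) < 10 || nrow(traj) <= order * 3) {
    stop("insufficient data: trajectory shorter than the filter pad length",
         call. = FALSE)
  }
  for (nm in setdiff(names(traj), "t")) {
    if (is.numeric(traj[[nm]])) {
      traj[[nm]] <- dual_pass(traj[[nm]], as.numeric(bt$b), as.numeric(bt$a),
                              pad_n)
    }
  }
  traj
}

#' Segment a trajectory into strides bookended by heel strikes
#'
#' One stride per consecutive heel-strike pair of the requested leg, each
#' annotated with its interior toe-off. Strides lacking exactly one interior
#' toe-off are dropped with a warning (count in attribute `"n_dropped"`).
#'
#' @param traj data frame with time column `t` and joint-angle columns.
#' @param events a [gait_events()] table.
#' @param leg `"L"` or `"R"`.
#' @return list of `raw_stride` objects: `t_hs_start`, `t_to`, `t_hs_end`,
#'   `data` (the trajectory rows spanning the stride, one sample of margin
#'   kept at each end for exact endpoint interpolation).
#' @export
segment_strides <- function(traj, events, leg = "L") {
  hs <- event_times(events, leg, "HS")
  to <- event_times(events, leg, "TO")
  if (length(hs) < 2) {
    stop("insufficient data: need at least two heel strikes", call. = FALSE)
  }
  strides <- list()
  dropped <- 0L
  for (k in seq_len(length(hs) - 1)) {
    t0 <- hs[k]; t1 <- hs[k + 1]
    inner <- to[to > t0 & to < t1]
    if (length(inner) != 1L) {
      dropped <- dropped + 1L
      next
    }
    i0 <- max(1L, findInterval(t0, traj$t))
    i1 <- min(nrow(traj), findInterval(t1, traj$t) + 1L)
    strides[[length(strides) + 1L]] <- structure(
      list(t_hs_start = t0, t_to = inner, t_hs_end = t1, leg = leg,
           data = traj[i0:i1, , drop = FALSE]),
      class = "raw_stride")
  }
  if (dropped > 0) {
    warning(sprintf("%d stride(s) dropped (no unique interior toe-off)", dropped))
  }
  attr(strides, "n_dropped") <- dropped
  strides
}

#' Time-normalize a stride onto 101 gait-cycle nodes (60/40 split)
#'
#' The stance phase (heel strike to toe-off) is resampled by linear
#' interpolation onto nodes 0-60 and the swing phase (toe-off to the next
#' heel strike) onto nodes 60-100, regardless of the raw stance/swing time
#' fractions; node 60 is the toe-off sample shared by both pieces, and the
#' endpoint values are the raw signal interpolated at the exact event
#' instants.
#'
#' @param stride a `raw_stride` from [segment_strides()].
#' @param toe_off toe-off time; defaults to the stride's annotated one.
#' @param joints names of the columns to normalize (default: all non-time
#'   numeric columns).
#' @return object of class `normalized_stride`: `nodes` (101 x joints
#'   matrix), `leg`, `contains_perturbation` (initialized `FALSE`), and the
#'   source event times.
#' @export
time_normalize <- function(stride, toe_off = stride$t_to, joints = NULL) {
  stopifnot(inherits(stride, "raw_stride"))
  t0 <- stride$t_hs_start; t1 <- stride$t_hs_end
  if (!(t0 < toe_off && toe_off < t1)) {
    stop("toe-off outside stride interval", call. = FALSE)
  }
  d <- stride$data
  if (is.null(joints)) {
    joints <- setdiff(names(d), "t")
    joints <- joints[vapply(d[joints], is.numeric, logical(1))]
  }
  t_stance <- seq(t0, toe_off, length.out = STANCE_NODE + 1L)
  t_swing <- seq(toe_off, t1, length.out = N_NODES - STANCE_NODE)
  t_nodes <- c(t_stance, t_swing[-1])
  nodes <- vapply(joints,
                  function(nm) stats::approx(d$t, d[[nm]], xout = t_nodes)$y,
                  numeric(N_NODES))
  colnames(nodes) <- joints
  structure(list(nodes = nodes, leg = stride$leg,
                 contains_perturbation = FALSE,
                 t_hs_start = t0, t_to = toe_off, t_hs_end = t1),
            class = "normalized_stride")
}

#' @export
print.normalized_stride <- function(x, ...) {
  cat(sprintf(
    "normalized_stride (%s leg): 101 nodes x {%s}, stance 0-60%%, %.2f-%.2f s%s\n",
    x$leg, paste(colnames(x$nodes), collapse = ", "), x$t_hs_start, x$t_hs_end,
    if (x$contains_perturbation) ", perturbed" else ""))
  invisible(x)
}

#' Select perturbation-containing gait cycles
#'
#' Flags every stride whose half-open interval `[heel strike, next heel
#' strike)` contains a trigger firing time. For fall conditions only the
#' flagged cycles are retained (only the cycles that contain the
#' perturbation instances are analysed); for unperturbed conditions all
#' complete strides are kept.
#'
#' @param strides list of `normalized_stride` objects.
#' @param trigger_events list of `trigger_event`s (or numeric firing times).
#' @param condition trial condition label; `"NW"` and `"SW"` keep all
#'   strides, anything else keeps only perturbed ones.
#' @param subject_id subject label carried into the set.
#' @return object of class `trial_waveform_set`: `condition`, `subject_id`,
#'   `leg`, `strides`.
#' @export
select_perturbed_cycles <- function(strides, trigger_events,
                                    condition = "NW", subject_id = "S1") {
  t_fire <- if (is.numeric(trigger_events)) {
    trigger_events
  } else {
    vapply(trigger_events, function(e) e$t_fire, numeric(1))
  }
  for (k in seq_along(strides)) {
    s <- strides[[k]]
    strides[[k]]$contains_perturbation <-
      any(t_fire >= s$t_hs_start & t_fire < s$t_hs_end)
  }
  if (!condition %in% c("NW", "SW")) {
    strides <- Filter(function(s) s$contains_perturbation, strides)
  }
  leg <- if (length(strides)) strides[[1]]$leg else NA_character_
  structure(list(condition = condition, subject_id = subject_id, leg = leg,
                 strides = strides),
            class = "trial_waveform_set")
}

#' @export
print.trial_waveform_set <- function(x, ...) {
  cat(sprintf("trial_waveform_set: %s/%s, %s leg, %d stride(s) (%d perturbed)\n",
              x$subject_id, x$condition, x$leg, length(x$strides),
              sum(vapply(x$strides, `[[`, logical(1), "contains_perturbation"))))
  invisible(x)
}

#' Stack a waveform set into a strides x 101 matrix for one joint
#'
#' @param set a `trial_waveform_set`.
#' @param joint column name in the normalized strides.
#' @return numeric matrix, one row per stride.
#' @export
waveform_matrix <- function(set, joint = "hip") {
  do.call(rbind, lapply(set$strides, function(s) s$nodes[, joint]))
}

#' Step lengths from heel positions and gait events
#'
#' Step length is the forward distance between the two heels at each heel
#' strike (the trailing, contralateral foot being stationary since its own
#' preceding strike). Consecutive same-leg strikes (a missing contralateral
#' event) skip a step.
#'
#' @param heel_positions data frame `t`, `L`, `R`: forward-axis heel
#'   positions in metres.
#' @param events a [gait_events()] table.
#' @return data frame `time_s`, `leading_leg`, `step_length_m`.
#' @export
step_length <- function(heel_positions, events) {
  hs <- events[events$event == "HS", , drop = FALSE]
  hs <- hs[order(hs$time_s), , drop = FALSE]
  pos_at <- function(leg, tt) {
    stats::approx(heel_positions$t, heel_positions[[leg]], xout = tt,
                  rule = 2)$y
  }
  out <- data.frame(time_s = numeric(0), leading_leg = character(0),
                    step_length_m = numeric(0))
  if (nrow(hs) < 2) return(out)
  for (k in 2:nrow(hs)) {
    lead <- hs$leg[k]; trail <- hs$leg[k - 1]
    if (lead == trail) next
    tt <- hs$time_s[k]
    out[nrow(out) + 1L, ] <- list(tt, lead,
                                  pos_at(lead, tt) - pos_at(trail, tt))
  }
  out
}

#' Detect gait events from heel forward kinematics
#'
#' Fallback detector for synthetic data (real trials take events as primary
#' inputs): a heel strike is the transition of the heel's forward velocity
#' from moving to stationary, toe-off the reverse, against a small velocity
#' threshold.
#'
#' @param heel_positions data frame `t`, `L`, `R` (metres).
#' @param threshold velocity threshold, m/s.
#' @return a [gait_events()] table.
#' @export
detect_gait_events <- function(heel_positions, threshold = 0.05) {
  t <- heel_positions$t
  dt <- mean(diff(t))
  legs <- c("L", "R")
  leg_v <- character(0); ev_v <- character(0); tt_v <- numeric(0)
  for (leg in legs) {
    v <- c(0, diff(heel_positions[[leg]])) / dt
    moving <- v > threshold
    hs <- which(moving[-length(moving)] & !moving[-1]) + 1L
    to <- which(!moving[-length(moving)] & moving[-1]) + 1L
    leg_v <- c(leg_v, rep(leg, length(hs) + length(to)))
    ev_v <- c(ev_v, rep("HS", length(hs)), rep("TO", length(to)))
    tt_v <- c(tt_v, t[hs], t[to])
  }
  gait_events(leg_v, ev_v, tt_v)
}
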