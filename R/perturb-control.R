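# Phase-gated perturbation triggering: poll a fall request, watch the
# discretized phase stream, fire the configured mechanism on entry into the
# target segment, and stop the platform.

#' Fall-type configuration
#'
#' One row of the platform's fall table: which mechanism induces the fall,
#' at which discretized gait-phase segment it fires, and for how long it
#' stays active.
#'
#' @param fall_type `"elevating"`, `"skipping"`, `"lowering"` or `"slip"`.
#' @param target_segment discretization segment (0-19) whose entry fires the
#'   mechanism.
#' @param activation_ms activation duration in milliseconds. Defaults per
#'   fall type: elevating 200 (any value under 250 is admissible), skipping
#'   250, lowering 400, slip 250.
#' @param mechanism `"brake"` or `"motor"`; defaults to brake for the three
#'   trip types and motor for the slip, which is also enforced.
#' @return object of class `fall_config`.
#' @export
fall_config <- function(fall_type = c("lowering", "skipping", "elevating", "slip"),
                        target_segment,
                        activation_ms = NULL,
                        mechanism = NULL) {
  fall_type <- match.arg(fall_type)
  default_ms <- c(elevating = 200, skipping = 250, lowering = 400, slip = 250)
  if (is.null(activation_ms)) activation_ms <- default_ms[[fall_type]]
  required_mech <- if (fall_type == "slip") "motor" else "brake"
  if (is.null(mechanism)) mechanism <- required_mech
  if (mechanism != required_mech) {
    stop(sprintf("configuration error: %s falls use the %s mechanism",
                 fall_type, required_mech), call. = FALSE)
  }
  if (!target_segment %in% 0:19) {
    stop("configuration error: `target_segment` must be in 0..19", call. = FALSE)
  }
  check_positive(activation_ms, "activation_ms")
  if (fall_type == "elevating" && activation_ms >= 250) {
    stop("configuration error: elevating activation must be < 250 ms",
         call. = FALSE)
  }
  structure(list(fall_type = fall_type, mechanism = mechanism,
                 target_segment = as.integer(target_segment),
                 activation_ms = activation_ms,
                 gait_phase_label = switch(fall_type,
                                           elevating = "early-mid swing",
                                           skipping = "early-mid swing",
                                           lowering = "mid-late swing",
                                           slip = "early stance")),
            class = "fall_config")
}

#' @export
print.fall_config <- function(x, ...) {
  cat(sprintf("fall_config: %s (%s, %s), segment %d, %g ms\n",
              x$fall_type, x$gait_phase_label, x$mechanism,
              x$target_segment, x$activation_ms))
  invisible(x)
}

# segment index gating a given gait-cycle fraction, under the generator's
# phase convention (left heel strike at wrapped phase pi/2)
segment_for_cycle_fraction <- function(fraction) {
  discretize_phase(PHASE_AT_HS + 2 * pi * fraction)
}

#' Default fall table
#'
#' The four configured fall types with their mechanisms and activation
#' durations (elevating < 250 ms, skipping 250 ms, lowering 400 ms, slip
#' 250 ms). The segment-to-fall assignment is calibration, not a published
#' constant: defaults are derived from the synthetic generator's phase-event
#' convention — mid-swing detection (cycle fraction 0.80) gates the
#' mid-swing trips, and early stance (fraction 0.02) gates the slip.
#'
#' @return named list of [fall_config()] objects.
#' @export
default_fall_table <- function() {
  seg_midswing <- segment_for_cycle_fraction(0.80)
  seg_earlystance <- segment_for_cycle_fraction(0.02)
  seg_earlyswing <- segment_for_cycle_fraction(0.70)
  list(
    elevating = fall_config("elevating", seg_earlyswing),
    skipping = fall_config("skipping", seg_earlyswing),
    lowering = fall_config("lowering", seg_midswing),
    slip = fall_config("slip", seg_earlystance))
}

#' Cable-tension metadata for the fall mechanisms
#'
#' Static, dynamic and maximum ankle-cable tension (newtons) of the trip
#' (brake) and slip (motor) mechanisms. Carried as metadata only; no cable
#' or spring dynamics are simulated.
#'
#' @return data frame with one row per mechanism.
#' @export
mechanism_forces <- function() {
  data.frame(mechanism = c("brake", "motor"),
             static_force_n = c(3.0, 1.0),
             dynamic_force_n = c(5.9, 3.5),
             max_force_n = c(347.8, 110.3))
}

#' Run the trigger control loop over a phase stream
#'
#' From the request time onward, the loop watches the discretized phase
#' stream and fires at the first sample where the stream *transitions into*
#' the target segment (entry-edge semantics: a request issued while the
#' stream is already inside the target segment fires on the next entry, not
#' immediately). Exactly one event is emitted per request, carrying the
#' configured activation duration; the platform stop is issued at the same
#' sample.
#'
#' @param phase_stream a `phase_series` (or any list with `t` and `segment`).
#' @param request list with `t_request` (s) and `fall_type`.
#' @param config fall table, as from [default_fall_table()]; the entry named
#'   by `request$fall_type` is used.
#' @return object of class `trigger_event`, or `NULL` with a timeout
#'   warning if the target segment is never entered before the stream ends.
#' @export
run_control_loop <- function(phase_stream, request,
                             config = default_fall_table()) {
  if (is.null(request)) return(NULL)
  fall <- config[[request$fall_type]]
  if (is.null(fall)) {
    stop(sprintf("configuration error: unknown fall type '%s'",
                 request$fall_type), call. = FALSE)
  }
  t <- phase_stream$t
  seg <- phase_stream$segment
  if (request$t_request < t[1] || request$t_request > t[length(t)]) {
    stop("request time outside the phase-stream span", call. = FALSE)
  }
  i_req <- which(t >= request$t_request)[1]
  target <- fall$target_segment
  # entry edge: segment changes into `target` at i (previous sample known
  # and different); NA segments (warm-up) never match
  cand <- seq(max(i_req, 2L), length(t))
  prev_ok <- !is.na(seg[cand - 1L]) & seg[cand - 1L] != target
  now_ok <- !is.na(seg[cand]) & seg[cand] == target
  hit <- cand[prev_ok & now_ok]
  if (length(hit) == 0) {
    warning("timeout: target segment never entered before stream end")
    return(NULL)
  }
  i_fire <- hit[1]
  structure(list(t_request = request$t_request, t_fire = t[i_fire],
                 i_fire = i_fire, fall_type = fall$fall_type,
                 mechanism = fall$mechanism,
                 duration_ms = fall$activation_ms,
                 segment_at_fire = seg[i_fire],
                 platform_stop_issued = TRUE),
            class = "trigger_event")
}

#' @export
print.trigger_event <- function(x, ...) {
  cat(sprintf(
    "trigger_event: %s (%s) requested %.3f s, fired %.3f s in segment %d, %g ms\n",
    x$fall_type, x$mechanism, x$t_request, x$t_fire, x$segment_at_fire,
    x$duration_ms))
  invisible(x)
}

#' Actuation window of a trigger event
#'
#' @param event a `trigger_event`.
#' @param stream optional phase stream; when given, the window is also
#'   expressed in sample counts and truncated (with attribute
#'   `"truncated" = TRUE`) if the stream ends first.
#' @return list `t_start`, `t_end` (`t_end - t_start` equals the configured
#'   duration exactly), and `n_samples` when a stream is supplied.
#' @export
actuation_window <- function(event, stream = NULL) {
  stopifnot(inherits(event, "trigger_event"))
  t_start <- event$t_fire
  t_end <- t_start + event$duration_ms / 1000
  out <- list(t_start = t_start, t_end = t_end)
  if (!is.null(stream)) {
    t <- stream$t
    dt <- mean(diff(t))
    n_nominal <- round(event$duration_ms / 1000 / dt)
    in_stream <- sum(t >= t_start & t < t_end)
    out$n_samples <- n_nominal
    if (t[length(t)] < t_end) {
      out$n_samples <- in_stream
      attr(out, "truncated") <- TRUE
    }
  }
  out
}

#' Randomize the fall schedule across trials
#'
#' Uniformly random assignment of which trials contain which fall type,
#' deterministic under the seed. Mirrors the protocol device of perturbing
#' the subject only during some trials so falls cannot be anticipated.
#'
#' @param n_trials total number of trials.
#' @param falls named integer vector of fall counts, e.g.
#'   `c(skipping = 3, lowering = 3, slip = 3)`.
#' @param seed RNG seed.
#' @return data frame `trial`, `fall_type` (`NA` for plain walking trials).
#' @export
randomize_trials <- function(n_trials, falls, seed = 1L) {
  total <- sum(falls)
  if (total > n_trials) {
    stop("infeasible schedule: more falls than trials", call. = FALSE)
  }
  restore <- local_seed(seed)
  on.exit(restore())
  sched <- data.frame(trial = seq_len(n_trials),
                      fall_type = NA_character_)
  if (total > 0) {
    chosen <- sample(n_trials, total)
    types <- sample(rep(names(falls), times = falls))
    sched$fall_type[chosen] <- types
  }
  sched
}
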