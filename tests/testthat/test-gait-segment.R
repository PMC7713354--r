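test_that("dual-pass low-pass is zero-phase and matches |H|^2", {
  rate <- 200
  t <- seq(0, 10, by = 1 / rate)
  # DC passes unchanged
  dc <- data.frame(t = t, y = rep(3.5, length(t)))
  expect_equal(lowpass_mocap(dc, rate)$y, dc$y, tolerance = 1e-9)
  # 1 Hz sine: attenuation equals the squared single-pass magnitude
  bt <- signal::butter(1, 6 / (rate / 2), type = "low")
  filt <- list(b = as.numeric(bt$b), a = as.numeric(bt$a), rate = rate)
  s1 <- data.frame(t = t, y = sin(2 * pi * 1 * t))
  f1 <- lowpass_mocap(s1, rate)
  mid <- t > 2 & t < 8
  expect_equal(max(abs(f1$y[mid])), Mod(freq_response(filt, 1))^2,
               tolerance = 0.01)
  # no phase lag: peak cross-correlation at zero lag
  cc <- stats::ccf(f1$y[mid], s1$y[mid], lag.max = 20, plot = FALSE)
  expect_equal(as.integer(cc$lag[which.max(cc$acf)]), 0L)
  # 50 Hz noise knocked down by far more than 90%
  s50 <- data.frame(t = t, y = sin(2 * pi * 50 * t))
  f50 <- lowpass_mocap(s50, rate)
  expect_lt(max(abs(f50$y[mid])), 0.1)
  expect_error(lowpass_mocap(data.frame(t = t[1:5], y = 1:5), rate),
               "insufficient data")
})

test_that("stride segmentation is fencepost-correct and drops bad strides", {
  t <- seq(0, 10, by = 0.005)
  traj <- data.frame(t = t, hip = sin(t))
  hs <- c(1, 3, 5, 7, 9)
  to <- c(2.2, 4.2, 6.2, 8.2)
  ev <- gait_events(rep("L", 9), c(rep("HS", 5), rep("TO", 4)), c(hs, to))
  st <- segment_strides(traj, ev, "L")
  expect_length(st, 4L)
  # a stride lacking its toe-off is excluded, others kept
  ev2 <- gait_events(rep("L", 8), c(rep("HS", 5), rep("TO", 3)),
                     c(hs, to[-2]))
  expect_warning(st2 <- segment_strides(traj, ev2, "L"), "dropped")
  expect_length(st2, 3L)
  expect_identical(attr(st2, "n_dropped"), 1L)
  expect_error(segment_strides(traj, gait_events("L", "HS", 1), "L"),
               "two heel strikes")
})

test_that("generated trials segment into the expected stride count", {
  tr <- default_trial()
  for (leg in c("L", "R")) {
    st <- segment_strides(tr$joints[[leg]], tr$events, leg)
    n_hs <- sum(tr$events$leg == leg & tr$events$event == "HS")
    expect_identical(length(st), n_hs - 1L)
  }
})

test_that("time normalization maps stance to nodes 0-60 for any raw split", {
  rate <- 200
  for (stance_frac in c(0.4, 0.5, 0.6, 0.75)) {
    dur <- 1.2
    t <- seq(-0.05, dur + 0.05, by = 1 / rate)
    traj <- data.frame(t = t, ang = 10 * sin(2 * pi * t / dur) + 3 * t)
    to_t <- stance_frac * dur
    stride <- structure(list(t_hs_start = 0, t_to = to_t, t_hs_end = dur,
                             leg = "L", data = traj),
                        class = "raw_stride")
    ns <- time_normalize(stride)
    expect_identical(nrow(ns$nodes), 101L)
    # endpoints and the shared toe-off node are the raw signal at the events
    raw_at <- function(tt) stats::approx(traj$t, traj$ang, xout = tt)$y
    expect_equal(unname(ns$nodes[1, "ang"]), raw_at(0), tolerance = 1e-12)
    expect_equal(unname(ns$nodes[61, "ang"]), raw_at(to_t), tolerance = 1e-12)
    expect_equal(unname(ns$nodes[101, "ang"]), raw_at(dur), tolerance = 1e-12)
    # stance nodes sample the stance interval uniformly
    mid_stance <- raw_at(seq(0, to_t, length.out = 61))
    expect_equal(unname(ns$nodes[1:61, "ang"]), mid_stance,
                 tolerance = 1e-6)
  }
})

test_that("normalization preserves linearity piecewise and is idempotent", {
  t <- seq(0, 2, by = 0.005)
  traj <- data.frame(t = t, ang = 2 * t + 1)
  stride <- structure(list(t_hs_start = 0.1, t_to = 0.9, t_hs_end = 1.9,
                           leg = "L", data = traj), class = "raw_stride")
  ns <- time_normalize(stride)
  expect_lt(max(abs(diff(diff(ns$nodes[1:61, "ang"])))), 1e-10)
  expect_lt(max(abs(diff(diff(ns$nodes[61:101, "ang"])))), 1e-10)
  # identity on an already-normalized stride with events at 0/60/100
  pre <- data.frame(t = 0:100, ang = ns$nodes[, "ang"])
  again <- time_normalize(structure(list(t_hs_start = 0, t_to = 60,
                                         t_hs_end = 100, leg = "L",
                                         data = pre), class = "raw_stride"))
  expect_equal(unname(again$nodes[, "ang"]), unname(ns$nodes[, "ang"]),
               tolerance = 1e-12)
  expect_error(time_normalize(stride, toe_off = 2.5), "outside")
})

test_that("perturbed-cycle selection flags by half-open stride interval", {
  tr <- default_trial()
  st <- lapply(segment_strides(tr$joints$L, tr$events, "L"), time_normalize)
  t_fire <- st[[4]]$t_hs_start + 0.3
  set <- select_perturbed_cycles(st, t_fire, condition = "TS")
  expect_length(set$strides, 1L)
  expect_true(set$strides[[1]]$contains_perturbation)
  expect_identical(set$strides[[1]]$t_hs_start, st[[4]]$t_hs_start)
  # a firing exactly on a stride boundary belongs to the starting stride
  set_b <- select_perturbed_cycles(st, st[[5]]$t_hs_start, condition = "TS")
  expect_identical(set_b$strides[[1]]$t_hs_start, st[[5]]$t_hs_start)
  # walking conditions keep all strides, flagged or not
  set_nw <- select_perturbed_cycles(st, t_fire, condition = "NW")
  expect_length(set_nw$strides, length(st))
  m <- waveform_matrix(set_nw, "knee")
  expect_identical(dim(m), c(length(st), 101L))
})

test_that("step length is zero for static feet and v/(2f) when walking", {
  hp <- data.frame(t = seq(0, 10, 0.01), L = 0.3, R = 0.1)
  ev <- gait_events(c("L", "R", "L"), rep("HS", 3), c(1, 2, 3))
  sl <- step_length(hp, ev)
  expect_equal(sl$step_length_m, c(-0.2, 0.2), tolerance = 1e-12)
  tr <- default_trial()
  sl2 <- step_length(tr$heel_pos, tr$events)
  expected <- tr$params$speed / (2 * tr$params$cadence / 60)
  expect_equal(mean(sl2$step_length_m), expected, tolerance = 0.03)
  # consecutive same-leg strikes are skipped
  ev_gap <- gait_events(c("L", "L", "R"), rep("HS", 3), c(1, 2, 3))
  expect_identical(nrow(step_length(hp, ev_gap)), 1L)
})

test_that("the fallback event detector recovers generator events", {
  tr <- default_trial()
  det <- detect_gait_events(tr$heel_pos)
  for (leg in c("L", "R")) {
    true_hs <- tr$events$time_s[tr$events$leg == leg & tr$events$event == "HS"]
    det_hs <- det$time_s[det$leg == leg & det$event == "HS"]
    true_hs <- true_hs[true_hs > 0.5 & true_hs < 14]
    err <- vapply(true_hs, function(tt) min(abs(det_hs - tt)), numeric(1))
    expect_lt(stats::median(err), 0.05)
  }
})
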