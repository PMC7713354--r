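test_that("bandpass magnitude response hits -3 dB at both cutoffs", {
  filt <- design_bandpass(bandpass_spec(), 333)
  expect_equal(Mod(freq_response(filt, 0.4)), 1 / sqrt(2), tolerance = 0.01)
  expect_equal(Mod(freq_response(filt, 3.0)), 1 / sqrt(2), tolerance = 0.01)
  # bandpass limits and passband maximum
  expect_lt(Mod(freq_response(filt, 0.005)), 0.01)
  expect_lt(Mod(freq_response(filt, 166)), 0.01)
  mid <- sqrt(0.4 * 3)
  expect_gt(Mod(freq_response(filt, mid)), Mod(freq_response(filt, 0.4)))
  expect_gt(Mod(freq_response(filt, mid)), Mod(freq_response(filt, 3.0)))
})

test_that("cutoffs at or above Nyquist are rejected", {
  expect_error(design_bandpass(bandpass_spec(f_hi = 200), 333), "Nyquist")
  expect_error(bandpass_spec(f_lo = 3, f_hi = 1), "f_lo")
})

test_that("single-pass filtering is causal, rejects DC, obeys |H|", {
  rate <- 333
  t <- seq(0, 20, by = 1 / rate)
  # DC rejection
  s_const <- imu_series(t, rep(5, length(t)), rep(5, length(t)),
                        nominal_rate = rate)
  out <- filter_single_pass(s_const)
  expect_lt(max(abs(utils::tail(out$hip_flexion, 500))), 1e-3 * 5)
  # in-band 1 Hz sine: steady-state amplitude matches |H(1)|
  filt <- design_bandpass(bandpass_spec(), rate)
  s1 <- imu_series(t, sin(2 * pi * 1 * t), cos(2 * pi * 1 * t),
                   nominal_rate = rate)
  o1 <- filter_single_pass(s1)
  amp <- max(abs(o1$hip_flexion[t > 15]))
  expect_equal(amp, Mod(freq_response(filt, 1)), tolerance = 0.02)
  # out-of-band 10 Hz sine strongly attenuated, per |H(10)|
  s10 <- imu_series(t, sin(2 * pi * 10 * t), cos(2 * pi * 10 * t),
                    nominal_rate = rate)
  o10 <- filter_single_pass(s10)
  amp10 <- max(abs(o10$hip_flexion[t > 15]))
  expect_lt(amp10, 0.10)
  expect_equal(amp10, Mod(freq_response(filt, 10)), tolerance = 0.05)
})

test_that("too-short series raise an insufficient-data error", {
  t <- seq(0, 1, by = 1 / 333)
  s <- imu_series(t, sin(t), cos(t), nominal_rate = 333)
  expect_error(filter_single_pass(s), "insufficient data")
})

test_that("jittered timestamps are resampled before filtering", {
  rate <- 333
  set.seed(1)
  t <- cumsum(abs(rnorm(6000, 1 / rate, 0.3 / rate)))
  s <- imu_series(t, sin(2 * pi * t), 2 * pi * cos(2 * pi * t),
                  nominal_rate = rate)
  out <- filter_single_pass(s)
  expect_lt(max(abs(diff(diff(out$t)))), 1e-9)  # uniform grid
})

test_that("unit-sine fit recovers exact parameters and flags degeneracy", {
  t <- seq(0, 3, by = 1 / 333)
  arg <- 2 * pi * 0.9 * t + 0.5
  fit <- fit_unit_sine(t, sin(arg), cos(arg),
                       init = list(freq = 0.8, phase_offset = 0))
  expect_true(fit$converged)
  expect_equal(fit$freq, 0.9, tolerance = 1e-6)
  expect_equal(fit$phase_offset, 0.5, tolerance = 1e-6)
  # flat window: flagged, no error
  flat <- fit_unit_sine(t, rep(0, length(t)), rep(0, length(t)),
                        init = list(freq = 1, phase_offset = 0))
  expect_false(flat$converged)
})

test_that("fitted frequency tracks cadence on noisy gait", {
  p <- walk_params(duration = 12, noise_sd = 3, seed = 8)  # 10% amplitude
  tr <- generate_walk(p)
  ps <- estimate_phase(tr$imu)
  expect_lt(abs(stats::median(ps$freq, na.rm = TRUE) - p$cadence / 60), 0.05)
})

test_that("estimator is exact on noiseless single-harmonic input", {
  p <- walk_params(duration = 16, noise_sd = 0, harmonic_weights = 1,
                   seed = 3)
  tr <- generate_walk(p)
  ps <- estimate_phase(tr$imu)
  late <- which(ps$t > 8 & !is.na(ps$phase))
  err <- abs(wrap_phase(ps$phase[late] - tr$truth_phase[late]))
  # floor set by the running quantile normalization over non-integer
  # period windows; the filter transient has decayed by 8 s
  expect_lt(max(err), 2e-3)
})

test_that("direct atan2 phase extraction also tracks the truth", {
  p <- walk_params(duration = 12, noise_sd = 0, harmonic_weights = 1,
                   seed = 3)
  tr <- generate_walk(p)
  ps <- estimate_phase(tr$imu,
                       config = phase_fit_config(method = "atan2"))
  ok <- !is.na(ps$phase) & ps$t > 6
  expect_lt(circular_rmse(ps$phase[ok], tr$truth_phase[ok]), 0.05)
})

test_that("phase output is wrapped and monotone on forward walking", {
  unwrap_diffs <- function(p) {
    d <- diff(p)
    d - 2 * pi * round(d / (2 * pi))
  }
  tr <- default_trial()
  ps <- estimate_phase(tr$imu)
  ok <- !is.na(ps$phase)
  expect_true(all(ps$phase[ok] > -pi & ps$phase[ok] <= pi))
  # under measurement noise each window refit may correct the phase by a
  # fraction of a discretization segment; never more
  expect_gt(min(unwrap_diffs(ps$phase[ok])), -pi / 100)
  # strictly non-decreasing on clean input
  tr0 <- generate_walk(walk_params(duration = 15, seed = 7, noise_sd = 0,
                                   harmonic_weights = 1))
  ps0 <- estimate_phase(tr0$imu)
  ok0 <- !is.na(ps0$phase)
  expect_gt(min(unwrap_diffs(ps0$phase[ok0])), 0)
})

test_that("phase progression is near-linear at every speed", {
  for (lbl in c("slow", "normal", "fast")) {
    p <- walk_params(speed_label = lbl, duration = 12, seed = 21)
    tr <- generate_walk(p)
    ps <- estimate_phase(tr$imu)
    ok <- which(!is.na(ps$phase))
    d <- diff(ps$phase[ok])
    unwrapped <- cumsum(c(ps$phase[ok][1], d - 2 * pi * round(d / (2 * pi))))
    fitlm <- stats::lm(unwrapped ~ ps$t[ok])
    expect_gt(summary(fitlm)$r.squared, 0.95)
    slope_hz <- stats::coef(fitlm)[2] / (2 * pi)
    expect_equal(unname(slope_hz), p$cadence / 60, tolerance = 0.05)
  }
})

test_that("truncating the input tail never changes earlier phase outputs", {
  tr <- default_trial()
  full <- estimate_phase(tr$imu)
  n_keep <- 3000L
  short <- imu_series(tr$imu$t[1:n_keep], tr$imu$hip_flexion[1:n_keep],
                      tr$imu$hip_angvel[1:n_keep], tr$imu$torso_yaw[1:n_keep],
                      tr$imu$nominal_rate)
  ps_short <- estimate_phase(short)
  stride <- max(1L, round(full$config$refit_interval_s * 333))
  cmp <- seq_len(n_keep - stride)
  expect_identical(full$phase[cmp], ps_short$phase[cmp])
})

test_that("discretization partitions (-pi, pi] into 20 equal half-open bins", {
  eps <- 1e-9
  expect_identical(discretize_phase(-pi + eps), 0L)
  expect_identical(discretize_phase(pi), 19L)
  expect_identical(discretize_phase(0), 10L)
  # bin edges are half-open: just above an edge belongs to the upper bin,
  # just below to the lower (the edges themselves are irrational, so exact
  # membership is below floating-point resolution)
  edges <- -pi + (1:19) * pi / 10
  expect_identical(discretize_phase(edges + 1e-9), 1:19)
  expect_identical(discretize_phase(edges - 1e-9), 0:18)
  # uniform sweep covers exactly 20 segments with equal width
  x <- seq(-pi + 1e-6, pi, length.out = 10000)
  seg <- discretize_phase(x)
  expect_identical(sort(unique(seg)), 0:19)
  widths <- tapply(x, seg, function(v) diff(range(v)))
  expect_true(all(abs(widths - pi / 10) < 0.01))
  # wrap identity
  y <- runif(200, -10, 10)
  expect_identical(discretize_phase(y + 2 * pi), discretize_phase(y))
})

test_that("phase-portrait circularity scores circle, line, and harmonics", {
  th <- seq(0, 2 * pi, length.out = 500)
  expect_equal(phase_portrait_circularity(sin(th), cos(th)), 1,
               tolerance = 0.05)
  line <- seq(-1, 1, length.out = 500)
  expect_lt(phase_portrait_circularity(line, 2 * line), 0.05)
  expect_identical(phase_portrait_circularity(rep(0, 100), rep(0, 100)), 0)
  # two-harmonic gait is less circular than its single-harmonic counterpart
  p2 <- walk_params(duration = 10, noise_sd = 0, seed = 4)  # 2 harmonics
  p1 <- walk_params(duration = 10, noise_sd = 0, harmonic_weights = 1,
                    seed = 4)
  t2 <- generate_walk(p2); t1 <- generate_walk(p1)
  sel <- t1$imu$t > 2  # skip the initial transient-free region equally
  s2 <- phase_portrait_circularity(t2$imu$hip_flexion[sel] - 5,
                                   t2$imu$hip_angvel[sel])
  s1 <- phase_portrait_circularity(t1$imu$hip_flexion[sel] - 5,
                                   t1$imu$hip_angvel[sel])
  expect_lt(s2, s1)
})

test_that("heading compensation is exact for constant yaw", {
  t <- seq(0, 10, by = 1 / 333)
  s0 <- imu_series(t, sin(t), cos(t), rep(0, length(t)), 333)
  expect_identical(heading_compensate(s0)$hip_flexion, s0$hip_flexion)
  # constant 30 deg offset: identical phase output to the zero-yaw trial
  p <- walk_params(duration = 12, seed = 13)
  p30 <- walk_params(duration = 12, seed = 13,
                     heading_profile = function(t) rep(30, length(t)))
  tr0 <- generate_walk(p); tr30 <- generate_walk(p30)
  c0 <- heading_compensate(tr0$imu)
  c30 <- heading_compensate(tr30$imu)
  expect_equal(c0$hip_flexion, c30$hip_flexion, tolerance = 1e-10)
  expect_equal(estimate_phase(c0)$phase, estimate_phase(c30)$phase,
               tolerance = 1e-6)
})

test_that("missing torso yaw passes through with a warning", {
  t <- seq(0, 5, by = 0.01)
  s <- imu_series(t, sin(t), cos(t), nominal_rate = 100)
  expect_warning(out <- heading_compensate(s), "torso_yaw")
  expect_identical(out$hip_flexion, s$hip_flexion)
})

test_that("yaw compensation rescues phase estimation through a turn", {
  turn <- function(t) 90 * pmin(1, pmax(0, (t - 6) / 2))
  p_turn <- walk_params(duration = 14, seed = 17, heading_profile = turn)
  p_straight <- walk_params(duration = 14, seed = 17)
  tr_turn <- generate_walk(p_turn)
  tr_str <- generate_walk(p_straight)
  rmse_of <- function(imu, truth) {
    ps <- estimate_phase(imu)
    ok <- !is.na(ps$phase)
    circular_rmse(ps$phase[ok], truth[ok])
  }
  rmse_straight <- rmse_of(heading_compensate(tr_str$imu), tr_str$truth_phase)
  rmse_comp <- rmse_of(heading_compensate(tr_turn$imu), tr_turn$truth_phase)
  expect_lt(rmse_comp, 2 * rmse_straight)
})
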