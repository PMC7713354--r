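# Seeded end-to-end pipeline: synthesize trials, estimate phase, trigger,
# inject, segment, normalize, run the waveform statistics, and write all
# artifacts (stamped with the config hash) into an output directory.

FALL_FOR_CONDITION <- c(TS = "lowering", MS = "skipping", SL = "slip")

#' Gait-cycle percent at which a fall's target segment sits
#'
#' Converts a trigger segment back to the generator's gait-cycle fraction
#' (left heel strike at 0%), for marking perturbation onset on reports.
#'
#' @param segment segment index 0-19.
#' @return percent of gait cycle (0-100).
#' @export
segment_cycle_pct <- function(segment) {
  (((segment_centre(segment) - PHASE_AT_HS) / (2 * pi)) %% 1) * 100
}

#' Pipeline configuration
#'
#' Bundles every constant the end-to-end run needs. The defaults are a
#' desk-scale demo (3 subjects, short trials); the full protocol shape
#' (7 subjects, 5 walking trials of each kind, 3 falls per fall type) is a
#' matter of raising the counts.
#'
#' @param n_subjects subjects to simulate.
#' @param n_walk_trials trials per unperturbed condition (NW, SW) and
#'   subject.
#' @param n_fall_trials perturbed trials per subject.
#' @param fall_condition `"TS"`, `"MS"` or `"SL"` (terminal-swing trip,
#'   mid-swing trip, slip); selects the fall type per the fall table.
#' @param duration trial duration, s.
#' @param imu_rate IMU sampling rate, Hz (default 333).
#' @param mocap_rate marker-trajectory rate, Hz (default 200; the synthetic
#'   joint trajectories are generated on the IMU clock and filtered at
#'   their own rate).
#' @param alpha significance level for the waveform statistics.
#' @param phase_source `"estimated"` runs the real-time phase estimator to
#'   drive the trigger; `"truth"` gates on the generator's ground-truth
#'   phase (faster, for smoke runs).
#' @param fall_table from [default_fall_table()].
#' @param gains follower [pd_gains()] (carried for provenance; the
#'   follower is exercised by its own simulation, not per trial).
#' @param seed master seed; all per-trial seeds derive from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(n_subjects = 3, n_walk_trials = 2, n_fall_trials = 2,
                       fall_condition = c("TS", "MS", "SL"),
                       duration = 10, imu_rate = 333, mocap_rate = 200,
                       alpha = 0.05,
                       phase_source = c("estimated", "truth"),
                       fall_table = default_fall_table(),
                       gains = pd_gains(), seed = 1L) {
  fall_condition <- match.arg(fall_condition)
  phase_source <- match.arg(phase_source)
  structure(list(n_subjects = n_subjects, n_walk_trials = n_walk_trials,
                 n_fall_trials = n_fall_trials,
                 fall_condition = fall_condition, duration = duration,
                 imu_rate = imu_rate, mocap_rate = mocap_rate, alpha = alpha,
                 phase_source = phase_source, fall_table = fall_table,
                 gains = gains, seed = as.integer(seed)),
            class = "run_config")
}

# phase stream from ground truth (same shape as estimate_phase output)
truth_phase_stream <- function(trial) {
  structure(list(t = trial$imu$t, phase = trial$truth_phase,
                 segment = discretize_phase(trial$truth_phase)),
            class = "phase_series")
}

# normalized strides of one leg of a trial (joints low-passed first)
normalized_strides_of <- function(trial, leg, rate) {
  traj <- lowpass_mocap(trial$joints[[leg]], rate = rate)
  raw <- segment_strides(traj, trial$events, leg = leg)
  lapply(raw, time_normalize)
}

#' Run the end-to-end pipeline
#'
#' Synthesis, phase estimation, triggering, perturbation injection, stride
#' segmentation/normalization, repeated-measures SPM per joint and leg,
#' post-hoc t fields, and the four-row reports. Every artifact carries the
#' config hash; re-running with an identical config reproduces the
#' deterministic outputs bit-identically.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the results summary and artifact paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("waveforms", "spm", "figures")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  fall_type <- FALL_FOR_CONDITION[[config$fall_condition]]
  fall <- config$fall_table[[fall_type]]
  conditions <- c("NW", "SW", config$fall_condition)
  joints <- c("hip", "knee", "ankle")
  legs <- c("L", "R")

  # subject x condition x joint x leg subject-mean waveforms, plus
  # per-subject trial replicates for the individual analyses
  subj_mean <- list()
  subj_trials <- list()
  triggers <- list()

  for (s in seq_len(config$n_subjects)) {
    for (cond in conditions) {
      n_tr <- if (cond %in% c("NW", "SW")) config$n_walk_trials else
        config$n_fall_trials
      for (tr_i in seq_len(n_tr)) {
        seed_tr <- config$seed + s * 971 + match(cond, conditions) * 131 +
          tr_i * 17
        params <- walk_params(duration = config$duration,
                              sample_rate = config$imu_rate, seed = seed_tr)
        trial <- stage("synth", generate_walk(params, condition = cond,
                                              subject_id = paste0("S", s)))
        fire_times <- numeric(0)
        if (!cond %in% c("NW", "SW")) {
          ps <- stage("phase", if (config$phase_source == "estimated") {
            estimate_phase(trial$imu)
          } else {
            truth_phase_stream(trial)
          })
          req <- list(t_request = config$duration / 2, fall_type = fall_type)
          ev <- stage("trigger",
                      run_control_loop(ps, req, config$fall_table))
          if (!is.null(ev)) {
            triggers[[length(triggers) + 1L]] <- ev
            fire_times <- ev$t_fire
            trial <- stage("synth",
                           inject_perturbation(trial, fall,
                                               after_time = req$t_request))
          }
        }
        for (leg in legs) {
          strides <- stage("segment",
                           normalized_strides_of(trial, leg,
                                                 config$imu_rate))
          set <- select_perturbed_cycles(strides, fire_times,
                                         condition = cond,
                                         subject_id = paste0("S", s))
          for (j in joints) {
            mat <- waveform_matrix(set, j)
            if (is.null(mat) || nrow(mat) == 0) next
            key <- paste(s, cond, j, leg, sep = ".")
            subj_trials[[key]] <- rbind(subj_trials[[key]], colMeans(mat))
          }
        }
      }
    }
  }
  for (key in names(subj_trials)) {
    subj_mean[[key]] <- colMeans(subj_trials[[key]])
  }

  results <- list(config_hash = hash, seed = config$seed,
                  fall_condition = config$fall_condition,
                  fall_type = fall_type, legs = list())
  perturb_pct <- segment_cycle_pct(fall$target_segment)

  for (leg in legs) {
    joint_results <- list()
    per_subject <- list()
    for (j in joints) {
      y <- array(NA_real_, c(config$n_subjects, length(conditions), N_NODES))
      for (s in seq_len(config$n_subjects)) {
        for (ci in seq_along(conditions)) {
          key <- paste(s, conditions[ci], j, leg, sep = ".")
          if (is.null(subj_mean[[key]])) {
            stop(sprintf("pipeline stage 'segment' failed: no strides for %s",
                         key), call. = FALSE)
          }
          y[s, ci, ] <- subj_mean[[key]]
        }
      }
      spm <- stage("spm", spm_anova(y, alpha = config$alpha))
      ph <- stage("spm", posthoc_pairwise(y, alpha = config$alpha,
                                          conditions = conditions))
      cond_means <- apply(y, c(2, 3), mean)
      cond_sds <- apply(y, c(2, 3), stats::sd)
      joint_results[[j]] <- list(cond_means = cond_means,
                                 cond_sds = cond_sds,
                                 conditions = conditions, spm = spm)
      # per-subject rows: trials as replicates, between-trials ANOVA
      bins <- list()
      for (s in seq_len(config$n_subjects)) {
        keys <- paste(s, conditions, j, leg, sep = ".")
        reps <- min(vapply(subj_trials[keys], nrow, integer(1)))
        if (reps >= 2) {
          ys <- array(NA_real_, c(reps, length(conditions), N_NODES))
          for (ci in seq_along(conditions)) {
            ys[, ci, ] <- subj_trials[[keys[ci]]][seq_len(reps), ]
          }
          spm_s <- spm_anova(ys, alpha = config$alpha, design = "between")
          bins[[s]] <- spm_s$colour_bins
        } else {
          bins[[s]] <- rep(0L, N_NODES)
        }
      }
      per_subject[[j]] <- bins

      mat <- do.call(rbind, lapply(seq_len(config$n_subjects), function(s) {
        y[s, , ]
      }))
      wf_path <- file.path(out_dir, "waveforms",
                           sprintf("%s_%s.csv", leg, j))
      write_waveform_matrix(
        mat, wf_path,
        meta = list(config_hash = hash, leg = leg, joint = j,
                    conditions = conditions,
                    layout = "subject-major rows, one condition row each"))
      jsonlite::write_json(
        list(config_hash = hash, leg = leg, joint = j,
             f_field = spm$f_field, mse_field = spm$mse_field,
             df = spm$df, f_crit = spm$f_crit, fwhm = spm$fwhm,
             clusters = spm$clusters,
             posthoc = lapply(ph, function(p) {
               list(pair = p$pair, t_crit = p$t_crit,
                    alpha_adjusted = p$alpha_adjusted,
                    clusters = p$clusters)
             })),
        file.path(out_dir, "spm", sprintf("%s_%s.json", leg, j)),
        auto_unbox = TRUE, digits = NA)
      results$legs[[leg]][[j]] <- list(
        f_crit = spm$f_crit, fwhm = spm$fwhm,
        n_clusters = nrow(spm$clusters), clusters = spm$clusters)
    }
    fig <- file.path(out_dir, "figures", sprintf("report_%s.png", leg))
    stage("report", four_row_report(joint_results, per_subject, fig,
                                    perturb_node = perturb_pct))
  }

  stage("io", write_trigger_log(triggers, file.path(out_dir, "triggers.csv")))
  jsonlite::write_json(
    c(list(config_hash = hash),
      lapply(unclass(config)[c("n_subjects", "n_walk_trials", "n_fall_trials",
                               "fall_condition", "duration", "imu_rate",
                               "alpha", "phase_source", "seed")], identity)),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(results = results, out_dir = out_dir, hash = hash))
}
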