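# Independent scalar oracles and small fixture builders used across tests.

# textbook one-way repeated-measures ANOVA F at a single node, via stats::aov
scalar_rm_f <- function(y_node) {
  n <- nrow(y_node); k <- ncol(y_node)
  df <- data.frame(y = as.vector(y_node),
                   subj = factor(rep(seq_len(n), k)),
                   cond = factor(rep(seq_len(k), each = n)))
  s <- summary(stats::aov(y ~ cond + Error(subj), data = df))
  s[["Error: Within"]][[1]]["cond", "F value"]
}

# textbook one-way between-groups ANOVA F at a single node
scalar_between_f <- function(y_node) {
  n <- nrow(y_node); k <- ncol(y_node)
  df <- data.frame(y = as.vector(y_node),
                   cond = factor(rep(seq_len(k), each = n)))
  stats::anova(stats::lm(y ~ cond, data = df))["cond", "F value"]
}

# quick synthetic trial cache (generation is cheap but repeated a lot)
default_trial <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_walk(walk_params(duration = 15, seed = 7))
    }
    cache
  }
})

# phase stream built from generator ground truth
truth_stream <- function(trial) {
  structure(list(t = trial$imu$t, phase = trial$truth_phase,
                 segment = discretize_phase(trial$truth_phase)),
            class = "phase_series")
}
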