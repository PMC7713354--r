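test_that("F field equals the scalar ANOVA oracle at every node", {
  y <- generate_null_dataset(null_dataset_spec(n_subjects = 6, n_nodes = 15,
                                               fwhm = 4, seed = 11))[, , 1, ]
  an <- rm_anova_field(y)
  for (q in seq_len(15)) {
    expect_equal(an$f_field[q], scalar_rm_f(y[, , q]), tolerance = 1e-8)
  }
  expect_identical(an$df, c(2, 10))
  # between-trials design against the scalar one-way oracle
  anb <- rm_anova_field(y, design = "between")
  for (q in c(1, 7, 15)) {
    expect_equal(anb$f_field[q], scalar_between_f(y[, , q]), tolerance = 1e-8)
  }
  expect_identical(anb$df, c(2, 15))
})

test_that("repeated-measures blocking removes subject offsets", {
  y <- generate_null_dataset(null_dataset_spec(n_subjects = 5, n_nodes = 20,
                                               fwhm = 5, seed = 12))[, , 1, ]
  f0 <- rm_anova_field(y)$f_field
  y_off <- y
  for (i in 1:5) y_off[i, , ] <- y_off[i, , ] + i * 10
  expect_equal(rm_anova_field(y_off)$f_field, f0, tolerance = 1e-8)
  # equal condition means at a node give F = 0 there
  y0 <- array(0, c(3, 3, 2))
  y0[, , 1] <- cbind(c(0, 1, -1), c(1, -1, 0), c(-1, 0, 1))  # means all 0
  y0[, , 2] <- y0[, , 1] + matrix(c(1, 2, 3), 3, 3) * 0.5
  expect_equal(rm_anova_field(y0)$f_field[1], 0, tolerance = 1e-12)
})

test_that("smoothness estimation is scale-invariant with a white-noise floor", {
  set.seed(31)
  r <- matrix(rnorm(200 * 101), 200, 101)
  w <- estimate_fwhm(r)
  # discrete white-noise floor of the gradient-based estimator
  # (central differences): about 2.3 nodes
  expect_gt(w, 2.0)
  expect_lt(w, 2.6)
  expect_equal(estimate_fwhm(r * 10), w, tolerance = 1e-12)
  expect_warning(wc <- estimate_fwhm(matrix(0, 10, 20)), "constant")
  expect_identical(wc, Inf)
})

test_that("smoothness recovery is within 15% for FWHM 5-25", {
  for (w in c(5, 15, 25)) {
    est <- vapply(1:30, function(i) {
      y <- generate_null_dataset(null_dataset_spec(fwhm = w,
                                                   seed = 300 + i))[, , 1, ]
      estimate_fwhm(rm_anova_field(y)$residuals)
    }, numeric(1))
    expect_lt(abs(mean(est) - w) / w, 0.15)
  }
})

test_that("RFT threshold is ordered, resel-monotone, and has the right limits", {
  df <- c(2, 12)
  u10 <- rft_threshold(0.05, df, 101, 10)
  u20 <- rft_threshold(0.05, df, 101, 20)
  expect_gt(u10, u20)
  pointwise <- stats::qf(0.95, df[1], df[2])
  expect_gt(u20, pointwise)
  # vanishing-resel limit approaches the scalar quantile from above
  u_huge <- rft_threshold(0.05, df, 101, 5000)
  expect_gt(u_huge, pointwise)
  expect_lt((u_huge - pointwise) / pointwise, 0.05)
  expect_error(rft_threshold(1.5, df, 101, 10), "alpha")
  expect_error(rft_threshold(0.05, c(0, 2), 101, 10), "degrees of freedom")
  # one denominator df: no finite t threshold exists
  expect_error(rft_threshold(0.05, 1, 101, 10, stat = "T"), "finite")
})

test_that("the squared paired-t field is the two-condition F field", {
  y <- generate_null_dataset(null_dataset_spec(n_conditions = 2, fwhm = 12,
                                               seed = 21))[, , 1, ]
  an <- rm_anova_field(y)
  ph <- posthoc_pairwise(y, alpha = 0.05)
  expect_length(ph, 1L)
  expect_equal(ph[[1]]$t_field^2, an$f_field, tolerance = 1e-10)
})

test_that("post-hoc maps are Bonferroni-corrected over all pairs", {
  y <- generate_null_dataset(null_dataset_spec(fwhm = 15, seed = 22))[, , 1, ]
  ph <- posthoc_pairwise(y, alpha = 0.05, conditions = c("NW", "SW", "TS"))
  expect_length(ph, 3L)
  expect_named(ph, c("NW_vs_SW", "NW_vs_TS", "SW_vs_TS"))
  for (p in ph) expect_equal(p$alpha_adjusted, 0.05 / 3)
  # identical conditions: no suprathreshold clusters on this null draw
  expect_true(all(vapply(ph, function(p) nrow(p$clusters) == 0, logical(1))))
})

test_that("cluster extraction is strict and maximal", {
  f <- rep(1, 101)
  expect_identical(nrow(find_clusters(f, 2)), 0L)
  f[41:51] <- 5
  cl <- find_clusters(f, 2)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$start_node, 40L)
  expect_identical(cl$end_node, 50L)
  expect_equal(cl$start_pct, 40)
  expect_equal(cl$end_pct, 50)
  # a node exactly at the threshold is excluded
  f2 <- rep(0, 101); f2[10] <- 2
  expect_identical(nrow(find_clusters(f2, 2)), 0L)
})

test_that("colour bins are unit-F intervals above the threshold", {
  f_crit <- 7.3
  expect_identical(colour_map(c(0, 7.29), f_crit), c(0L, 0L))
  expect_identical(colour_map(f_crit + 2.5, f_crit), 3L)
  expect_identical(colour_map(f_crit + 0.01, f_crit), 1L)
  f <- seq(0, 30, by = 0.1)
  expect_true(all(diff(colour_map(f, f_crit)) >= 0))
})

test_that("permutation threshold is seeded, bounded, and exact when possible", {
  y <- generate_null_dataset(null_dataset_spec(fwhm = 15, seed = 23))[, , 1, ]
  a <- permutation_threshold(y, n_perm = 300, seed = 5)
  b <- permutation_threshold(y, n_perm = 300, seed = 5)
  expect_identical(a$threshold, b$threshold)
  # alpha = 1: threshold at the distribution minimum
  low <- permutation_threshold(y, alpha = 1, n_perm = 300, seed = 5)
  expect_equal(low$threshold, min(low$max_f))
  # tiny design: exact enumeration of (k!)^n arrangements
  ys <- generate_null_dataset(null_dataset_spec(n_subjects = 3,
                                                n_conditions = 2,
                                                n_nodes = 20, fwhm = 4,
                                                seed = 24))[, , 1, ]
  ex <- permutation_threshold(ys, n_perm = 500, seed = 1)
  expect_true(ex$exact)
  expect_identical(ex$n_perm_used, 8L)
})

test_that("spm_anova assembles a coherent result object", {
  y <- generate_null_dataset(null_dataset_spec(fwhm = 15, seed = 25))[, , 1, ]
  s <- spm_anova(y)
  expect_s3_class(s, "spm_result")
  expect_length(s$f_field, 101L)
  expect_identical(s$df, c(2, 12))
  expect_identical(s$colour_bins, colour_map(s$f_field, s$f_crit))
  expect_identical(s$clusters, find_clusters(s$f_field, s$f_crit))
  expect_output(print(s), "spm_result")
})

test_that("the four-row report draws shading that matches the clusters", {
  y_eff <- generate_null_dataset(null_dataset_spec(fwhm = 15,
                                                   seed = 26))[, , 1, ]
  # add a strong mid-swing effect to one condition so a cluster exists
  bump <- 3 * exp(-0.5 * ((0:100 - 75) / 6)^2)
  for (i in 1:7) y_eff[i, 3, ] <- y_eff[i, 3, ] + bump
  s <- spm_anova(y_eff)
  expect_gt(nrow(s$clusters), 0L)
  jr <- list()
  for (j in c("hip", "knee", "ankle")) {
    jr[[j]] <- list(cond_means = apply(y_eff, c(2, 3), mean),
                    cond_sds = apply(y_eff, c(2, 3), sd),
                    conditions = c("NW", "SW", "TS"), spm = s)
  }
  per_subject <- lapply(jr, function(x) {
    lapply(1:7, function(i) colour_map(s$f_field, s$f_crit))
  })
  f <- tempfile(fileext = ".png")
  drawn <- four_row_report(jr, per_subject, f, perturb_node = 80)
  expect_true(file.exists(f) && file.size(f) > 0)
  expect_identical(drawn$knee, s$clusters)
  # missing joint: column omitted with a warning, three-row degradation
  f2 <- tempfile(fileext = ".png")
  expect_warning(four_row_report(jr[c("hip", "knee")], NULL, f2),
                 "missing joint")
  expect_true(file.exists(f2))
})
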