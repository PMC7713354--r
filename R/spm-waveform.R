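# One-dimensional statistical parametric mapping of gait waveforms:
# pointwise repeated-measures ANOVA fields, random-field-theory critical
# thresholds (expected Euler characteristic of the F field), permutation
# thresholds, suprathreshold clusters, MSE colour maps, post-hoc paired t
# fields, and the four-row report figure.

#' Pointwise one-way ANOVA field over waveform nodes
#'
#' At each node independently, decomposes the total sum of squares. For the
#' repeated-measures design (subjects as blocks)
#' `SS_total = SS_conditions + SS_subjects + SS_error` and
#' `F = (SS_cond / (k-1)) / (SS_error / ((k-1)(n-1)))`; the between-subject
#' variance never enters the error term. For per-subject analyses (trials as
#' replicates, no blocking) a one-way between-trials ANOVA is used with
#' denominator degrees of freedom `N - k`.
#'
#' @param y numeric array `n x k x Q` (subjects or trials, conditions,
#'   nodes); the design must be balanced.
#' @param design `"repeated"` (default) or `"between"`.
#' @return list with `f_field` (length Q), `mse_field`, `df` (numerator,
#'   denominator), and `residuals` (`n*k x Q` matrix of model residuals, for
#'   smoothness estimation).
#' @export
rm_anova_field <- function(y, design = c("repeated", "between")) {
  design <- match.arg(design)
  stopifnot(is.array(y), length(dim(y)) == 3)
  n <- dim(y)[1]; k <- dim(y)[2]; q <- dim(y)[3]
  if (k < 2 || n < 2) stop("need >= 2 conditions and >= 2 rows", call. = FALSE)
  ymat <- matrix(y, n * k, q)                  # rows: subject fastest
  grand <- colMeans(ymat)
  cond_means <- t(apply(y, c(2, 3), mean))     # Q x k
  ss_cond <- n * colSums((t(cond_means) - matrix(grand, k, q, byrow = TRUE))^2)
  if (design == "repeated") {
    subj_means <- t(apply(y, c(1, 3), mean))   # Q x n
    ss_subj <- k * colSums((t(subj_means) - matrix(grand, n, q, byrow = TRUE))^2)
    ss_tot <- colSums((ymat - matrix(grand, n * k, q, byrow = TRUE))^2)
    ss_err <- pmax(ss_tot - ss_subj - ss_cond, 0)
    df <- c(k - 1, (k - 1) * (n - 1))
    # residuals: y_ij - subj_i - cond_j + grand
    resid <- ymat
    for (j in seq_len(k)) {
      rows <- (j - 1) * n + seq_len(n)
      resid[rows, ] <- matrix(y[, j, ], n, q) - t(subj_means) -
        matrix(cond_means[, j], n, q, byrow = TRUE) +
        matrix(grand, n, q, byrow = TRUE)
    }
  } else {
    ss_tot <- colSums((ymat - matrix(grand, n * k, q, byrow = TRUE))^2)
    ss_err <- pmax(ss_tot - ss_cond, 0)
    df <- c(k - 1, n * k - k)
    resid <- ymat
    for (j in seq_len(k)) {
      rows <- (j - 1) * n + seq_len(n)
      resid[rows, ] <- matrix(y[, j, ], n, q) -
        matrix(cond_means[, j], n, q, byrow = TRUE)
    }
  }
  mse <- ss_err / df[2]
  f <- (ss_cond / df[1]) / mse
  list(f_field = f, mse_field = mse, df = df, residuals = resid)
}

#' Estimate field smoothness (FWHM) from model residuals
#'
#' Ratio of the variance of the normalized residual gradients to the
#' residual variance, converted to the full width at half maximum of the
#' Gaussian kernel that would produce that ratio on white noise. Invariant
#' to rescaling of the residuals. Central differences in the interior,
#' one-sided at the edges.
#'
#' @param residuals numeric matrix, observations x nodes.
#' @return FWHM in nodes; `Inf` (with a warning) for constant residuals.
#' @export
estimate_fwhm <- function(residuals) {
  r <- as.matrix(residuals)
  q <- ncol(r)
  ssq <- colSums(r^2)
  if (all(ssq < 1e-24)) {
    warning("constant residuals: smoothness is unidentifiable (infinite)")
    return(Inf)
  }
  # np.gradient-style derivative along nodes
  g <- r
  g[, 2:(q - 1)] <- (r[, 3:q] - r[, 1:(q - 2)]) / 2
  g[, 1] <- r[, 2] - r[, 1]
  g[, q] <- r[, q] - r[, q - 1]
  v <- colSums(g^2) / (ssq + .Machine$double.eps)
  v <- v[is.finite(v) & v > 0]
  if (length(v) == 0) return(Inf)
  resels_per_node <- sqrt(v / (4 * log(2)))
  1 / mean(resels_per_node)
}

# 1D Euler-characteristic density of F and t random fields (unit-variance
# underlying Gaussian components), after Worsley's unified formulas
ec_density_1d <- function(u, df, stat = c("F", "T")) {
  stat <- match.arg(stat)
  if (stat == "F") {
    # prefactor sqrt(4 log 2 / 2 pi): reduces to twice the t density at
    # sqrt(u) when df1 = 1 (the t^2 field identity)
    v1 <- df[1]; v2 <- df[2]
    a <- exp(lgamma((v1 + v2 - 1) / 2) - lgamma(v1 / 2) - lgamma(v2 / 2))
    sqrt(4 * log(2) / (2 * pi)) * a * sqrt(2) *
      (v1 * u / v2)^((v1 - 1) / 2) *
      (1 + v1 * u / v2)^(-(v1 + v2 - 2) / 2)
  } else {
    v <- df[length(df)]
    sqrt(4 * log(2)) / (2 * pi) * (1 + u^2 / v)^(-(v - 1) / 2)
  }
}

# expected suprathreshold-cluster count (expected EC) over a 1D search
# region: point term + resel term
expected_ec <- function(u, df, resels, stat = "F", two_tailed = FALSE) {
  p0 <- if (stat == "F") {
    stats::pf(u, df[1], df[2], lower.tail = FALSE)
  } else {
    stats::pt(u, df[length(df)], lower.tail = FALSE)
  }
  e <- p0 + resels * ec_density_1d(u, df, stat)
  if (two_tailed) 2 * e else e
}

#' Random-field-theory critical threshold for a waveform field
#'
#' The smallest statistic height at which the expected number of
#' suprathreshold clusters of a smooth random field over the search region
#' (extent `(Q-1) / fwhm` resels) equals `alpha` — the threshold at which
#' 5% (at the default alpha) of null statistical maps of the same
#' smoothness would be expected to contain a significant region. Monotone
#' decreasing in `fwhm` and never below the pointwise `(1 - alpha)`
#' quantile.
#'
#' @param alpha significance level in (0, 1).
#' @param df degrees of freedom: `c(df1, df2)` for F, denominator df for t.
#' @param n_nodes number of field nodes Q.
#' @param fwhm field smoothness in nodes.
#' @param stat `"F"` or `"T"`.
#' @param two_tailed for t fields, split alpha over both tails.
#' @return critical threshold.
#' @export
rft_threshold <- function(alpha, df, n_nodes, fwhm, stat = "F",
                          two_tailed = FALSE) {
  if (!(alpha > 0 && alpha < 1)) {
    stop("invalid parameter: alpha must be in (0, 1)", call. = FALSE)
  }
  if (any(df <= 0)) stop("invalid degrees of freedom", call. = FALSE)
  check_positive(fwhm, "fwhm")
  resels <- (n_nodes - 1) / fwhm
  f <- function(u) expected_ec(u, df, resels, stat, two_tailed) - alpha
  lo <- if (stat == "F") stats::qf(1 - alpha, df[1], df[2]) else 0
  if (f(lo) < 0) return(lo)       # one-resel limit: pointwise quantile
  hi <- lo + 1
  while (f(hi) > 0 && hi < 1e12) hi <- hi * 2
  if (f(hi) > 0) {
    # with 1 denominator df the t-field EC density does not decay: the
    # expected cluster count never drops to alpha and no finite threshold
    # exists
    stop("no finite random-field threshold for these degrees of freedom; increase the sample size",
         call. = FALSE)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Permutation critical threshold for the ANOVA field
#'
#' Nonparametric counterpart of [rft_threshold()]: the `(1 - alpha)`
#' quantile of the maximum-over-nodes F statistic under within-subject
#' permutation of the condition labels (each subject's condition set is
#' permuted independently — the repeated-measures exchangeability unit).
#' Falls back to exact enumeration when the number of distinct
#' arrangements does not exceed `n_perm`.
#'
#' @param y array `n x k x Q`.
#' @param alpha significance level.
#' @param n_perm number of permutations (>= 500 recommended).
#' @param seed RNG seed; the result is deterministic under it.
#' @param design passed to [rm_anova_field()].
#' @return list `threshold`, `max_f` (the permutation distribution),
#'   `n_perm_used`, `exact`.
#' @export
permutation_threshold <- function(y, alpha = 0.05, n_perm = 1000, seed = 1L,
                                  design = "repeated") {
  stopifnot(is.array(y), length(dim(y)) == 3)
  n <- dim(y)[1]; k <- dim(y)[2]; q <- dim(y)[3]
  restore <- local_seed(seed)
  on.exit(restore())

  # invariants under within-subject label permutation
  ymat <- matrix(y, n * k, q)
  grand <- colMeans(ymat)
  ss_tot <- colSums((ymat - matrix(grand, n * k, q, byrow = TRUE))^2)
  subj_means <- t(apply(y, c(1, 3), mean))
  ss_subj <- k * colSums((t(subj_means) - matrix(grand, n, q, byrow = TRUE))^2)
  df <- c(k - 1, (k - 1) * (n - 1))
  grand_k <- matrix(grand, k, q, byrow = TRUE)

  slices <- lapply(seq_len(n), function(i) matrix(y[i, , ], k, q))

  max_f_for <- function(perm_mat) {  # perm_mat: n x k, row i permutes subject i
    csum <- matrix(0, k, q)
    for (i in seq_len(n)) csum <- csum + slices[[i]][perm_mat[i, ], ]
    cmean <- csum / n
    ss_cond <- n * colSums((cmean - grand_k)^2)
    ss_err <- pmax(ss_tot - ss_subj - ss_cond, .Machine$double.eps)
    max((ss_cond / df[1]) / (ss_err / df[2]))
  }

  all_perms <- function(k) {
    if (k == 1) return(matrix(1L, 1, 1))
    sub <- all_perms(k - 1)
    do.call(rbind, lapply(seq_len(k), function(pos) {
      cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
            sub[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
    }))
  }
  kfact <- factorial(k)
  n_arrangements <- kfact^n
  exact <- is.finite(n_arrangements) && n_arrangements <= n_perm
  if (exact) {
    pk <- all_perms(k)
    idx <- expand.grid(rep(list(seq_len(kfact)), n))
    max_f <- apply(idx, 1, function(row) {
      max_f_for(pk[unlist(row), , drop = FALSE])
    })
    n_used <- nrow(idx)
  } else {
    max_f <- numeric(n_perm)
    max_f[1] <- max_f_for(matrix(rep(seq_len(k), n), n, k, byrow = TRUE))
    for (b in 2:n_perm) {
      pm <- t(vapply(seq_len(n), function(i) sample.int(k), integer(k)))
      max_f[b] <- max_f_for(pm)
    }
    n_used <- n_perm
  }
  list(threshold = stats::quantile(max_f, 1 - alpha, names = FALSE, type = 7),
       max_f = max_f, n_perm_used = n_used, exact = exact)
}

#' Suprathreshold clusters of a statistic field
#'
#' Maximal contiguous runs of nodes with field value strictly above the
#' threshold (a node exactly at the threshold is excluded).
#'
#' @param f_field numeric field over Q nodes.
#' @param f_crit threshold.
#' @return data frame `start_node`, `end_node` (0-based node indices) and
#'   `start_pct`, `end_pct` (percent of gait cycle); zero rows if nothing
#'   exceeds.
#' @export
find_clusters <- function(f_field, f_crit) {
  above <- f_field > f_crit
  q <- length(f_field)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start_node = starts[keep] - 1L, end_node = ends[keep] - 1L,
             start_pct = (starts[keep] - 1L) / (q - 1) * 100,
             end_pct = (ends[keep] - 1L) / (q - 1) * 100)
}

#' Colour-map binning of a thresholded F field
#'
#' The F statistic is the mean condition effect per unit of error variance,
#' so one unit of F corresponds to one mean square of error: nodes below
#' the threshold map to bin 0, nodes above it to
#' `floor(F - F_crit) + 1` (unit-F intervals above the threshold).
#'
#' @param f_field numeric field.
#' @param f_crit threshold.
#' @return integer vector of bins, monotone in F.
#' @export
colour_map <- function(f_field, f_crit) {
  as.integer(ifelse(f_field > f_crit, floor(f_field - f_crit) + 1, 0))
}

#' Full SPM repeated-measures ANOVA of a waveform dataset
#'
#' Runs the ANOVA field, estimates the residual smoothness, computes the
#' random-field-theory critical threshold at `alpha`, and extracts
#' suprathreshold clusters and the MSE colour map.
#'
#' @param y array `n x k x Q`.
#' @param alpha significance level (default 0.05).
#' @param design `"repeated"` or `"between"` (see [rm_anova_field()]).
#' @return object of class `spm_result`.
#' @export
spm_anova <- function(y, alpha = 0.05, design = "repeated") {
  an <- rm_anova_field(y, design = design)
  fwhm <- estimate_fwhm(an$residuals)
  q <- length(an$f_field)
  f_crit <- rft_threshold(alpha, an$df, q, min(fwhm, q - 1))
  structure(list(f_field = an$f_field, mse_field = an$mse_field,
                 df = an$df, f_crit = f_crit,
                 clusters = find_clusters(an$f_field, f_crit),
                 colour_bins = colour_map(an$f_field, f_crit),
                 fwhm = fwhm, resels = (q - 1) / min(fwhm, q - 1),
                 alpha = alpha, design = design),
            class = "spm_result")
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf(
    "spm_result: F(%d, %d) field over %d nodes, FWHM %.1f, F_crit %.2f (alpha %.3g)\n",
    x$df[1], x$df[2], length(x$f_field), x$fwhm, x$f_crit, x$alpha))
  if (nrow(x$clusters) == 0) {
    cat("  no suprathreshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters))) {
      cat(sprintf("  cluster %d: %.0f%% - %.0f%% of gait cycle\n", i,
                  x$clusters$start_pct[i], x$clusters$end_pct[i]))
    }
  }
  invisible(x)
}

#' Bonferroni-corrected post-hoc paired t fields
#'
#' One paired (repeated-measures) two-tailed t field per condition pair,
#' each thresholded by random field theory for t fields at
#' `alpha / (number of pairs)`.
#'
#' @param y array `n x k x Q`.
#' @param alpha family significance level before correction.
#' @param conditions optional condition labels (length k).
#' @return list of per-pair results: `pair`, `t_field`, `df`, `t_crit`,
#'   `clusters` (on `|t|`), `fwhm`, `alpha_adjusted`.
#' @export
posthoc_pairwise <- function(y, alpha = 0.05, conditions = NULL) {
  stopifnot(is.array(y), length(dim(y)) == 3)
  n <- dim(y)[1]; k <- dim(y)[2]; q <- dim(y)[3]
  if (n < 2) stop("need >= 2 subjects for paired comparisons", call. = FALSE)
  if (is.null(conditions)) conditions <- paste0("C", seq_len(k))
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  alpha_adj <- alpha / n_pairs
  out <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    a <- pairs[1, p]; b <- pairs[2, p]
    d <- matrix(y[, a, ] - y[, b, ], n, q)
    m <- colMeans(d)
    s <- sqrt(colSums((d - matrix(m, n, q, byrow = TRUE))^2) / (n - 1))
    t_field <- m / (s / sqrt(n))
    resid <- d - matrix(m, n, q, byrow = TRUE)
    fwhm <- estimate_fwhm(resid)
    t_crit <- rft_threshold(alpha_adj, n - 1, q, min(fwhm, q - 1),
                            stat = "T", two_tailed = TRUE)
    out[[p]] <- list(pair = c(conditions[a], conditions[b]),
                     t_field = t_field, df = n - 1, t_crit = t_crit,
                     clusters = find_clusters(abs(t_field), t_crit),
                     fwhm = fwhm, alpha_adjusted = alpha_adj)
  }
  names(out) <- apply(pairs, 2,
                      function(ab) paste(conditions[ab], collapse = "_vs_"))
  out
}

#' Four-row SPM report figure
#'
#' One column per joint (hip, knee, ankle): row 1 condition mean and SD
#' clouds; row 2 the F field with the dotted critical threshold and grey
#' suprathreshold shading; row 3 the MSE colour map; row 4 per-subject
#' significance strips. A vertical divider marks the stance/swing boundary
#' at node 60, and an optional marker the perturbation-onset node. With no
#' per-subject results a three-row figure is drawn.
#'
#' @param joint_results named list (joints as names); each element a list
#'   with `cond_means` (k x Q matrix), `cond_sds` (k x Q), `conditions`
#'   (labels), `spm` (an `spm_result`).
#' @param per_subject optional named list (same joints); each element a
#'   list of per-subject integer colour-bin vectors (length Q).
#' @param file output image path (`.png` or `.pdf`).
#' @param perturb_node optional 0-based node of perturbation onset.
#' @param joints columns to draw, in order; missing ones are dropped with a
#'   warning.
#' @return invisibly, the per-joint cluster tables actually shaded.
#' @export
four_row_report <- function(joint_results, per_subject = NULL, file,
                            perturb_node = NULL,
                            joints = c("hip", "knee", "ankle")) {
  have <- joints[joints %in% names(joint_results)]
  if (length(have) < length(joints)) {
    warning(sprintf("missing joint column(s): %s",
                    paste(setdiff(joints, have), collapse = ", ")))
  }
  if (length(have) == 0) stop("no joint results to draw", call. = FALSE)
  n_rows <- if (is.null(per_subject)) 3L else 4L

  ext <- tolower(tools::file_ext(file))
  if (ext == "pdf") {
    grDevices::pdf(file, width = 3.2 * length(have), height = 2.2 * n_rows)
  } else {
    grDevices::png(file, width = 320 * length(have), height = 220 * n_rows)
  }
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(n_rows, length(have)), mar = c(2.5, 3, 1.5, 0.5),
                mgp = c(1.6, 0.5, 0), cex = 0.7)
  drawn <- list()

  pct <- function(q) seq(0, 100, length.out = q)
  add_markers <- function() {
    graphics::abline(v = 60, lty = 3, col = "black")
    if (!is.null(perturb_node)) {
      graphics::abline(v = perturb_node, lty = 4, col = "cyan3")
    }
  }

  for (row in seq_len(n_rows)) {
    for (j in have) {
      jr <- joint_results[[j]]
      q <- length(jr$spm$f_field)
      x <- pct(q)
      if (row == 1) {
        k <- nrow(jr$cond_means)
        cols <- grDevices::hcl.colors(k, "Dark 3")
        ylim <- range(jr$cond_means + jr$cond_sds,
                      jr$cond_means - jr$cond_sds)
        graphics::plot(NA, xlim = c(0, 100), ylim = ylim,
                       xlab = "% gait cycle", ylab = "angle (deg)",
                       main = j)
        for (c_i in seq_len(k)) {
          graphics::polygon(c(x, rev(x)),
                            c(jr$cond_means[c_i, ] + jr$cond_sds[c_i, ],
                              rev(jr$cond_means[c_i, ] - jr$cond_sds[c_i, ])),
                            col = grDevices::adjustcolor(cols[c_i], 0.2),
                            border = NA)
          graphics::lines(x, jr$cond_means[c_i, ], col = cols[c_i])
        }
        if (j == have[1]) {
          graphics::legend("topright", legend = jr$conditions, col = cols,
                           lwd = 1, bty = "n", cex = 0.8)
        }
        add_markers()
      } else if (row == 2) {
        spm <- jr$spm
        graphics::plot(x, spm$f_field, type = "l", xlab = "% gait cycle",
                       ylab = "F", main = sprintf("SPM{F} %s", j))
        graphics::abline(h = spm$f_crit, lty = 2)
        cl <- spm$clusters
        if (nrow(cl) > 0) {
          for (i in seq_len(nrow(cl))) {
            sel <- x >= cl$start_pct[i] & x <= cl$end_pct[i]
            graphics::polygon(c(x[sel], rev(x[sel])),
                              c(pmax(spm$f_field[sel], spm$f_crit),
                                rep(spm$f_crit, sum(sel))),
                              col = "grey70", border = NA)
          }
        }
        drawn[[j]] <- cl
        add_markers()
      } else if (row == 3) {
        bins <- jr$spm$colour_bins
        top <- max(bins, 1)
        pal <- c("white", grDevices::hcl.colors(max(top, 2), "Reds",
                                                rev = TRUE))
        graphics::image(x, 1, matrix(bins, ncol = 1),
                        col = pal[seq_len(top + 1)],
                        zlim = c(0, top), xlab = "% gait cycle", ylab = "",
                        yaxt = "n", main = sprintf("MSE intervals %s", j))
        add_markers()
      } else {
        subj <- per_subject[[j]]
        ns <- length(subj)
        if (ns == 0) {
          graphics::plot.new()
          next
        }
        mat <- do.call(cbind, subj)
        top <- max(mat, 1)
        pal <- c("white", grDevices::hcl.colors(max(top, 2), "Reds",
                                                rev = TRUE))
        graphics::image(x, seq_len(ns), mat, col = pal[seq_len(top + 1)],
                        zlim = c(0, top), xlab = "% gait cycle",
                        ylab = "subject", yaxt = "n",
                        main = sprintf("per-subject %s", j))
        graphics::axis(2, at = seq_len(ns), labels = paste0("S", seq_len(ns)),
                       las = 1, cex.axis = 0.6)
        add_markers()
      }
    }
  }
  invisible(drawn)
}
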