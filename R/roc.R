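# Sliding-window ROC analysis. Per window, each trial is summarized by its
# mean dF/F (or rate), and the AUC between the per-trial distributions is the
# rank (Mann-Whitney) statistic P(A > B) + 0.5 P(A = B): 0.5 means no
# discrimination, > 0.5 activation (or selectivity for condition 1).

# AUC by average ranks; equals pairwise enumeration including tie halving.
rank_auc <- function(a, b) {
  r <- rank(c(a, b))
  (sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2) /
    (length(a) * length(b))
}

# Half-open sample selection [start, end) shared by the sliding test windows
# and the fixed control window, so a test window at the control position
# selects exactly the control samples.
halfopen_index <- function(time_axis, window) {
  dt <- time_axis[2] - time_axis[1]
  which(time_axis >= window[1] - dt / 2 & time_axis < window[2] - dt / 2)
}

roc_windows <- function(time_axis, test_width, step) {
  starts <- seq(time_axis[1], max(time_axis) - test_width + 1e-9, by = step)
  centers <- starts + test_width / 2
  idx <- lapply(starts, function(s)
    halfopen_index(time_axis, c(s, s + test_width)))
  keep <- lengths(idx) > 0
  list(centers = centers[keep], idx = idx[keep])
}

#' Sliding-window ROC activation profile
#'
#' Slides a 200 ms test window in 50 ms steps over the trial and, for each
#' position, computes the AUC between per-trial mean responses in the test
#' window and in a fixed 200 ms control window just before trial onset
#' (default -2 to -1.8 s). AUC > 0.5 indicates activation above the control
#' period, AUC < 0.5 inhibition. Window positions extending past the time
#' axis are dropped. Optional per-window permutation p-values come from
#' shuffling the test/control labels.
#'
#' @param m an [erf_matrix()] or [peth_matrix()].
#' @param test_width sliding test window width (s).
#' @param step window advance step (s).
#' @param control_window fixed control window `c(start, end)` (s).
#' @param n_perm label-shuffling permutations per window for p-values; `0`
#'   skips p-values (`p = NA`).
#' @param seed integer seed.
#' @return A list of class `roc_profile`: `window_centers` (s), `auc`, `p`,
#'   plus the window parameters. Windows where all values are equal are
#'   flagged and given `auc = 0.5`.
#' @export
sliding_roc <- function(m, test_width = 0.2, step = 0.05,
                        control_window = c(-2, -1.8), n_perm = 1000,
                        seed = 1) {
  v <- m$values %||% m$rates
  if (nrow(v) < 2L) stop("need at least two trials")
  time_axis <- m$time_axis
  c_idx <- halfopen_index(time_axis, control_window)
  if (!length(c_idx)) stop("control window does not overlap the time axis")
  ctrl <- rowMeans(v[, c_idx, drop = FALSE])
  w <- roc_windows(time_axis, test_width, step)
  set.seed(seed)
  n <- nrow(v)
  auc <- p <- numeric(length(w$idx))
  flagged <- logical(length(w$idx))
  for (k in seq_along(w$idx)) {
    a <- rowMeans(v[, w$idx[[k]], drop = FALSE])
    if (all(a == a[1]) && all(ctrl == a[1])) {
      auc[k] <- 0.5; p[k] <- NA_real_; flagged[k] <- TRUE; next
    }
    auc[k] <- rank_auc(a, ctrl)
    p[k] <- if (n_perm > 0) {
      pool <- c(a, ctrl)
      d_obs <- abs(auc[k] - 0.5)
      d_null <- replicate(n_perm, {
        ix <- sample.int(2 * n, n)
        abs(rank_auc(pool[ix], pool[-ix]) - 0.5)
      })
      (1 + sum(d_null >= d_obs - 1e-12)) / (n_perm + 1)
    } else NA_real_
  }
  structure(list(window_centers = w$centers, auc = auc, p = p,
                 test_width = test_width, step = step,
                 control_window = control_window, flagged = flagged),
            class = "roc_profile")
}

#' Between-condition selectivity ROC
#'
#' AUC between two conditions' per-trial window means at each sliding-window
#' position: 1 means complete selectivity for condition 1, 0 complete
#' selectivity for condition 2, 0.5 none. Raw window means are compared (no
#' control-window normalization).
#'
#' @param m1,m2 [erf_matrix()] or [peth_matrix()] objects on the same time
#'   axis.
#' @param test_width,step window width and advance step (s).
#' @return A list of class `roc_profile` (no p-values).
#' @export
condition_roc <- function(m1, m2, test_width = 0.2, step = 0.05) {
  v1 <- m1$values %||% m1$rates
  v2 <- m2$values %||% m2$rates
  if (nrow(v1) < 2L || nrow(v2) < 2L) stop("each condition needs >= 2 trials")
  if (length(m1$time_axis) != length(m2$time_axis) ||
      any(abs(m1$time_axis - m2$time_axis) > 1e-9))
    stop("the two conditions must share one time axis")
  w <- roc_windows(m1$time_axis, test_width, step)
  auc <- vapply(w$idx, function(ix)
    rank_auc(rowMeans(v1[, ix, drop = FALSE]),
             rowMeans(v2[, ix, drop = FALSE])), 0)
  structure(list(window_centers = w$centers, auc = auc,
                 p = rep(NA_real_, length(auc)), test_width = test_width,
                 step = step, control_window = NULL,
                 flagged = rep(FALSE, length(auc))),
            class = "roc_profile")
}

#' @export
print.roc_profile <- function(x, ...) {
  cat(sprintf("<roc_profile> %d windows of %g ms (step %g ms), AUC range [%.3f, %.3f]\n",
              length(x$auc), 1000 * x$test_width, 1000 * x$step,
              min(x$auc), max(x$auc)))
  invisible(x)
}
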