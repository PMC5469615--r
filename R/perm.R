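# Multivariate permutation testing with max-|T| family-wise correction.
#
# The observed statistic is the pointwise one-sample t across trials of the
# baseline-subtracted traces. The null is built by randomly sign-flipping
# whole trial traces (a paired against-baseline design that preserves the
# within-trial autocorrelation) and recording, for each permutation, the
# maximum absolute T over all timepoints. Pointwise p-values are therefore
# corrected for the whole family of timepoints.

#' Max-|T| multivariate permutation test
#'
#' Tests, at every timepoint, whether the trial population deviates from its
#' own baseline, with family-wise correction from the maximum absolute
#' T-score over all permutations (default 1000 permutations at alpha 0.05,
#' two-tailed). Maximal runs of corrected `p < alpha` are returned as
#' significant segments, split by the sign of T.
#'
#' @param m an [erf_matrix()], [peth_matrix()], or plain trials x timepoints
#'   matrix (then supply `time_axis`).
#' @param baseline_window `c(start, end)` (s): each trial's mean over this
#'   window is subtracted from that trial before testing.
#' @param n_perm number of sign-flip permutations; values `< 100` warn.
#' @param alpha two-tailed family-wise level.
#' @param seed integer seed for the permutation draw.
#' @param exact if `TRUE` (or `n_perm >= 2^n_trials` when `2^n_trials <=
#'   4096`), enumerate all `2^n` sign patterns instead of sampling; p-values
#'   are then exact.
#' @param time_axis required when `m` is a bare matrix.
#' @return A list of class `perm_test_result`: `t_obs`, `p` (corrected,
#'   pointwise), `alpha`, `n_perm`, `segments_up`, `segments_down` (matrices
#'   of start/end seconds), `time_axis`.
#' @export
maxt_test <- function(m, baseline_window = c(-2, -0.5), n_perm = 1000,
                      alpha = 0.05, seed = 1, exact = FALSE,
                      time_axis = NULL) {
  if (inherits(m, "erf_matrix")) { x <- m$values; time_axis <- m$time_axis }
  else if (inherits(m, "peth_matrix")) { x <- m$rates; time_axis <- m$time_axis }
  else { x <- as.matrix(m)
         if (is.null(time_axis)) stop("time_axis required for a bare matrix") }
  n <- nrow(x)
  if (n < 2L) stop("need at least two trials")
  if (n_perm < 100 && !exact) warning("n_perm < 100 gives coarse p-values")
  b_idx <- window_index(time_axis, baseline_window)
  xb <- x - rowMeans(x[, b_idx, drop = FALSE])
  ss <- colSums(xb^2)
  # Sign flips leave the per-timepoint sum of squares invariant, so
  # T^2 = n (n-1) q / (1 - n q) with q = m^2 / ss, a monotone map of q while
  # n q < 1 (guaranteed by Cauchy-Schwarz). Per permutation we therefore only
  # need the row maximum of q, computed from one matrix product against
  # columns pre-scaled by 1 / (n sqrt(ss)).
  q_to_t2 <- function(q) {
    out <- n * (n - 1) * q / pmax(1 - n * q, 1e-12)
    out[q >= 1 / n - 1e-12] <- Inf
    out
  }
  pos <- ss > 0
  xs <- xb
  xs[, pos] <- sweep(xb[, pos, drop = FALSE], 2, n * sqrt(ss[pos]), "/")
  xs[, !pos] <- 0
  q_obs <- colSums(xs)^2
  t2_obs <- q_to_t2(q_obs)
  t2_obs[!pos] <- 0
  t_obs <- sign(colMeans(xb)) * sqrt(t2_obs)
  if (exact || (2^n <= 4096 && n_perm >= 2^n)) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    denom <- nrow(signs)
    add_one <- 0L
  } else {
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                    nrow = n_perm)
    denom <- n_perm + 1L
    add_one <- 1L
  }
  q_null <- (signs %*% xs)^2
  max_t2 <- q_to_t2(q_null[cbind(seq_len(nrow(q_null)),
                                 max.col(q_null, ties.method = "first"))])
  srt <- sort(max_t2)
  n_ge <- length(srt) - findInterval(t2_obs, srt, left.open = TRUE)
  p <- (add_one + n_ge) / denom
  sig <- p < alpha
  seg <- function(mask) {
    r <- logical_runs(mask)
    cbind(start_s = time_axis[r[, 1]], end_s = time_axis[r[, 2]])
  }
  structure(list(t_obs = t_obs, p = p, alpha = alpha,
                 n_perm = nrow(signs),
                 segments_up = seg(sig & t_obs > 0),
                 segments_down = seg(sig & t_obs < 0),
                 time_axis = time_axis),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf("<perm_test_result> max-|T| over %d timepoints, %d permutations, alpha %g\n",
              length(x$t_obs), x$n_perm, x$alpha))
  cat(sprintf("  %d significant increase segment(s), %d decrease segment(s)\n",
              nrow(x$segments_up), nrow(x$segments_down)))
  invisible(x)
}

#' Two-sample permutation test on response strength
#'
#' Two-tailed permutation p-value on the difference of group means under
#' label shuffling (default 1000 permutations), used to compare per-trial
#' response strengths or selectivity indices between conditions. Uses the
#' add-one convention, `p = (1 + #{|d*| >= |d|}) / (n_perm + 1)`, unless the
#' splits are exhaustively enumerated.
#'
#' @param values_a,values_b per-trial scalars, each of length `>= 2`.
#' @param n_perm number of label shuffles.
#' @param seed integer seed.
#' @param exact enumerate all splits when `choose(n, n_a) <= 4096` (forced on
#'   with `exact = TRUE`).
#' @return The p-value.
#' @export
strength_perm_test <- function(values_a, values_b, n_perm = 1000, seed = 1,
                               exact = FALSE) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 2L || nb < 2L) stop("each group needs at least two values")
  pool <- c(values_a, values_b)
  d_obs <- abs(mean(values_a) - mean(values_b))
  if (exact || choose(na + nb, na) <= 4096) {
    splits <- utils::combn(na + nb, na)
    d_null <- apply(splits, 2, function(ix)
      abs(mean(pool[ix]) - mean(pool[-ix])))
    mean(d_null >= d_obs - 1e-12)
  } else {
    set.seed(seed)
    d_null <- replicate(n_perm, {
      ix <- sample.int(na + nb, na)
      abs(mean(pool[ix]) - mean(pool[-ix]))
    })
    (1 + sum(d_null >= d_obs - 1e-12)) / (n_perm + 1)
  }
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D statistic (sup distance between empirical CDFs) and p-value for the
#' difference between two cumulative distributions.
#'
#' @param sample_a,sample_b numeric samples, each of length `>= 2`.
#' @return A list with `d` and `p`.
#' @export
ks_compare <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stop("each sample needs at least two values")
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b))
  list(d = unname(kt$statistic), p = kt$p.value)
}
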