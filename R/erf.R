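#' Event-related fluorescence matrix
#'
#' Trials x timepoints of dF/F aligned to event onset.
#'
#' @param values numeric matrix, one row per aligned event.
#' @param time_axis strictly increasing times (s) relative to event onset,
#'   uniform step.
#' @param event_label label of the aligned events.
#' @param trial_order original indices of the rows in the session event log.
#' @return An object of class `erf_matrix`.
#' @export
erf_matrix <- function(values, time_axis, event_label = "event",
                       trial_order = seq_len(nrow(values))) {
  values <- as.matrix(values)
  if (ncol(values) != length(time_axis))
    stop("time_axis length must equal the number of columns")
  bad <- first_nonincreasing(time_axis)
  if (bad) stop(sprintf("time_axis must be strictly increasing (index %d)", bad))
  structure(list(values = values, time_axis = as.numeric(time_axis),
                 event_label = as.character(event_label),
                 trial_order = trial_order),
            class = "erf_matrix")
}

#' @export
print.erf_matrix <- function(x, ...) {
  cat(sprintf("<erf_matrix> '%s': %d trials x %d timepoints [%g, %g] s\n",
              x$event_label, nrow(x$values), ncol(x$values),
              min(x$time_axis), max(x$time_axis)))
  invisible(x)
}

#' Moving-average smoothing of a fluorescence trace
#'
#' Centered moving average with the 20 ms span used for raw photometry data.
#' Edges use shrunken (one-sided) windows so the length is preserved and the
#' filter stays an average everywhere.
#'
#' @param rec a [recording()].
#' @param span filter span (s); default 0.020.
#' @return A smoothed [recording()] of the same length.
#' @export
smooth_trace <- function(rec, span = 0.020) {
  stopifnot(inherits(rec, "recording"))
  w <- max(1L, round(span * rec$rate))
  n <- length(rec$trace)
  if (w > n) stop("smoothing span exceeds the trace length")
  if (w == 1L) return(rec)
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w - 1L - half_lo
  cs <- cumsum(c(0, rec$trace))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  recording(sm, rate = rec$rate, t0 = rec$t0, channel_label = rec$channel_label)
}

#' Event-aligned dF/F matrix
#'
#' Segments the trace around each selected event and converts it to
#' fractional fluorescence change `(F - F0)/F0`, where `F0` is that trial's
#' mean raw fluorescence over the baseline window (default the 1.5 s window
#' ending 0.5 s before onset). Trials whose `F0` is not positive are excluded
#' with a warning.
#'
#' @param rec a [recording()] (typically already passed through
#'   [smooth_trace()]).
#' @param events an [event_stream()]; use `label` to select the aligned event.
#' @param label event label(s) to align to; `NULL` aligns to all events.
#' @param baseline_window `c(start, end)` (s relative to onset) of the F0
#'   window; the social-interaction convention is `c(-5, -3.5)`.
#' @param window alignment window `c(start, end)` (s relative to onset).
#' @return An [erf_matrix()].
#' @export
compute_dff <- function(rec, events, label = NULL,
                        baseline_window = c(-2, -0.5), window = c(-2, 10)) {
  stopifnot(inherits(rec, "recording"), inherits(events, "event_stream"))
  if (!is.null(label)) events <- events_with_label(events, label)
  if (!nrow(events)) stop("no events to align to")
  if (baseline_window[1] < window[1] || baseline_window[2] > window[2])
    stop("baseline_window must lie within the alignment window")
  r <- rec$rate
  i_rel <- seq(round(window[1] * r), round(window[2] * r))
  time_axis <- i_rel / r
  b_idx <- which(time_axis >= baseline_window[1] &
                   time_axis <= baseline_window[2])
  n <- length(rec$trace)
  rows <- list(); kept <- integer()
  for (k in seq_len(nrow(events))) {
    i0 <- round((events$onset[k] - rec$t0) * r)   # sample index of onset - 1
    idx <- i0 + i_rel + 1L
    if (idx[1] < 1L || idx[length(idx)] > n) {
      warning(sprintf("event %d at %.3f s: alignment window out of range; excluded",
                      k, events$onset[k]))
      next
    }
    f <- rec$trace[idx]
    f0 <- mean(f[b_idx])
    if (!is.finite(f0) || f0 <= 0) {
      warning(sprintf("event %d at %.3f s: non-positive baseline F0; excluded",
                      k, events$onset[k]))
      next
    }
    rows[[length(rows) + 1L]] <- (f - f0) / f0
    kept <- c(kept, k)
  }
  if (!length(rows)) stop("all trials excluded; no dF/F matrix to build")
  erf_matrix(do.call(rbind, rows), time_axis,
             event_label = paste(unique(events$label[kept]), collapse = "+"),
             trial_order = kept)
}

#' Pointwise mean and SEM of an event-related matrix
#'
#' @param m an [erf_matrix()] (or [peth_matrix()]).
#' @return A list of class `erf_summary` with `mean`, `sem`, `time_axis`,
#'   `n_trials`, and `single_trial` flag (SEM set to 0 when n = 1).
#' @export
erf_summary <- function(m) {
  v <- m$values %||% m$rates
  n <- nrow(v)
  if (n < 1L) stop("need at least one trial")
  mu <- colMeans(v)
  sem <- if (n > 1L) apply(v, 2, stats::sd) / sqrt(n) else rep(0, ncol(v))
  structure(list(mean = mu, sem = sem, time_axis = m$time_axis,
                 n_trials = n, single_trial = n == 1L),
            class = "erf_summary")
}

#' @export
plot.erf_summary <- function(x, xlab = "time from onset (s)",
                             ylab = "dF/F", ...) {
  graphics::plot(x$time_axis, x$mean, type = "n", xlab = xlab, ylab = ylab,
                 ylim = range(x$mean - x$sem, x$mean + x$sem), ...)
  graphics::polygon(c(x$time_axis, rev(x$time_axis)),
                    c(x$mean + x$sem, rev(x$mean - x$sem)),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(x$time_axis, x$mean, lwd = 2, col = "steelblue4")
  invisible(x)
}

#' Peak, latency, decay constant and AUC of a mean response
#'
#' Peak dF/F and time-to-peak are read off the trial-averaged trace inside the
#' response window; the decay constant comes from a Levenberg-Marquardt
#' least-squares fit of `A * exp(-(t - t_peak)/tau)` to the mean trace from
#' its peak to the window end, with `tau` initialized at the 1/e crossing.
#' The AUC is the sum of dF/F samples over the window.
#'
#' @param m an [erf_matrix()] or [erf_summary()].
#' @param response_window `c(start, end)` (s) searched for the peak.
#' @return A list of class `response_metrics`: `peak_dff`, `t_peak` (s),
#'   `tau_decay` (s, `NA` with `tau_flagged = TRUE` when the peak is not
#'   positive or the fit fails), `auc`.
#' @examples
#' t <- seq(0, 10, 0.002)
#' m <- erf_matrix(rbind(0.3 * exp(-t / 4)), t)
#' response_metrics(m, c(0, 10))$tau_decay  # 4
#' @export
response_metrics <- function(m, response_window = c(0, 10)) {
  s <- if (inherits(m, "erf_summary")) m else erf_summary(m)
  idx <- window_index(s$time_axis, response_window)
  y <- s$mean[idx]; tt <- s$time_axis[idx]
  ipk <- which.max(y)
  peak <- y[ipk]; t_peak <- tt[ipk]
  auc <- sum(y)
  tau <- NA_real_; flagged <- FALSE
  if (peak <= 0) {
    flagged <- TRUE
  } else {
    yd <- y[ipk:length(y)]; td <- tt[ipk:length(y)] - t_peak
    cross <- which(yd <= peak / exp(1))[1]
    tau0 <- if (is.na(cross)) max(td) / 2 else td[cross]
    fit <- tryCatch(
      minpack.lm::nlsLM(yd ~ A * exp(-td / tau),
                        start = list(A = peak, tau = max(tau0, 1e-3)),
                        lower = c(0, 1e-4),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) flagged <- TRUE else tau <- stats::coef(fit)[["tau"]]
  }
  structure(list(peak_dff = peak, t_peak = t_peak, tau_decay = tau,
                 auc = auc, tau_flagged = flagged),
            class = "response_metrics")
}

#' Block averages of per-trial values
#'
#' Means over consecutive non-overlapping blocks of trials (5 trials for
#' aversive conditioning sessions, 10 for appetitive); a trailing partial
#' block is averaged over its actual size.
#'
#' @param x per-trial numeric values.
#' @param block block size (`>= 1`).
#' @return Numeric vector of block means.
#' @examples
#' block_average(1:20, 5)
#' @export
block_average <- function(x, block) {
  stopifnot(block >= 1)
  as.numeric(tapply(x, ceiling(seq_along(x) / block), mean))
}

#' First block of sustained significance
#'
#' Smallest block index from which a blockwise significance flag holds for
#' every subsequent block -- the operational definition of learning onset for
#' conditioned cue responses.
#'
#' @param flags logical vector, one flag per block.
#' @return Integer block index, or `NA_integer_` if the criterion is never
#'   sustained.
#' @export
learning_onset <- function(flags) {
  stopifnot(is.logical(flags), length(flags) >= 2L)
  ok <- rev(cumprod(rev(flags))) > 0    # TRUE where all later flags are TRUE
  if (!any(ok)) NA_integer_ else which(ok)[1]
}
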