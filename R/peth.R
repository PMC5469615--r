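#' Peri-event time histogram matrix
#'
#' @param rates trials x bins matrix of firing rates (spikes/s).
#' @param bin_width bin width (s).
#' @param time_axis bin centers (s relative to event onset).
#' @param smoothing_sigma Gaussian sd (s) already applied, or `NULL`.
#' @return An object of class `peth_matrix`.
#' @export
peth_matrix <- function(rates, bin_width, time_axis, smoothing_sigma = NULL) {
  rates <- as.matrix(rates)
  stopifnot(ncol(rates) == length(time_axis), bin_width > 0)
  structure(list(rates = rates, bin_width = bin_width,
                 time_axis = as.numeric(time_axis),
                 smoothing_sigma = smoothing_sigma),
            class = "peth_matrix")
}

#' @export
print.peth_matrix <- function(x, ...) {
  cat(sprintf("<peth_matrix> %d trials x %d bins of %g ms [%g, %g] s%s\n",
              nrow(x$rates), ncol(x$rates), 1000 * x$bin_width,
              min(x$time_axis), max(x$time_axis),
              if (!is.null(x$smoothing_sigma))
                sprintf(", smoothed (sigma %g ms)", 1000 * x$smoothing_sigma)
              else ""))
  invisible(x)
}

#' Peri-event time histogram of a unit
#'
#' Spike counts per trial in fixed bins around each event (default 50 ms
#' bins), divided by the bin width to give rates. Counts are conserved: the
#' summed counts equal the number of spikes falling inside the windows.
#'
#' @param unit a [spike_unit()].
#' @param events an [event_stream()]; `label` selects the aligned event.
#' @param label event label(s) to align to, or `NULL` for all.
#' @param window `c(start, end)` (s relative to onset).
#' @param bin_width bin width (s), default 0.05.
#' @return A [peth_matrix()].
#' @export
peth <- function(unit, events, label = NULL, window = c(-2, 10),
                 bin_width = 0.05) {
  stopifnot(inherits(unit, "spike_unit"), inherits(events, "event_stream"))
  if (!is.null(label)) events <- events_with_label(events, label)
  if (!nrow(events)) stop("no events to align to")
  if (diff(window) < bin_width) stop("window must span at least one bin")
  breaks <- seq(window[1], window[2], by = bin_width)
  nb <- length(breaks) - 1L
  counts <- t(vapply(events$onset, function(on) {
    rel <- unit$spike_times - on
    rel <- rel[rel >= breaks[1] & rel < breaks[nb + 1L]]
    tabulate(findInterval(rel, breaks), nbins = nb)
  }, integer(nb)))
  peth_matrix(counts / bin_width, bin_width,
              time_axis = breaks[-length(breaks)] + bin_width / 2)
}

#' Gaussian smoothing of a PETH
#'
#' Per-trial convolution with a normalized Gaussian kernel (default sigma =
#' 50 ms) truncated at +/-4 sigma; edges are handled by reflection so rate
#' mass is preserved near the boundaries.
#'
#' @param p a [peth_matrix()].
#' @param sigma Gaussian sd (s), `> 0`.
#' @return A smoothed [peth_matrix()].
#' @export
gaussian_smooth <- function(p, sigma = 0.05) {
  stopifnot(inherits(p, "peth_matrix"), sigma > 0)
  sb <- sigma / p$bin_width
  half <- ceiling(4 * sb)
  k <- stats::dnorm(seq(-half, half), sd = sb)
  k <- k / sum(k)
  nb <- ncol(p$rates)
  if (half >= nb) stop("kernel wider than the histogram")
  pad <- cbind(p$rates[, half:1, drop = FALSE], p$rates,
               p$rates[, nb:(nb - half + 1L), drop = FALSE])
  sm <- matrix(0, nrow(p$rates), nb)
  for (j in seq_along(k))
    sm <- sm + k[j] * pad[, (j - 1L) + seq_len(nb), drop = FALSE]
  peth_matrix(sm, p$bin_width, p$time_axis, smoothing_sigma = sigma)
}

#' Standard-score response profile
#'
#' Z-standardizes the trial-averaged rate against the mean and sd of a
#' control period (default the 2 s before cue onset): by construction the
#' profile has mean ~0 and sd ~1 inside the control window. The sd is taken
#' across the bins of the trial-averaged profile within the control window.
#'
#' @param p a [peth_matrix()] (typically Gaussian-smoothed).
#' @param control_window `c(start, end)` (s), must cover `>= 2` bins.
#' @return A list of class `z_profile` with `z`, `time_axis`,
#'   `control_window`, and `flagged` (`TRUE` with `z = NA` when the control
#'   sd is zero).
#' @export
zscore_profile <- function(p, control_window = c(-2, 0)) {
  stopifnot(inherits(p, "peth_matrix"))
  idx <- window_index(p$time_axis, control_window)
  if (length(idx) < 2L) stop("control window must contain at least two bins")
  mu_prof <- colMeans(p$rates)
  m <- mean(mu_prof[idx])
  s <- stats::sd(mu_prof[idx])
  if (!is.finite(s) || s == 0) {
    warning("control-period sd is zero; z-profile undefined")
    return(structure(list(z = rep(NA_real_, length(mu_prof)),
                          time_axis = p$time_axis,
                          control_window = control_window, flagged = TRUE),
                     class = "z_profile"))
  }
  structure(list(z = (mu_prof - m) / s, time_axis = p$time_axis,
                 control_window = control_window, flagged = FALSE),
            class = "z_profile")
}
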