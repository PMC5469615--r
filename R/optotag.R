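# Optogenetic identification of units. Three criteria, applied together:
# the spontaneous/evoked mean waveforms must correlate (C > 0.85), evoked
# spiking within 10 ms of pulse onset is summarized by its latency
# distribution and reliability (R), and a bootstrap over surrogate pulse
# trains placed in the stimulation-free epoch gives the tagging p-value
# (tagged when p < 0.001).

#' Waveform correlation between spontaneous and evoked spikes
#'
#' Pearson correlation of the concatenated per-channel mean waveforms.
#'
#' @param wf_spont,wf_evoked equal-shaped numeric waveforms (matrix channels x
#'   samples, or vector).
#' @return The correlation coefficient; `NA` (with a warning) when either
#'   waveform is constant.
#' @export
waveform_correlation <- function(wf_spont, wf_evoked) {
  a <- as.vector(wf_spont); b <- as.vector(wf_evoked)
  if (length(a) != length(b)) stop("waveforms must have equal lengths")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant waveform: correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Evoked first-spike latencies and reliability
#'
#' For each light pulse, the first spike in `(onset, onset + window]`; the
#' reliability R is the fraction of pulses followed by such a spike, and the
#' latencies are returned for those pulses.
#'
#' @param unit a [spike_unit()] with `light_pulses`.
#' @param window evoked-spike acceptance window after pulse onset (s),
#'   default 0.010.
#' @return A list with `latencies` (s) and `r`.
#' @export
evoked_latency_reliability <- function(unit, window = 0.010) {
  stopifnot(inherits(unit, "spike_unit"))
  pulses <- unit$light_pulses$onsets
  if (is.null(pulses) || !length(pulses)) stop("unit has no light pulses")
  lat <- first_latencies(unit$spike_times, pulses, window)
  list(latencies = lat[!is.na(lat)], r = mean(!is.na(lat)))
}

# First-spike latency per pulse (NA when no spike within the window).
first_latencies <- function(spikes, pulses, window) {
  i <- findInterval(pulses, spikes) + 1L    # first spike strictly after onset
  lat <- rep(NA_real_, length(pulses))
  ok <- i <= length(spikes)
  lat[ok] <- spikes[i[ok]] - pulses[ok]
  lat[!is.na(lat) & lat > window] <- NA
  lat
}

#' Bootstrap tagging p-value
#'
#' Compares light-evoked spiking against surrogate pulse trains placed
#' uniformly in the stimulation-free epoch preceding the real train. Each
#' surrogate keeps the full inter-pulse structure (the whole train is
#' shifted), preserving within-train dependence. With the default
#' `statistic = "reliability"` the observed within-window reliability R is
#' ranked against the surrogate reliabilities; `statistic = "latency"` ranks
#' the observed median first-spike latency against surrogate medians instead.
#' `p = (1 + #{surrogate at least as extreme}) / (n_boot + 1)`.
#'
#' @param unit a [spike_unit()] with `light_pulses`; the stimulation-free
#'   epoch before the first pulse must span at least 10x the pulse-train
#'   length.
#' @param window evoked-spike window (s).
#' @param n_boot number of surrogate trains.
#' @param seed integer seed.
#' @param statistic `"reliability"` or `"latency"`.
#' @return The bootstrap p-value.
#' @export
tagging_pvalue <- function(unit, window = 0.010, n_boot = 1000, seed = 1,
                           statistic = c("reliability", "latency")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(unit, "spike_unit"))
  pulses <- unit$light_pulses$onsets
  if (is.null(pulses) || !length(pulses)) stop("unit has no light pulses")
  span <- max(pulses) - min(pulses)
  free_end <- min(pulses) - 0.5
  if (free_end < 10 * max(span, window))
    stop("stimulation-free epoch too short for surrogate placement (need >= 10x the pulse-train span)")
  obs <- evoked_latency_reliability(unit, window)
  rel_pulses <- pulses - min(pulses)
  set.seed(derive_seed(seed, 0L, salt = 71L))
  starts <- stats::runif(n_boot, 0, free_end - span)
  stat_surr <- vapply(starts, function(s) {
    lat <- first_latencies(unit$spike_times, s + rel_pulses, window)
    if (statistic == "reliability") mean(!is.na(lat))
    else if (all(is.na(lat))) Inf else stats::median(lat, na.rm = TRUE)
  }, 0)
  if (statistic == "reliability")
    (1 + sum(stat_surr >= obs$r - 1e-12)) / (n_boot + 1)
  else {
    obs_med <- if (length(obs$latencies)) stats::median(obs$latencies) else Inf
    (1 + sum(stat_surr <= obs_med + 1e-12)) / (n_boot + 1)
  }
}

#' Classify a unit as optogenetically tagged
#'
#' Applies the three tagging criteria: waveform correlation `C > 0.85`,
#' within-10-ms reliability/latency summary, and bootstrap `p < 0.001` (both
#' inequalities strict).
#'
#' @param unit a [spike_unit()] with `light_pulses` and both `waveform_mean`
#'   and `waveform_evoked`.
#' @param window evoked-spike window (s).
#' @param n_boot surrogate trains for [tagging_pvalue()].
#' @param seed integer seed.
#' @param statistic bootstrap statistic, see [tagging_pvalue()].
#' @return A list of class `tag_result`: `c`, `latencies`, `r`, `p`,
#'   `tagged`.
#' @export
classify_tagging <- function(unit, window = 0.010, n_boot = 1000, seed = 1,
                             statistic = "reliability") {
  if (is.null(unit$waveform_evoked))
    stop("unit has no evoked mean waveform")
  cc <- waveform_correlation(unit$waveform_mean, unit$waveform_evoked)
  lr <- evoked_latency_reliability(unit, window)
  p <- tagging_pvalue(unit, window, n_boot, seed, statistic)
  structure(list(c = cc, latencies = lr$latencies, r = lr$r, p = p,
                 tagged = isTRUE(cc > 0.85) && p < 0.001),
            class = "tag_result")
}

#' @export
print.tag_result <- function(x, ...) {
  cat(sprintf("<tag_result> C = %.3f, R = %.3f, median latency = %s ms, p = %.4g -> %s\n",
              x$c, x$r,
              if (length(x$latencies))
                sprintf("%.2f", 1000 * stats::median(x$latencies)) else "NA",
              x$p, if (x$tagged) "tagged" else "not tagged"))
  invisible(x)
}
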