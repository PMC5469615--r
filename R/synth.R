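# Synthetic-session generators. These define the test bed for the whole
# pipeline: GCaMP-like transients with the measured amplitude/time-to-peak/
# decay statistics, conditioned spiking profiles, light-evoked spikes for
# tagging, and random-walk locomotion. All generators are deterministic for a
# fixed seed, with per-unit seeds derived from the master seed by index.

#' Unit-peak calcium transient kernel
#'
#' Difference-of-exponentials kernel
#' `k(t) = c * (exp(-t/tau_decay) - exp(-t/tau_rise))` for `t >= 0`, with the
#' rise constant solved numerically so the peak falls at `t_peak`, and `c`
#' normalizing the peak to 1. This is the minimal smooth kernel matching the
#' two quantities reported for the recorded transients (time to peak and
#' mono-exponential decay constant).
#'
#' @param t times from event onset (s); values `< 0` map to 0.
#' @param t_peak time to peak (s), `> 0`.
#' @param tau_decay decay time constant (s), `> t_peak / 5` in practice.
#' @return Kernel values, peak normalized to 1.
#' @examples
#' k <- transient_kernel(seq(0, 10, 0.002), t_peak = 0.68, tau_decay = 5.88)
#' max(k)  # 1
#' @export
transient_kernel <- function(t, t_peak, tau_decay) {
  p <- solve_kernel(t_peak, tau_decay)
  k <- numeric(length(t))
  pos <- t >= 0
  k[pos] <- p$c * (exp(-t[pos] / tau_decay) - exp(-t[pos] / p$tau_rise))
  k
}

# tau_rise such that the kernel peaks at t_peak given tau_decay:
# t_peak(tau_r) = log(tau_d/tau_r) * tau_d*tau_r / (tau_d - tau_r),
# monotone increasing in tau_r on (0, tau_d).
solve_kernel <- function(t_peak, tau_decay) {
  stopifnot(t_peak > 0, tau_decay > t_peak / 50)
  f <- function(tr) log(tau_decay / tr) * tau_decay * tr / (tau_decay - tr) - t_peak
  tr <- stats::uniroot(f, c(tau_decay * 1e-8, tau_decay * (1 - 1e-8)),
                       tol = 1e-12)$root
  peak <- exp(-t_peak / tau_decay) - exp(-t_peak / tr)
  list(tau_rise = tr, c = 1 / peak)
}

# Lognormal draw with mean m (magnitude) and coefficient of variation cv;
# the sign of m is preserved so inhibitory (negative) components stay negative.
rlnorm_cv <- function(n, m, cv) {
  if (cv == 0 || m == 0) return(rep(m, n))
  s2 <- log(1 + cv^2)
  sign(m) * stats::rlnorm(n, meanlog = log(abs(m)) - s2 / 2, sdlog = sqrt(s2))
}

# Trial onsets for a layout: uniform ITIs, first trial after a pre-roll long
# enough for any baseline window.
layout_onsets <- function(layout, n_trials, pre_roll = 30) {
  gaps <- stats::runif(n_trials, layout$iti_range[1], layout$iti_range[2])
  pre_roll + cumsum(gaps) - gaps[1] + 0

}

#' Photometry recording-site preset for reward conditioning
#'
#' Kernel stack of a conditioned sucrose site: cue-locked inhibition sustained
#' through cue and delay, deeper inhibition at sucrose infusion, and -- for
#' `"type2"` sites only -- an excitatory rebound transient after infusion
#' offset. Amplitudes are generator choices on the dF/F scale (the site-level
#' magnitudes are not reported as group numbers); the rebound (+0.20) is set
#' well above the profile noise so the two site classes are separable the way
#' the recorded ensemble was.
#'
#' @param profile_type `"type1"` (pure inhibition) or `"type2"`
#'   (inhibition-then-excitation).
#' @inheritParams transient_preset
#' @return A list of class `photometry_site_preset`.
#' @export
photometry_site_preset <- function(profile_type = c("type1", "type2"),
                                   amplitude_cv = 0.3, amp_noise_sd = 0.05,
                                   noise_sd = 0.01, drift_tau = 2000) {
  profile_type <- match.arg(profile_type)
  comps <- list(
    cue = list(offset = 0, amplitude = -0.10, t_peak = 1.0, tau_decay = 3.0),
    us  = list(offset = 4.0, amplitude = -0.15, t_peak = 0.6, tau_decay = 2.0))
  if (profile_type == "type2")
    comps$rebound <- list(offset = 4.5, amplitude = 0.20, t_peak = 0.8,
                          tau_decay = 2.0)
  structure(list(name = paste0("sucrose_", profile_type),
                 profile_type = profile_type, components = comps,
                 amplitude_cv = amplitude_cv, amp_noise_sd = amp_noise_sd,
                 noise_sd = noise_sd, drift_tau = drift_tau,
                 baseline_window = c(-2, -0.5), align_window = c(-2, 10)),
            class = "photometry_site_preset")
}

#' Simulate a fiber-photometry session
#'
#' Builds a 500 Hz fluorescence trace as a photobleaching baseline
#' `B(t) = exp(-t/drift_tau)` carrying multiplicative event-locked transients,
#' `F(t) = B(t) * (1 + sum_i A_i k(t - t_i)) + noise`, so the fractional
#' fluorescence change recovered downstream equals the preset amplitude
#' regardless of drift. Per-trial amplitudes are lognormal with the preset CV;
#' the cue-locked component (conditioning layouts) is scaled by the learning
#' schedule's per-trial gain.
#'
#' @param preset a [transient_preset()] (single aligned stimulus per trial) or
#'   [photometry_site_preset()] (cue-delay-reward trials).
#' @param n_trials number of trials (`>= 1`).
#' @param schedule optional [learning_schedule()] applied to the cue-locked
#'   component.
#' @param layout optional [trial_layout()]; defaults to the preset's natural
#'   layout.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param rate sampling rate (Hz).
#' @return A [session()] holding the `recording` and its `event_stream`.
#' @examples
#' s <- gen_photometry_session(transient_preset("footshock"), n_trials = 3,
#'                             seed = 1)
#' s$events
#' @export
gen_photometry_session <- function(preset, n_trials, schedule = NULL,
                                   layout = NULL, seed = 1, rate = 500) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  set.seed(derive_seed(seed, 0L, salt = 11L))
  if (is.null(layout)) layout <- default_layout(preset)
  onsets <- layout_onsets(layout, n_trials,
                          pre_roll = max(30, -min(preset_align(preset)[1]) + 10))
  gen_photometry_impl(preset, onsets, schedule, layout,
                      derive_seed(seed, 1L, salt = 12L), rate)
}

default_layout <- function(preset) {
  if (inherits(preset, "transient_preset"))
    trial_layout("simple", iti_range = preset$iti_range,
                 us_label = preset$event_label,
                 us_duration = preset$event_duration)
  else trial_layout("conditioning", iti_range = c(20, 40),
                    us_label = "sucrose")
}

preset_align <- function(preset) preset$align_window %||% c(-2, 10)

# Kernel components per trial for a preset under a layout. Each component:
# offset from trial onset, mean amplitude, kernel shape.
preset_components <- function(preset, layout) {
  if (inherits(preset, "photometry_site_preset")) return(preset$components)
  if (layout$kind == "simple")
    return(list(us = list(offset = 0, amplitude = preset$amplitude,
                          t_peak = preset$t_peak,
                          tau_decay = preset$tau_decay)))
  # transient preset in a conditioning layout: conditioned cue response takes
  # the US kernel shape at half amplitude, gated by the learning schedule
  list(cue = list(offset = 0, amplitude = 0.5 * preset$amplitude,
                  t_peak = preset$t_peak, tau_decay = preset$tau_decay),
       us = list(offset = layout$cue_duration + layout$delay,
                 amplitude = preset$amplitude, t_peak = preset$t_peak,
                 tau_decay = preset$tau_decay))
}

gen_photometry_impl <- function(preset, onsets, schedule, layout, seed, rate) {
  set.seed(seed)
  n_trials <- length(onsets)
  comps <- preset_components(preset, layout)
  t_total <- max(onsets) + preset_align(preset)[2] + 20
  n <- ceiling(t_total * rate)
  times <- (seq_len(n) - 1) / rate
  signal <- numeric(n)
  us_on <- if (layout$kind == "simple") 0 else layout$cue_duration + layout$delay
  us_delivered <- if (layout$us_probability < 1)
    stats::runif(n_trials) < layout$us_probability else rep(TRUE, n_trials)
  for (nm in names(comps)) {
    co <- comps[[nm]]
    sk <- solve_kernel(co$t_peak, co$tau_decay)
    support <- co$t_peak + 8 * co$tau_decay
    amps <- rlnorm_cv(n_trials, co$amplitude, preset$amplitude_cv)
    if (nm == "cue" && !is.null(schedule))
      amps <- amps * schedule$gain(seq_len(n_trials))
    # kernel-shaped across-trial variability (spontaneous transients): does
    # not scale with the learned gain, so it sets the detection floor
    amps <- amps + stats::rnorm(n_trials, sd = preset$amp_noise_sd)
    if (nm != "cue") amps[!us_delivered] <- 0
    for (i in seq_len(n_trials)) {
      if (amps[i] == 0) next
      t0 <- onsets[i] + co$offset
      i0 <- max(1L, ceiling(t0 * rate) + 1L)
      i1 <- min(n, floor((t0 + support) * rate) + 1L)
      if (i1 < i0) next
      rel <- times[i0:i1] - t0
      signal[i0:i1] <- signal[i0:i1] +
        amps[i] * sk$c * (exp(-rel / co$tau_decay) - exp(-rel / sk$tau_rise))
    }
  }
  trace <- exp(-times / preset$drift_tau) * (1 + signal) +
    stats::rnorm(n, sd = preset$noise_sd)
  ev <- build_events(onsets, layout, us_delivered)
  session(recording(trace, rate = rate, t0 = 0, channel_label = "gcamp"),
          events = ev)
}

build_events <- function(onsets, layout, us_delivered = TRUE) {
  n <- length(onsets)
  us_delivered <- rep_len(us_delivered, n)
  if (layout$kind == "simple")
    return(event_stream(onsets, layout$us_label, layout$us_duration))
  us_on <- onsets[us_delivered] + layout$cue_duration + layout$delay
  df <- rbind(
    data.frame(onset = onsets, label = layout$cue_label,
               duration = layout$cue_duration),
    if (length(us_on))
      data.frame(onset = us_on, label = layout$us_label,
                 duration = layout$us_duration))
  df <- df[order(df$onset), ]
  event_stream(df$onset, df$label, df$duration)
}

#' Rate function of a conditioned spiking profile
#'
#' The deterministic intensity (spikes/s) underlying [gen_spike_unit()]:
#' baseline firing between trials, a step to the cue rate through cue and
#' delay, a step to the reward rate during infusion, then exponential return
#' to baseline starting from the reward rate (type1) or from the rebound rate
#' above baseline (type2). Useful as a noiseless oracle for the peri-event
#' histogram stages.
#'
#' @param preset a [spike_profile_preset()].
#' @param cue_onsets trial (cue) onset times (s).
#' @param layout a [trial_layout()] (conditioning timings are used).
#' @return A vectorized function `f(t)` giving the rate at time `t`.
#' @export
spike_rate_function <- function(preset, cue_onsets,
                                layout = trial_layout("conditioning")) {
  cue_len <- layout$cue_duration + layout$delay
  us_off <- cue_len + layout$us_duration
  r0 <- if (preset$profile_type == "type2") preset$rebound_rate else preset$us_rate
  function(t) {
    i <- findInterval(t, cue_onsets)
    rel <- t - c(-Inf, cue_onsets)[i + 1L]
    rate <- rep(preset$baseline_rate, length(t))
    rate[rel >= 0 & rel < cue_len] <- preset$cue_rate
    rate[rel >= cue_len & rel < us_off] <- preset$us_rate
    post <- which(rel >= us_off & is.finite(rel))
    rate[post] <- preset$baseline_rate +
      (r0 - preset$baseline_rate) * exp(-(rel[post] - us_off) / preset$rebound_tau)
    rate
  }
}

#' Simulate a conditioned single unit
#'
#' Inhomogeneous Poisson spike train whose intensity follows
#' [spike_rate_function()] over a seeded trial schedule, generated by thinning
#' a homogeneous train at the peak rate.
#'
#' @param preset a [spike_profile_preset()].
#' @param layout a [trial_layout()].
#' @param n_trials number of trials.
#' @param seed integer seed.
#' @param unit_id unit identifier.
#' @return A [session()] with one `spike_unit` and the trial `event_stream`.
#' @export
gen_spike_unit <- function(preset, layout = trial_layout("conditioning",
                                                         us_label = "sucrose"),
                           n_trials = 100, seed = 1, unit_id = "u1") {
  set.seed(derive_seed(seed, 0L, salt = 21L))
  onsets <- layout_onsets(layout, n_trials, pre_roll = 15)
  u <- gen_spike_unit_impl(preset, onsets, layout,
                           derive_seed(seed, 1L, salt = 22L), unit_id)
  session(events = build_events(onsets, layout), units = list(u))
}

gen_spike_unit_impl <- function(preset, onsets, layout, seed, unit_id) {
  set.seed(seed)
  t_total <- max(onsets) + 15
  rate_fun <- spike_rate_function(preset, onsets, layout)
  max_rate <- max(preset$baseline_rate, preset$cue_rate, preset$us_rate,
                  preset$rebound_rate)
  spikes <- numeric()
  if (max_rate > 0) {
    n <- stats::rpois(1, max_rate * t_total)
    cand <- sort(stats::runif(n, 0, t_total))
    keep <- stats::runif(n) < rate_fun(cand) / max_rate
    spikes <- unique(cand[keep])
  }
  spike_unit(spikes, waveform_mean = waveform_template(),
             unit_id = unit_id, duration = t_total)
}

# Canonical tetrode mean waveform: biphasic spike, 32 samples, 4 channels
# with decaying amplitude across channels.
waveform_template <- function() {
  i <- seq_len(32)
  shape <- -80 * exp(-((i - 10) / 2)^2) + 35 * exp(-((i - 17) / 5)^2)
  outer(c(1, 0.7, 0.45, 0.2), shape)
}

#' Simulate an optogenetic tagging epoch
#'
#' Spontaneous Poisson firing over a long stimulation-free epoch followed by a
#' pulse train (default 5 ms pulses at 10 Hz); each pulse evokes, with the
#' preset reliability, one spike at the pulse onset plus a jittered latency.
#' The evoked mean waveform equals the spontaneous one up to a small
#' perturbation, as for a directly activated opsin-expressing unit.
#'
#' @param preset a [tagging_preset()].
#' @param seed integer seed.
#' @param unit_id unit identifier.
#' @return A [spike_unit()] with `light_pulses` and `waveform_evoked` set.
#' @export
gen_tagging_epoch <- function(preset, seed = 1, unit_id = "tag1") {
  set.seed(derive_seed(seed, 0L, salt = 31L))
  span <- preset$n_pulses / preset$pulse_rate
  t_free <- 10.5 * span + 30     # stimulation-free epoch before the train
  t_total <- t_free + span + 5
  pulses <- t_free + (seq_len(preset$n_pulses) - 1) / preset$pulse_rate
  spont <- sort(stats::runif(stats::rpois(1, preset$spont_rate * t_total),
                             0, t_total))
  evoked_mask <- stats::runif(preset$n_pulses) < preset$reliability
  lat <- pmax(2e-4, preset$latency_mean +
                stats::rnorm(preset$n_pulses, sd = preset$latency_jitter))
  evoked <- pulses[evoked_mask] + lat[evoked_mask]
  spikes <- sort(unique(c(spont, evoked)))
  wf <- waveform_template()
  wf_ev <- wf + stats::rnorm(length(wf), sd = 0.02 * max(abs(wf)))
  spike_unit(spikes, waveform_mean = wf, unit_id = unit_id,
             light_pulses = list(onsets = pulses, width = preset$pulse_width),
             waveform_evoked = wf_ev, duration = t_total)
}

#' Simulate a population of units or photometry sites
#'
#' All members share one trial schedule drawn from the master seed; each
#' member's data use a seed derived from the master seed and the member index,
#' so reordering members never changes any member's data.
#'
#' @param spec a [mixture_spec()].
#' @return A list with `events` (shared schedule), `labels` (true profile type
#'   per member) and either `units` (spike mixtures) or `sessions` (photometry
#'   mixtures).
#' @examples
#' pop <- gen_population(mixture_spec(c(type1 = 2, type2 = 1), n_trials = 5))
#' pop$labels
#' @export
gen_population <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  set.seed(derive_seed(spec$seed, 0L, salt = 41L))
  onsets <- layout_onsets(spec$layout, spec$n_trials,
                          pre_roll = if (spec$kind == "photometry") 30 else 15)
  labels <- rep(names(spec$counts), spec$counts)
  ev <- build_events(onsets, spec$layout)
  if (spec$kind == "spikes") {
    units <- lapply(seq_along(labels), function(i)
      gen_spike_unit_impl(spike_profile_preset(labels[i]), onsets, spec$layout,
                          derive_seed(spec$seed, i, salt = 42L),
                          sprintf("u%02d", i)))
    names(units) <- vapply(units, `[[`, "", "unit_id")
    list(units = units, events = ev, labels = labels)
  } else {
    sessions <- lapply(seq_along(labels), function(i)
      gen_photometry_impl(photometry_site_preset(labels[i]), onsets,
                          schedule = NULL, layout = spec$layout,
                          seed = derive_seed(spec$seed, i, salt = 43L),
                          rate = 500))
    list(sessions = sessions, events = ev, labels = labels)
  }
}

#' Simulate a locomotion trace with cue-locked suppression
#'
#' Planar random walk sampled at the video frame rate; the step size within
#' the 0-4 s window after each cue onset is scaled by a per-trial suppression
#' gain, emulating the conditioned suppression of locomotor speed that
#' develops over aversive conditioning.
#'
#' @param layout a [trial_layout()].
#' @param n_trials number of trials.
#' @param suppression_gain numeric vector (recycled to `n_trials`) of gains in
#'   `[0, 1]` applied to the post-cue step size; 1 = no suppression.
#' @param seed integer seed.
#' @param frame_rate video sampling rate (Hz).
#' @param step_sd baseline per-frame step sd (cm).
#' @return A [session()] with `position` and the trial `event_stream`.
#' @export
gen_locomotion <- function(layout = trial_layout("conditioning"),
                           n_trials = 30, suppression_gain = 1, seed = 1,
                           frame_rate = 25, step_sd = 0.5) {
  set.seed(derive_seed(seed, 0L, salt = 51L))
  onsets <- layout_onsets(layout, n_trials, pre_roll = 15)
  gains <- rep_len(suppression_gain, n_trials)
  t_total <- max(onsets) + 15
  times <- seq(0, t_total, by = 1 / frame_rate)
  i <- findInterval(times, onsets)
  rel <- times - c(-Inf, onsets)[i + 1L]
  g <- rep(1, length(times))
  in_win <- rel >= 0 & rel < 4
  g[in_win] <- gains[pmax(i[in_win], 1L)]
  steps <- matrix(stats::rnorm(2 * length(times), sd = step_sd),
                  ncol = 2) * g
  xy <- apply(steps, 2, cumsum)
  session(events = build_events(onsets, layout),
          position = position_trace(times, xy))
}

#' Signal-free event-related matrix
#'
#' Gaussian-noise trial matrix with no event-locked structure, used for null
#' calibration of the permutation and ROC stages.
#'
#' @param n_trials trials (rows).
#' @param window time window (s relative to a notional onset).
#' @param rate sampling rate (Hz).
#' @param noise_sd Gaussian sd (dF/F units).
#' @param seed integer seed.
#' @return An [erf_matrix()].
#' @export
gen_null_erf <- function(n_trials = 10, window = c(-2, 10), rate = 500,
                         noise_sd = 0.01, seed = 1) {
  set.seed(derive_seed(seed, 0L, salt = 61L))
  time_axis <- seq(window[1], window[2] - 1 / rate, by = 1 / rate)
  erf_matrix(matrix(stats::rnorm(n_trials * length(time_axis), sd = noise_sd),
                    nrow = n_trials),
             time_axis = time_axis, event_label = "null")
}
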