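#' Calcium-transient preset
#'
#' Parameters of the event-locked GCaMP transient used by
#' [gen_photometry_session()]. The named presets carry the group statistics of
#' the three aversive stimuli: quinine infusion (peak 27.8% dF/F, time to peak
#' 0.68 s, decay constant 5.88 s), footshock (48.8%, 0.26 s, 1.89 s) and
#' social attack (32.9%, 0.57 s, 7.80 s). Across-trial amplitude variability
#' (multiplicative lognormal with CV 0.3 plus an additive spontaneous-
#' transient component of 0.05 dF/F), the sample noise floor (0.01 dF/F) and
#' the slow photobleaching drift (time constant 2000 s) are generator
#' choices, exposed here because no measured values exist for them.
#'
#' @param name one of `"quinine"`, `"footshock"`, `"social"`, or `"custom"`.
#' @param amplitude peak dF/F of the mean transient (fraction, e.g. 0.278).
#' @param t_peak time from event onset to peak (s).
#' @param tau_decay mono-exponential decay time constant (s).
#' @param amplitude_cv across-trial coefficient of variation of the amplitude.
#' @param amp_noise_sd additive across-trial amplitude noise (dF/F units):
#'   kernel-shaped trial-to-trial variability present independent of the
#'   stimulus response, emulating spontaneous calcium transients; this is
#'   what limits blockwise detectability of small conditioned responses.
#' @param noise_sd additive Gaussian sample noise (dF/F units).
#' @param drift_tau photobleaching time constant (s).
#' @param iti_range inter-trial interval range (s), uniform.
#' @param event_label label recorded for the aligned event.
#' @param event_duration stimulus duration (s).
#' @param baseline_window default baseline window for dF/F (s rel. onset).
#' @param align_window default alignment window (s rel. onset).
#' @return A list of class `transient_preset`.
#' @examples
#' transient_preset("quinine")$amplitude  # 0.278
#' @export
transient_preset <- function(name = c("quinine", "footshock", "social",
                                      "custom"),
                             amplitude = NULL, t_peak = NULL, tau_decay = NULL,
                             amplitude_cv = 0.3, amp_noise_sd = 0.05,
                             noise_sd = 0.01,
                             drift_tau = 2000, iti_range = NULL,
                             event_label = NULL, event_duration = NULL,
                             baseline_window = c(-2, -0.5),
                             align_window = c(-2, 10)) {
  name <- match.arg(name)
  def <- switch(name,
    quinine   = list(amplitude = 0.278, t_peak = 0.68, tau_decay = 5.88,
                     iti_range = c(110, 130), event_label = "quinine",
                     event_duration = 0.5),
    footshock = list(amplitude = 0.488, t_peak = 0.26, tau_decay = 1.89,
                     iti_range = c(20, 40), event_label = "footshock",
                     event_duration = 0.5),
    social    = list(amplitude = 0.329, t_peak = 0.57, tau_decay = 7.80,
                     iti_range = c(30, 60), event_label = "attack_onset",
                     event_duration = 3,
                     baseline_window = c(-5, -3.5), align_window = c(-5, 10)),
    custom    = list(iti_range = c(20, 40), event_label = "us",
                     event_duration = 0.5))
  p <- list(name = name,
            amplitude = amplitude %||% def$amplitude,
            t_peak = t_peak %||% def$t_peak,
            tau_decay = tau_decay %||% def$tau_decay,
            amplitude_cv = amplitude_cv, amp_noise_sd = amp_noise_sd,
            noise_sd = noise_sd, drift_tau = drift_tau,
            iti_range = iti_range %||% def$iti_range,
            event_label = event_label %||% def$event_label,
            event_duration = event_duration %||% def$event_duration,
            baseline_window = def$baseline_window %||% baseline_window,
            align_window = def$align_window %||% align_window)
  if (!missing(baseline_window)) p$baseline_window <- baseline_window
  if (!missing(align_window)) p$align_window <- align_window
  stopifnot(is.numeric(p$amplitude), p$t_peak >= 0, p$tau_decay > 0,
            p$amplitude_cv >= 0, p$amp_noise_sd >= 0, p$noise_sd >= 0,
            p$drift_tau > 0)
  structure(p, class = "transient_preset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Single-unit firing-rate preset
#'
#' Piecewise rate profile of a conditioned habenular unit in the cue-delay-
#' reward trial: tonic baseline of about 30 spikes/s, inhibition to ~25
#' spikes/s through cue and delay, deeper inhibition to ~20 spikes/s during
#' reward delivery, then either monotone recovery to baseline (`"type1"`,
#' pure inhibition) or an exponential post-inhibitory rebound above baseline
#' (`"type2"`, inhibition-then-excitation).
#'
#' @param profile_type `"type1"` or `"type2"`.
#' @param baseline_rate,cue_rate,us_rate rates (spikes/s) in the respective
#'   trial epochs.
#' @param rebound_rate peak rate (spikes/s) of the type2 rebound immediately
#'   after reward offset; must be `<= baseline_rate` for type1.
#' @param rebound_tau decay constant of the post-reward transient (s).
#' @return A list of class `spike_profile_preset`.
#' @export
spike_profile_preset <- function(profile_type = c("type1", "type2"),
                                 baseline_rate = 30, cue_rate = 25,
                                 us_rate = 20,
                                 rebound_rate = if (profile_type[1] == "type2") 40 else baseline_rate,
                                 rebound_tau = 1.5) {
  profile_type <- match.arg(profile_type)
  if (any(c(baseline_rate, cue_rate, us_rate, rebound_rate) < 0))
    stop("all rates must be >= 0")
  if (profile_type == "type1" && rebound_rate > baseline_rate)
    stop("type1 profiles must not rebound above baseline")
  structure(list(profile_type = profile_type, baseline_rate = baseline_rate,
                 cue_rate = cue_rate, us_rate = us_rate,
                 rebound_rate = rebound_rate, rebound_tau = rebound_tau),
            class = "spike_profile_preset")
}

#' Trial layout
#'
#' Timing skeleton of a trial. `"simple"` is a single stimulus per trial
#' (random quinine/footshock/attack alignment); `"conditioning"` is the
#' Pavlovian structure: a 2 s cue, a 2 s delay, then a 0.5 s unconditioned
#' stimulus, with uniform random inter-trial intervals.
#'
#' @param kind `"simple"` or `"conditioning"`.
#' @param iti_range uniform inter-trial-interval range (s), onset to onset gap.
#' @param cue_duration,delay,us_duration trial epoch durations (s).
#' @param cue_label,us_label event labels.
#' @param us_probability probability the US is delivered on a trial (1 for
#'   deterministic conditioning; 0.75/0.25 for the reward-probability task).
#' @return A list of class `trial_layout`.
#' @export
trial_layout <- function(kind = c("simple", "conditioning"),
                         iti_range = c(20, 40), cue_duration = 2, delay = 2,
                         us_duration = 0.5, cue_label = "cue",
                         us_label = "us", us_probability = 1) {
  kind <- match.arg(kind)
  stopifnot(length(iti_range) == 2L, iti_range[1] > 0,
            iti_range[2] >= iti_range[1],
            us_probability >= 0, us_probability <= 1)
  structure(list(kind = kind, iti_range = iti_range,
                 cue_duration = cue_duration, delay = delay,
                 us_duration = us_duration, cue_label = cue_label,
                 us_label = us_label, us_probability = us_probability),
            class = "trial_layout")
}

#' Learning schedule for cue-locked responses
#'
#' Per-trial multiplier on the cue-locked response component, a logistic curve
#' in trial number: near 0 on trial 1, 0.5 at the half-point trial `h`, and
#' saturating at 1. Aversive cue conditioning becomes detectable within 5-10
#' trials (default `h = 7`); appetitive conditioning only after about 120-150
#' trials (default `h = 135`).
#'
#' @param h half-point trial.
#' @param steepness logistic scale in trials; default `h/10`, a fairly
#'   abrupt acquisition curve whose blockwise detection onset falls near `h`.
#' @param direction `"excitatory"` (aversive cues) or `"inhibitory"`
#'   (reward-predicting cues).
#' @return A list of class `learning_schedule` with a `gain(trial)` function.
#' @examples
#' s <- learning_schedule(h = 7)
#' round(s$gain(c(1, 7, 20)), 3)
#' @export
learning_schedule <- function(h, steepness = h / 10,
                              direction = c("excitatory", "inhibitory")) {
  direction <- match.arg(direction)
  assert_scalar_pos(h, "h"); assert_scalar_pos(steepness, "steepness")
  g0 <- stats::plogis((1 - h) / steepness)  # subtract so gain(1) == 0 exactly
  structure(list(h = h, steepness = steepness, direction = direction,
                 gain = function(trial)
                   pmax(0, (stats::plogis((trial - h) / steepness) - g0) / (1 - g0))),
            class = "learning_schedule")
}

#' Optogenetic tagging preset
#'
#' Parameters for a photostimulation epoch: 5 ms light pulses at 10 Hz, each
#' evoking a short-latency spike with the stated reliability, on top of
#' spontaneous tonic firing.
#'
#' @param latency_mean mean evoked-spike latency from pulse onset (s).
#' @param latency_jitter Gaussian latency jitter sd (s).
#' @param reliability probability a pulse evokes a spike.
#' @param spont_rate spontaneous firing rate (spikes/s).
#' @param n_pulses number of light pulses.
#' @param pulse_rate pulse train frequency (Hz).
#' @param pulse_width pulse duration (s).
#' @return A list of class `tagging_preset`.
#' @export
tagging_preset <- function(latency_mean = 0.003, latency_jitter = 0.001,
                           reliability = 0.9, spont_rate = 30,
                           n_pulses = 600, pulse_rate = 10,
                           pulse_width = 0.005) {
  if (reliability < 0 || reliability > 1)
    stop("reliability must lie in [0, 1]")
  if (latency_mean < 0) stop("latency_mean must be >= 0")
  stopifnot(n_pulses >= 1, pulse_rate > 0, pulse_width > 0, spont_rate >= 0)
  structure(list(latency_mean = latency_mean, latency_jitter = latency_jitter,
                 reliability = reliability, spont_rate = spont_rate,
                 n_pulses = n_pulses, pulse_rate = pulse_rate,
                 pulse_width = pulse_width),
            class = "tagging_preset")
}

#' Mixture specification for a population of units or recording sites
#'
#' Composition of a synthetic ensemble sharing one trial schedule. The
#' defaults mirror the recorded single-unit dataset: 37 of 70 units with pure
#' inhibitory (type1) responses and 33 of 70 with inhibition-then-excitation
#' (type2); the photometry-site analogue is 9 + 9 of 18 recordings.
#'
#' @param counts named counts, e.g. `c(type1 = 37, type2 = 33)`.
#' @param kind `"spikes"` (units) or `"photometry"` (site recordings).
#' @param n_trials trials in the shared schedule.
#' @param layout a [trial_layout()]; defaults to sucrose conditioning.
#' @param seed master seed; per-unit seeds are derived from it keyed by unit
#'   index, so unit data do not depend on generation order.
#' @return A list of class `mixture_spec`.
#' @export
mixture_spec <- function(counts = c(type1 = 37, type2 = 33),
                         kind = c("spikes", "photometry"), n_trials = 100,
                         layout = trial_layout("conditioning",
                                               iti_range = c(20, 40)),
                         seed = 1) {
  kind <- match.arg(kind)
  stopifnot(all(counts >= 0), sum(counts) >= 2, !is.null(names(counts)))
  structure(list(counts = counts, kind = kind, n_trials = n_trials,
                 layout = layout, seed = seed), class = "mixture_spec")
}
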