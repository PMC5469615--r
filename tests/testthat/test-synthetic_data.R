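noiseless <- function(name) transient_preset(name, amplitude_cv = 0,
                                             amp_noise_sd = 0, noise_sd = 0)

test_that("every generator is byte-identical under a fixed seed", {
  p <- transient_preset("footshock")
  expect_identical(gen_photometry_session(p, 2, seed = 5),
                   gen_photometry_session(p, 2, seed = 5))
  sp <- spike_profile_preset("type2")
  expect_identical(gen_spike_unit(sp, n_trials = 5, seed = 5),
                   gen_spike_unit(sp, n_trials = 5, seed = 5))
  tp <- tagging_preset(n_pulses = 50)
  expect_identical(gen_tagging_epoch(tp, seed = 5),
                   gen_tagging_epoch(tp, seed = 5))
  expect_identical(gen_locomotion(n_trials = 3, seed = 5),
                   gen_locomotion(n_trials = 3, seed = 5))
  expect_identical(gen_null_erf(n_trials = 3, rate = 50, seed = 5),
                   gen_null_erf(n_trials = 3, rate = 50, seed = 5))
  spec <- mixture_spec(c(type1 = 1, type2 = 1), n_trials = 3, seed = 5)
  expect_identical(gen_population(spec), gen_population(spec))
})

test_that("the trace is pure drift when all signal and noise are off", {
  p <- transient_preset("quinine", amplitude = 0, amplitude_cv = 0,
                        amp_noise_sd = 0, noise_sd = 0)
  ses <- gen_photometry_session(p, n_trials = 2, seed = 1)
  tm <- recording_times(ses$recording)
  expect_equal(ses$recording$trace, exp(-tm / p$drift_tau), tolerance = 1e-12)
})

test_that("noiseless kernel parameters are recovered by the response metrics", {
  k <- transient_kernel(seq(0, 10, 1e-3), t_peak = 0.68, tau_decay = 5.88)
  expect_equal(max(k), 1, tolerance = 1e-6)
  expect_equal(seq(0, 10, 1e-3)[which.max(k)], 0.68, tolerance = 1e-3)

  p <- noiseless("quinine")
  p$drift_tau <- 1e9      # isolate the kernel from photobleaching
  ses <- gen_photometry_session(p, n_trials = 1, seed = 1)
  m <- compute_dff(ses$recording, ses$events, label = "quinine")
  met <- response_metrics(m, c(0, 10))
  expect_equal(met$peak_dff, 0.278, tolerance = 0.01)
  expect_lt(abs(met$t_peak - 0.68), 0.005)         # within ~2 samples
  expect_equal(met$tau_decay, 5.88, tolerance = 0.01)
})

test_that("spike trains realize their piecewise rate functions", {
  zero <- spike_profile_preset("type1", baseline_rate = 0, cue_rate = 0,
                               us_rate = 0, rebound_rate = 0)
  expect_length(gen_spike_unit(zero, n_trials = 3, seed = 1)$units[[1]]$spike_times, 0)

  # homogeneous 30 Hz: count within 3 sd of the Poisson expectation
  flat <- spike_profile_preset("type1", baseline_rate = 30, cue_rate = 30,
                               us_rate = 30, rebound_rate = 30)
  ses <- gen_spike_unit(flat, n_trials = 4, seed = 2)
  u <- ses$units[[1]]
  expected <- 30 * u$duration
  expect_lt(abs(length(u$spike_times) - expected), 3 * sqrt(expected))

  # long-run empirical rate converges to the preset (law of large numbers)
  ses2 <- gen_spike_unit(flat, n_trials = 100, seed = 3)
  u2 <- ses2$units[[1]]
  expect_gt(30 * u2$duration, 1e4)
  expect_equal(length(u2$spike_times) / u2$duration, 30, tolerance = 0.01)

  # rate-function oracle: type1 never exceeds baseline, type2 rebounds
  on <- c(100, 200)
  r1 <- spike_rate_function(spike_profile_preset("type1"), on)
  r2 <- spike_rate_function(spike_profile_preset("type2"), on)
  tt <- seq(99, 130, 0.01)
  expect_true(all(r1(tt) <= 30 + 1e-9))
  expect_gt(max(r2(tt)), 35)
  expect_equal(r2(99), 30)          # pre-trial baseline
  expect_equal(r1(101), 25)         # cue epoch
  expect_equal(r1(104.2), 20)       # reward epoch
})

test_that("tagging epochs lock evoked spikes to the pulse train", {
  lock <- tagging_preset(latency_mean = 0.003, latency_jitter = 0,
                         reliability = 1, spont_rate = 0, n_pulses = 100)
  u <- gen_tagging_epoch(lock, seed = 1)
  lr <- evoked_latency_reliability(u)
  expect_equal(lr$r, 1)
  expect_equal(lr$latencies, rep(0.003, 100), tolerance = 1e-9)

  none <- tagging_preset(reliability = 0, spont_rate = 0, n_pulses = 50)
  expect_length(gen_tagging_epoch(none, seed = 1)$spike_times, 0)

  # reliability recovery: evoked fraction plus chance spontaneous coverage
  tp <- tagging_preset(reliability = 0.9, spont_rate = 30, n_pulses = 600)
  u3 <- gen_tagging_epoch(tp, seed = 4)
  r <- evoked_latency_reliability(u3)$r
  expected <- 0.9 + 0.1 * (1 - exp(-30 * 0.010))
  expect_lt(abs(r - expected), 3 * sqrt(expected * (1 - expected) / 600))

  expect_error(tagging_preset(reliability = 1.2), "reliability")
})

test_that("population member data are keyed by index, not generation order", {
  a <- gen_population(mixture_spec(c(type1 = 2, type2 = 1), n_trials = 3,
                                   seed = 9))
  b <- gen_population(mixture_spec(c(type1 = 3), n_trials = 3, seed = 9))
  expect_length(a$units, 3L)
  # members 1 and 2 are type1 in both mixtures and must be identical
  expect_identical(a$units[[1]]$spike_times, b$units[[1]]$spike_times)
  expect_identical(a$units[[2]]$spike_times, b$units[[2]]$spike_times)
  expect_identical(a$events, b$events)
  expect_equal(a$labels, c("type1", "type1", "type2"))
})

test_that("learning schedules are monotone with a calibrated half-point", {
  s <- learning_schedule(h = 135)
  g <- s$gain(1:400)
  expect_equal(g[1], 0)
  expect_true(all(diff(g) >= 0))
  expect_equal(g[135], 0.5, tolerance = 0.01)
  expect_gt(g[400], 0.99)
  expect_error(learning_schedule(h = -1), "positive")
})

test_that("locomotor suppression scales the post-cue random walk", {
  flat <- gen_locomotion(n_trials = 20, suppression_gain = 1, seed = 3)
  sp <- speed_from_positions(flat$position)
  v <- cue_window_speed(sp, flat$events, label = "cue")
  bm <- block_average(v, 5)
  expect_lt(max(bm) / min(bm), 1.6)   # stationary across blocks

  gains <- seq(1, 0.1, length.out = 20)
  sup <- gen_locomotion(n_trials = 20, suppression_gain = gains, seed = 3)
  v2 <- cue_window_speed(speed_from_positions(sup$position), sup$events,
                         label = "cue")
  bm2 <- block_average(v2, 5)
  expect_true(all(diff(bm2) < 0))     # block means decrease across blocks
})
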