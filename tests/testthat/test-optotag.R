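test_that("waveform correlation behaves on canonical cases", {
  w <- matrix(rnorm(64), 2)
  expect_equal(waveform_correlation(w, w), 1)
  expect_equal(waveform_correlation(w, -w), -1)
  expect_warning(cc <- waveform_correlation(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(cc))
  expect_error(waveform_correlation(1:4, 1:5), "equal lengths")

  set.seed(1)
  wn <- w + rnorm(64, sd = 0.05 * sd(w))
  expect_gt(waveform_correlation(w, wn), 0.85)
})

test_that("evoked latency and reliability read out the generator", {
  lock <- gen_tagging_epoch(tagging_preset(latency_jitter = 0, reliability = 1,
                                           spont_rate = 0, n_pulses = 80),
                            seed = 2)
  lr <- evoked_latency_reliability(lock)
  expect_equal(lr$r, 1)
  expect_true(all(abs(lr$latencies - 0.003) < 1e-12))

  none <- spike_unit(numeric(),
                     light_pulses = list(onsets = seq(100, 110, 0.1),
                                         width = 0.005),
                     duration = 120)
  expect_equal(evoked_latency_reliability(none)$r, 0)
  expect_error(evoked_latency_reliability(spike_unit(1:3)), "light pulses")
})

test_that("the bootstrap p-value separates locked from unmodulated units", {
  lock <- gen_tagging_epoch(tagging_preset(reliability = 0.9,
                                           latency_jitter = 0.001,
                                           spont_rate = 30, n_pulses = 300),
                            seed = 3)
  p <- tagging_pvalue(lock, n_boot = 500, seed = 1)
  expect_equal(p, 1 / 501)

  # invariant to shifting all times by a constant
  sh <- spike_unit(lock$spike_times + 321.5,
                   waveform_mean = lock$waveform_mean,
                   light_pulses = list(onsets = lock$light_pulses$onsets + 321.5,
                                       width = 0.005),
                   waveform_evoked = lock$waveform_evoked,
                   duration = lock$duration + 321.5)
  expect_equal(tagging_pvalue(sh, n_boot = 500, seed = 1), p)

  # a unit with no spikes in any pulse window is maximally non-significant
  none <- spike_unit(seq(1, 200, 1.01),
                     light_pulses = list(onsets = seq(250, 260, 0.1),
                                         width = 0.005),
                     duration = 265)
  expect_gte(tagging_pvalue(none, n_boot = 200, seed = 1), 0.5)

  # too little stimulation-free time is an error
  short <- spike_unit(c(1, 2, 3),
                      light_pulses = list(onsets = seq(5, 65, 0.1),
                                          width = 0.005),
                      duration = 70)
  expect_error(tagging_pvalue(short), "stimulation-free")

  # median-latency variant also flags the locked unit
  expect_lt(tagging_pvalue(lock, n_boot = 200, seed = 1,
                           statistic = "latency"), 0.01)
})

test_that("classification applies the strict C and p thresholds jointly", {
  lock <- gen_tagging_epoch(tagging_preset(n_pulses = 300), seed = 5)
  res <- classify_tagging(lock, n_boot = 1000, seed = 2)
  expect_gt(res$c, 0.85)
  expect_equal(res$p, 1 / 1001)   # below the 0.001 threshold
  expect_true(res$tagged)

  # same spiking but a mismatched evoked waveform fails the C criterion
  bad <- lock
  bad$waveform_evoked <- lock$waveform_mean[, rev(seq_len(ncol(lock$waveform_mean)))]
  res2 <- classify_tagging(bad, n_boot = 1000, seed = 2)
  expect_false(res2$c > 0.85)
  expect_false(res2$tagged)

  # an unmodulated unit keeps its waveform but fails the p criterion
  null <- gen_tagging_epoch(tagging_preset(reliability = 0, spont_rate = 30,
                                           n_pulses = 300), seed = 6)
  res3 <- classify_tagging(null, n_boot = 1000, seed = 2)
  expect_gt(res3$c, 0.85)
  expect_gt(res3$p, 0.001)
  expect_false(res3$tagged)
})
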