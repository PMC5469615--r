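test_that("moving-average smoothing is exact on hand cases", {
  const <- recording(rep(2.5, 200), rate = 500)
  expect_equal(smooth_trace(const)$trace, rep(2.5, 200))

  x <- numeric(100); x[50] <- 1
  sm <- smooth_trace(recording(x, rate = 500), span = 0.020)  # 10 samples
  expect_equal(sum(sm$trace > 0), 10L)
  expect_equal(unique(round(sm$trace[sm$trace > 0], 12)), 0.1)
  expect_equal(sum(sm$trace), 1)       # interior impulse mass preserved

  expect_error(smooth_trace(recording(1:5 + 0, rate = 500), span = 1), "span")
})

test_that("dF/F is the per-trial fractional change about its own baseline", {
  r <- 100
  tr <- rep(4, 3000)
  ev <- event_stream(c(10, 20), "us", 0.5)
  m <- compute_dff(recording(tr, r), ev, baseline_window = c(-2, -0.5),
                   window = c(-2, 5))
  expect_equal(dim(m$values), c(2L, 701L))
  expect_true(all(m$values == 0))

  tr2 <- rep(4, 3000)
  tr2[1101:1200] <- 8                  # 11.00-11.99 s doubles the baseline
  m2 <- compute_dff(recording(tr2, r), ev, window = c(-2, 5))
  expect_equal(max(m2$values[1, ]), 1.0)
  expect_equal(m2$values[1, m2$time_axis == 1.5], 1.0)
  expect_true(all(m2$values[2, ] == 0))

  # invariant to rescaling the raw trace
  m3 <- compute_dff(recording(tr2 * 37.1, r), ev, window = c(-2, 5))
  expect_equal(m3$values, m2$values)

  # invariant to a common time shift of trace and events
  shift <- 3
  m4 <- compute_dff(recording(c(rep(4, shift * r), tr2), r),
                    event_stream(ev$onset + shift, ev$label, ev$duration),
                    window = c(-2, 5))
  expect_equal(m4$values, m2$values)

  # non-positive baselines are excluded, all-excluded errors
  neg <- recording(rep(-1, 3000) + 2e-9, r)
  expect_error(suppressWarnings(compute_dff(neg, ev, window = c(-2, 5))),
               "all trials excluded")
})

test_that("summaries handle degenerate trial counts", {
  m <- erf_matrix(matrix(1:5, nrow = 1), 1:5)
  s <- erf_summary(m)
  expect_true(s$single_trial)
  expect_equal(s$sem, rep(0, 5))
  s2 <- erf_summary(erf_matrix(rbind(1:5, 1:5), 1:5))
  expect_equal(s2$sem, rep(0, 5))
  expect_equal(s2$mean, as.numeric(1:5))
})

test_that("response metrics are exact on closed-form inputs", {
  tt <- seq(0, 10, 0.002)
  m <- erf_matrix(rbind(0.5 * exp(-tt / 4)), tt)
  met <- response_metrics(m, c(0, 10))
  expect_equal(met$tau_decay, 4, tolerance = 1e-6)
  expect_equal(met$peak_dff, 0.5)
  expect_equal(met$t_peak, 0)
  expect_false(met$tau_flagged)

  flat <- response_metrics(erf_matrix(rbind(rep(0, 100)), seq_len(100)),
                           c(1, 100))
  expect_equal(flat$peak_dff, 0)
  expect_true(flat$tau_flagged)
  expect_true(is.na(flat$tau_decay))

  # AUC is additive over a partition of the window
  set.seed(1)
  m2 <- erf_matrix(matrix(rnorm(300), 3), seq(0.01, 1, 0.01))
  a_full <- response_metrics(m2, c(0.01, 1))$auc
  a1 <- response_metrics(m2, c(0.01, 0.5))$auc
  a2 <- response_metrics(m2, c(0.51, 1))$auc
  expect_equal(a_full, a1 + a2)
})

test_that("block averaging and learning onset follow their definitions", {
  expect_length(block_average(rnorm(20), 5), 4L)
  expect_equal(block_average(1:6, 1), as.numeric(1:6))
  expect_equal(block_average(rep(7, 12), 4), rep(7, 3))
  expect_equal(block_average(c(1, 1, 1, 5, 5, 5, 9), 3), c(1, 5, 9))

  expect_equal(learning_onset(rep(TRUE, 4)), 1L)
  expect_true(is.na(learning_onset(c(TRUE, FALSE, TRUE, FALSE))))
  expect_equal(learning_onset(c(FALSE, TRUE, FALSE, TRUE, TRUE)), 4L)
})

test_that("conditioned cue responses emerge in the scheduled trial range", {
  # aversive conditioning: detection within the first several 5-trial blocks
  p <- transient_preset("footshock")
  ses <- gen_photometry_session(
    p, n_trials = 30, schedule = learning_schedule(7),
    layout = trial_layout("conditioning", iti_range = c(20, 40),
                          us_label = "footshock"),
    seed = 3)
  m <- compute_dff(smooth_trace(ses$recording), ses$events, label = "cue")
  amp <- rowMeans(m$values[, m$time_axis >= 0 & m$time_axis <= 2])
  flags <- vapply(split(amp, ceiling(seq_along(amp) / 5)), function(v)
    stats::t.test(v)$p.value < 0.05 && mean(v) > 0, TRUE)
  onset_block <- learning_onset(unname(flags))
  expect_false(is.na(onset_block))
  first_trial <- (onset_block - 1) * 5 + 1
  expect_gte(first_trial, 1)
  expect_lte(first_trial, 25)

  # appetitive conditioning: sustained inhibition appears around trial 135
  ps <- photometry_site_preset("type1")
  ses2 <- gen_photometry_session(
    ps, n_trials = 200, schedule = learning_schedule(135, direction = "inhibitory"),
    layout = trial_layout("conditioning", us_probability = 0), seed = 1)
  m2 <- compute_dff(smooth_trace(ses2$recording), ses2$events, label = "cue")
  amp2 <- rowMeans(m2$values[, m2$time_axis >= 0 & m2$time_axis <= 4])
  flags2 <- vapply(split(amp2, ceiling(seq_along(amp2) / 10)), function(v)
    stats::t.test(v)$p.value < 0.05 && mean(v) < 0, TRUE)
  onset2 <- learning_onset(unname(flags2))
  expect_false(is.na(onset2))
  first_trial2 <- (onset2 - 1) * 10 + 1
  expect_gte(first_trial2, 100)
  expect_lte(first_trial2, 180)
})
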