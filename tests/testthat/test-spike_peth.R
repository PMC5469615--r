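test_that("PETH counts are conserved and exact on hand cases", {
  ev <- event_stream(c(10, 30), "cue", 2)
  empty <- spike_unit(numeric(), duration = 50)
  p0 <- peth(empty, ev, window = c(-1, 1))
  expect_true(all(p0$rates == 0))
  expect_equal(dim(p0$rates), c(2L, 40L))

  one <- spike_unit(10.01, duration = 50)
  p1 <- peth(one, ev, window = c(0, 0.5), bin_width = 0.05)
  expect_equal(p1$rates[1, 1], 20)          # 1 spike / 50 ms bin
  expect_equal(sum(p1$rates), 20)
  expect_equal(p1$time_axis[1], 0.025)

  set.seed(2)
  spikes <- sort(runif(500, 0, 60))
  u <- spike_unit(spikes, duration = 60)
  ev2 <- event_stream(c(10, 25, 40), "cue", 2)   # windows do not overlap
  p2 <- peth(u, ev2, window = c(-2, 10), bin_width = 0.05)
  in_win <- sum(vapply(ev2$onset, function(on)
    sum(spikes >= on - 2 & spikes < on + 10), 0))
  expect_equal(sum(p2$rates) * p2$bin_width, in_win)  # exact conservation

  expect_error(peth(u, events_with_label(ev2, "absent")), "no events")
})

test_that("a homogeneous 30 Hz unit averages to its rate", {
  flat <- spike_profile_preset("type1", baseline_rate = 30, cue_rate = 30,
                               us_rate = 30, rebound_rate = 30)
  ses <- gen_spike_unit(flat, n_trials = 50, seed = 8)
  p <- peth(ses$units[[1]], ses$events, label = "cue")
  expect_equal(mean(p$rates), 30, tolerance = 0.05)
})

test_that("Gaussian smoothing preserves mass and reproduces the kernel", {
  ta <- seq(0.025, 4.975, 0.05)
  const <- peth_matrix(matrix(12, 2, length(ta)), 0.05, ta)
  expect_equal(gaussian_smooth(const)$rates, const$rates)

  imp <- matrix(0, 1, length(ta)); imp[1, 50] <- 1
  sm <- gaussian_smooth(peth_matrix(imp, 0.05, ta), sigma = 0.05)
  k <- dnorm(-4:4, sd = 1); k <- k / sum(k)
  expect_equal(sm$rates[1, 46:54], k, tolerance = 1e-12)
  expect_equal(sum(sm$rates), 1)      # interior mass preserved exactly

  set.seed(5)
  r <- matrix(rpois(3 * length(ta), 5), 3)
  smr <- gaussian_smooth(peth_matrix(r, 0.05, ta), sigma = 0.05)
  interior <- 10:(length(ta) - 10)
  expect_equal(rowSums(smr$rates[, interior]), rowSums(r[, interior]),
               tolerance = 0.01)
})

test_that("z-profiles standardize against the control period", {
  flat <- spike_profile_preset("type1", baseline_rate = 30, cue_rate = 30,
                               us_rate = 30, rebound_rate = 30)
  ses <- gen_spike_unit(flat, n_trials = 40, seed = 9)
  p <- gaussian_smooth(peth(ses$units[[1]], ses$events, label = "cue"))
  z <- zscore_profile(p, control_window = c(-2, 10))  # whole axis as control
  expect_equal(mean(z$z), 0, tolerance = 1e-10)
  expect_equal(sd(z$z), 1, tolerance = 1e-10)

  # invariant to rescaling all rates by a positive constant
  p2 <- peth_matrix(p$rates * 2.7, p$bin_width, p$time_axis)
  expect_equal(zscore_profile(p2, c(-2, 10))$z, z$z)

  # type1 unit: inhibition during reward delivery
  t1 <- gen_spike_unit(spike_profile_preset("type1"), n_trials = 60, seed = 10)
  pz <- zscore_profile(gaussian_smooth(peth(t1$units[[1]], t1$events,
                                            label = "cue")),
                       control_window = c(-2, 0))
  us_bins <- pz$time_axis >= 4 & pz$time_axis <= 4.5
  expect_lt(mean(pz$z[us_bins]), -1)

  # pathological zero-variance control period is flagged
  pc <- peth_matrix(matrix(5, 2, 20), 0.05, seq(0.025, 0.975, 0.05))
  expect_warning(zf <- zscore_profile(pc, c(0, 1)), "sd is zero")
  expect_true(zf$flagged)
  expect_true(all(is.na(zf$z)))
})
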