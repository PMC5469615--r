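test_that("max-|T| p-values match exhaustive sign-flip enumeration", {
  set.seed(4)
  ta <- seq(0, 1.9, 0.1)
  x <- matrix(rnorm(4 * 20), 4) + rep(c(0, 0.8), each = 10)[col(matrix(0, 4, 20))]
  r <- maxt_test(x, baseline_window = c(0, 0.4), time_axis = ta, exact = TRUE)
  oracle <- brute_maxt(x, which(ta >= 0 & ta <= 0.4))
  expect_equal(r$n_perm, 16L)
  expect_equal(r$p, oracle$p, tolerance = 1e-10)
  expect_equal(r$t_obs, oracle$t_obs, tolerance = 1e-10)

  # the exact path is invariant to trial order
  perm <- c(3, 1, 4, 2)
  r2 <- maxt_test(x[perm, ], baseline_window = c(0, 0.4), time_axis = ta,
                  exact = TRUE)
  expect_equal(r2$p, r$p)
})

test_that("segments are maximal runs of corrected significance", {
  set.seed(11)
  ta <- seq(-2, 9.995, 0.005)
  x <- matrix(rnorm(10 * length(ta), sd = 0.01), 10)
  bump <- exp(-(ta - 1)^2 / 0.5); bump[ta < 0] <- 0
  x <- x + rep(0.3 * bump, each = 10)
  r <- maxt_test(x, baseline_window = c(-2, -0.5), time_axis = ta,
                 n_perm = 500, seed = 2)
  expect_gte(nrow(r$segments_up), 1L)
  expect_equal(nrow(r$segments_down), 0L)
  # the detected increase covers the injected bump peak
  expect_true(any(r$segments_up[, 1] <= 1 & r$segments_up[, 2] >= 1))
  sig <- r$p < r$alpha & r$t_obs > 0
  expect_equal(sum(sig), sum(apply(r$segments_up, 1, function(s)
    sum(ta >= s[1] & ta <= s[2]))))
  # determinism under the seed
  expect_identical(r, maxt_test(x, baseline_window = c(-2, -0.5),
                                time_axis = ta, n_perm = 500, seed = 2))
})

test_that("all-zero data yield p = 1 everywhere and no segments", {
  z <- maxt_test(matrix(0, 5, 60), baseline_window = c(0, 0.1),
                 time_axis = seq(0, 0.59, 0.01), seed = 1)
  expect_true(all(z$p == 1))
  expect_equal(nrow(z$segments_up) + nrow(z$segments_down), 0L)
  expect_error(maxt_test(matrix(0, 1, 10), time_axis = 1:10), "two trials")
})

test_that("family-wise error stays at the nominal level on null data", {
  hits <- vapply(1:100, function(i) {
    m <- gen_null_erf(n_trials = 10, window = c(-1, 1), rate = 100, seed = i)
    r <- maxt_test(m, baseline_window = c(-1, -0.5), n_perm = 200,
                   alpha = 0.05, seed = i)
    nrow(r$segments_up) + nrow(r$segments_down) > 0
  }, TRUE)
  margin <- 1.96 * sqrt(0.05 * 0.95 / 100)
  expect_lte(mean(hits), 0.05 + margin)
})

test_that("two-sample permutation tests match exhaustive enumeration", {
  expect_equal(strength_perm_test(c(1, 2, 3), c(1, 2, 3)), 1)

  set.seed(6)
  a <- rnorm(3); b <- rnorm(3) + 1
  p <- strength_perm_test(a, b)          # enumerates all 20 splits
  splits <- combn(6, 3)
  pool <- c(a, b)
  d_obs <- abs(mean(a) - mean(b))
  d_null <- apply(splits, 2, function(ix) abs(mean(pool[ix]) - mean(pool[-ix])))
  expect_equal(p, mean(d_null >= d_obs - 1e-12))

  # widely separated large groups bottom out at the add-one floor
  p2 <- strength_perm_test(rnorm(10), rnorm(10) + 100, n_perm = 999,
                           seed = 1, exact = FALSE)
  expect_equal(p2, 1 / 1000)
  expect_error(strength_perm_test(1, c(1, 2)), "two values")
})

test_that("KS comparisons equal the brute-force sup distance", {
  same <- suppressWarnings(ks_compare(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(same$d, 0)
  expect_equal(ks_compare(1:5, 11:15)$d, 1)
  set.seed(8)
  a <- rnorm(11); b <- rnorm(13, 0.5)
  r <- ks_compare(a, b)
  expect_equal(r$d, brute_ks_d(a, b), tolerance = 1e-12)
  expect_true(r$p >= 0 && r$p <= 1)
})
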