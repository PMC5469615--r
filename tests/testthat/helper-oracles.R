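# Independent brute-force oracles. These deliberately avoid the package's own
# computational paths (and the optimized identities they use), so agreement is
# informative.

# Max-|T| sign-flip test by full enumeration: pointwise one-sample t via
# mean/var loops, null from every sign vector.
brute_maxt <- function(x, baseline_idx) {
  n <- nrow(x)
  xb <- x - rowMeans(x[, baseline_idx, drop = FALSE])
  t_of <- function(m) apply(m, 2, function(col) {
    s <- stats::sd(col)
    if (s == 0) 0 else mean(col) / (s / sqrt(length(col)))
  })
  t_obs <- t_of(xb)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  max_null <- apply(signs, 1, function(s) max(abs(t_of(xb * s))))
  p <- vapply(abs(t_obs), function(tt) mean(max_null >= tt), 0)
  list(t_obs = t_obs, p = p)
}

# AUC by explicit pairwise comparison.
brute_auc <- function(a, b) {
  cmp <- outer(a, b, ">") + 0.5 * outer(a, b, "==")
  mean(cmp)
}

# Two-sample KS D as the sup distance between empirical CDFs.
brute_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(ecdf(a)(pts) - ecdf(b)(pts)))
}

# Complete-linkage agglomeration from a distance matrix, returning the
# ordered merge heights.
brute_complete_heights <- function(d) {
  d <- as.matrix(d)
  groups <- as.list(seq_len(nrow(d)))
  heights <- numeric()
  while (length(groups) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(groups)) for (j in seq_len(i - 1L)) {
      h <- max(d[groups[[i]], groups[[j]]])
      if (h < best[1]) best <- c(h, j, i)
    }
    heights <- c(heights, best[1])
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  heights
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  sa <- sum(ch2(rowSums(tab)))
  sb <- sum(ch2(colSums(tab)))
  n2 <- ch2(sum(tab))
  exp_ind <- sa * sb / n2
  (sij - exp_ind) / ((sa + sb) / 2 - exp_ind)
}

# Small fully-populated synthetic session for I/O round-trips.
make_io_session <- function(seed = 7) {
  set.seed(seed)
  rec <- recording(1 + 0.05 * rnorm(300), rate = 100, t0 = 0.5,
                   channel_label = "gcamp")
  ev <- event_stream(c(0.8, 1.5, 2.2), c("cue", "us", "cue"), c(2, 0.5, 2))
  u1 <- spike_unit(sort(runif(40, 0, 3.4)),
                   waveform_mean = matrix(rnorm(8), 2),
                   unit_id = "u1",
                   light_pulses = list(onsets = seq(2, 3, 0.1), width = 0.005),
                   waveform_evoked = matrix(rnorm(8), 2), duration = 3.5)
  u2 <- spike_unit(c(0.3, 0.9), waveform_mean = rnorm(6), unit_id = "u2",
                   duration = 3.5)
  pos <- position_trace(seq(0, 3, 0.1), cbind(cumsum(rnorm(31)),
                                              cumsum(rnorm(31))))
  session(rec, ev, list(u1, u2), pos)
}

expect_session_equal <- function(a, b, tolerance = 1e-12) {
  expect_equal(a$recording, b$recording, tolerance = tolerance)
  expect_equal(as.data.frame(a$events), as.data.frame(b$events),
               tolerance = tolerance)
  expect_equal(length(a$units), length(b$units))
  for (id in names(a$units))
    expect_equal(a$units[[id]], b$units[[id]], tolerance = tolerance)
  expect_equal(a$position, b$position, tolerance = tolerance)
}
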