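#' @keywords internal
"_PACKAGE"

# Deterministic child-seed derivation: a fixed multiplicative hash keyed by
# (master seed, index, salt) so per-unit / per-session streams are independent
# of generation order. Result always fits a 32-bit R integer.
derive_seed <- function(master, index, salt = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- (as.double(master) * 2654435761 + as.double(index) * 40503 +
          as.double(salt) * 69821) %% 2147483647
  as.integer(h) + 1L
}

# First index at which a numeric vector fails to strictly increase, or 0L.
first_nonincreasing <- function(x) {
  if (length(x) < 2L) return(0L)
  bad <- which(diff(x) <= 0)
  if (length(bad)) bad[1L] + 1L else 0L
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}

# Indices of a time axis falling inside [window[1], window[2]] (closed).
window_index <- function(time_axis, window) {
  if (length(window) != 2L || window[2] < window[1])
    stop("window must be c(start, end) with end >= start", call. = FALSE)
  idx <- which(time_axis >= window[1] & time_axis <= window[2])
  if (!length(idx))
    stop(sprintf("window [%g, %g] does not overlap the time axis [%g, %g]",
                 window[1], window[2], min(time_axis), max(time_axis)),
         call. = FALSE)
  idx
}

# Maximal runs of TRUE in a logical vector -> two-column matrix of
# (start index, end index); zero-row matrix when none.
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  cbind(start = starts[keep], end = ends[keep])
}
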