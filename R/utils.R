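#' Central-difference time derivative
#'
#' Differentiates a uniformly sampled series (or each column of a matrix)
#' with central differences at interior samples and one-sided differences at
#' the two ends. This is the single differentiation scheme used throughout
#' the package (marker velocities, jerk, torque rate, effort), so derived
#' series stay numerically consistent with their parents.
#'
#' @param x numeric vector or matrix (rows = time).
#' @param sample_rate sampling rate in Hz.
#' @return object of the same shape as `x` containing d`x`/dt.
#' @export
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' v <- finite_diff(t^2, 100)  # ~ 2 t at interior samples
finite_diff <- function(x, sample_rate) {
  if (is.matrix(x)) return(apply(x, 2, finite_diff, sample_rate = sample_rate))
  n <- length(x)
  if (n < 2L) stop("finite_diff() needs at least 2 samples")
  d <- numeric(n)
  d[1L] <- (x[2L] - x[1L]) * sample_rate
  d[n] <- (x[n] - x[n - 1L]) * sample_rate
  if (n > 2L) d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * sample_rate / 2
  d
}

# Deterministic substream seed derivation (Lehmer step), keeps results
# reproducible for any subset of the dataset without sharing one RNG stream.
# All intermediates stay below 2^53 so double arithmetic is exact.
derive_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (k in ks) s <- (s * 48271 + as.numeric(k) + 1) %% 2147483647
  as.integer(s)
}

# Zero-phase low-pass Butterworth (order 4 by default), applied columnwise.
# Zero-phase (forward-backward) filtering avoids the group delay that would
# desynchronise kinematic and dynamic series.
lowpass <- function(x, sample_rate, cutoff = 6, order = 4) {
  if (cutoff <= 0 || cutoff >= sample_rate / 2)
    stop("cutoff must lie in (0, Nyquist)")
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "low")
  filt1 <- function(v) signal::filtfilt(bf, v)
  if (is.matrix(x)) apply(x, 2, filt1) else filt1(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  invisible(x)
}
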