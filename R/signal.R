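#' Quantization step of a sensor grid
#'
#' A logger with half-range `range_g` and `bits` output resolution represents
#' accelerations on the grid `-range_g + k * step`, `k = 0 .. 2^bits - 1`,
#' with `step = 2 * range_g / 2^bits`. A +/-8 g, 8-bit device therefore has
#' 256 levels and a 0.0625 g step (0.063 g to three decimals).
#'
#' @param range_g sensor half-range in g (> 0).
#' @param bits output resolution in bits (2..16).
#' @return the grid step in g.
#' @export
quantization_step <- function(range_g, bits) {
  .check_sensor(range_g, bits)
  2 * range_g / 2^bits
}

.check_sensor <- function(range_g, bits) {
  if (!is.numeric(range_g) || length(range_g) != 1L || !is.finite(range_g) || range_g <= 0)
    stop("`range_g` must be a single positive number")
  if (!is.numeric(bits) || length(bits) != 1L || bits != round(bits) || bits < 2 || bits > 16)
    stop("`bits` must be an integer in [2, 16]")
  invisible(TRUE)
}

#' Quantize a trace onto a sensor grid
#'
#' Maps every value to the nearest representable level
#' `-range_g + k * step`, with ties rounded half away from zero and
#' out-of-range values clipped to the extreme levels (saturating MEMS
#' output). The operation is idempotent and nonexpansive:
#' `|quantize(v) - v| <= step / 2` for in-range `v`.
#'
#' @param trace an `accel_trace`.
#' @param range_g sensor half-range in g (default 8, the field setting).
#' @param bits output resolution (default 8, i.e. 256 levels).
#' @return a quantized `accel_trace` with sensor metadata set.
#' @export
quantize <- function(trace, range_g = 8, bits = 8) {
  stopifnot(inherits(trace, "accel_trace"))
  .check_sensor(range_g, bits)
  v <- trace$samples
  if (nrow(v) > 0 && !all(is.finite(v))) stop("non-finite input")
  step <- 2 * range_g / 2^bits
  # grid index; ties in v-space round half away from zero
  idx <- (v + range_g) / step
  k <- ifelse(v >= 0, floor(idx + 0.5), ceiling(idx - 0.5))
  k <- pmin(pmax(k, 0), 2^bits - 1)
  q <- -range_g + k * step
  accel_trace(q[, "ax"], q[, "ay"], q[, "az"], trace$sample_rate,
              sensor_range = range_g, sensor_bits = bits)
}

#' Subsample a trace by an integer factor
#'
#' Keeps samples at original (0-based) indices `0, factor, 2*factor, ...`
#' bit-identically; the new rate is `sample_rate / factor`. Taking every
#' fourth data point converts a 100 Hz recording to 25 Hz.
#'
#' @param trace an `accel_trace`.
#' @param factor integer >= 1.
#' @return the subsampled `accel_trace` of length `ceiling(n / factor)`.
#' @export
subsample <- function(trace, factor) {
  stopifnot(inherits(trace, "accel_trace"))
  if (!is.numeric(factor) || length(factor) != 1L || factor != round(factor) || factor < 1)
    stop("`factor` must be a positive integer")
  keep <- seq(1L, nrow(trace$samples), by = factor)
  s <- trace$samples[keep, , drop = FALSE]
  accel_trace(s[, "ax"], s[, "ay"], s[, "az"], trace$sample_rate / factor,
              sensor_range = trace$sensor_range, sensor_bits = trace$sensor_bits)
}

# Centered running mean with clipped edge windows: at position i the mean is
# taken over [max(1, i-h), min(n, i+h)], h = (w-1)/2, so the output has the
# input's length and no fabricated padding enters the average.
.running_mean <- function(x, w) {
  n <- length(x)
  h <- (w - 1) / 2
  cs <- c(0, cumsum(x))
  lo <- pmax(1, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Static (gravitational + postural) acceleration
#'
#' Estimates the static component of each axis as a centered running mean.
#' The default window of 5 samples corresponds to 0.22 s at the 23 Hz field
#' sampling rate. Near the trace boundaries the window is clipped to the
#' available samples, so the output has the same length as the input.
#'
#' @param trace an `accel_trace`.
#' @param window_samples odd window length in samples (default 5).
#' @return an `accel_trace` of smoothed (static) accelerations.
#' @export
static_acceleration <- function(trace, window_samples = 5) {
  stopifnot(inherits(trace, "accel_trace"))
  w <- window_samples
  if (!is.numeric(w) || length(w) != 1L || w != round(w) || w < 1)
    stop("`window_samples` must be a positive integer")
  if (w %% 2 == 0) stop("`window_samples` must be odd (centering is undefined otherwise)")
  if (w > nrow(trace$samples)) stop("`window_samples` exceeds the trace length")
  s <- apply(trace$samples, 2, .running_mean, w = w)
  if (is.null(dim(s))) s <- matrix(s, nrow = 1, dimnames = list(NULL, c("ax", "ay", "az")))
  accel_trace(s[, 1], s[, 2], s[, 3], trace$sample_rate)
}

#' Vectorial dynamic body acceleration (VeDBA)
#'
#' Subtracts the running-mean static acceleration from the raw trace to get
#' the dynamic body acceleration DBA = A - A_static per axis, then takes the
#' per-sample Euclidean norm:
#' `VeDBA = sqrt(DBA_x^2 + DBA_y^2 + DBA_z^2)`.
#'
#' @param trace an `accel_trace`.
#' @param window_samples odd running-mean window (default 5 samples,
#'   i.e. 0.22 s at 23 Hz).
#' @return an object of class `vedba_series`: list with `values` (nonnegative,
#'   one per sample) and `sample_rate`.
#' @export
vedba <- function(trace, window_samples = 5) {
  st <- static_acceleration(trace, window_samples)
  dba <- trace$samples - st$samples
  structure(list(values = sqrt(rowSums(dba^2)), sample_rate = trace$sample_rate),
            class = "vedba_series")
}

#' @export
print.vedba_series <- function(x, ...) {
  cat(sprintf("<vedba_series> %d samples at %g Hz, mean %.3f g\n",
              length(x$values), x$sample_rate, mean(x$values)))
  invisible(x)
}

#' Mean VeDBA over a time segment
#'
#' Averages the VeDBA samples whose timestamps fall in the half-open
#' interval `[start, start + duration)`; timestamps are
#' `(i - 1) / sample_rate` (0-based sample index over rate).
#'
#' @param series a `vedba_series`.
#' @param start segment start in seconds (>= 0).
#' @param duration segment duration in seconds (> 0).
#' @return mean VeDBA in g.
#' @export
segment_mean_vedba <- function(series, start, duration) {
  stopifnot(inherits(series, "vedba_series"))
  if (duration <= 0) stop("`duration` must be positive")
  extent <- length(series$values) / series$sample_rate
  if (start < 0 || start + duration > extent + 1e-9)
    stop("segment [", start, ", ", start + duration, ") lies outside the series extent")
  t <- (seq_along(series$values) - 1) / series$sample_rate
  sel <- t >= start & t < start + duration
  if (!any(sel)) stop("segment contains no samples")
  mean(series$values[sel])
}
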