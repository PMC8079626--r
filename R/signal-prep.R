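#' Resample a trace onto an even time grid
#'
#' Device logs can carry uneven sample times; event detection assumes an
#' even grid, so force and direction are linearly interpolated onto
#' `t0 + k/rate` where `t0` is the first sample time. The grid never
#' extends beyond the recorded span (no extrapolation).
#'
#' @param trace A `leash_trace` with at least two samples.
#' @param rate Target rate in Hz (default 10, the device's nominal rate).
#' @return A uniform `leash_trace`.
#' @export
interpolate_uniform <- function(trace, rate = 10) {
  validate_trace(trace)
  if (nrow(trace) < 2) {
    rlang::abort("need at least 2 samples to interpolate",
                 class = "leashwalk_empty_error")
  }
  if (!is.numeric(rate) || rate <= 0) {
    rlang::abort("rate must be positive", class = "leashwalk_parameter_error")
  }
  t0 <- trace$time_s[1]
  span <- trace$time_s[nrow(trace)] - t0
  grid <- t0 + seq(0, floor(span * rate + 1e-9)) / rate
  f <- stats::approx(trace$time_s, trace$force_kgf, xout = grid)$y
  d <- stats::approx(trace$time_s, trace$dir, xout = grid)$y
  out <- leash_trace(grid, f, d, session_id = trace_session(trace),
                     rate_hz = rate,
                     range_kgf = trace_meta(trace)$range_kgf,
                     resolution_kgf = trace_meta(trace)$resolution_kgf,
                     uniform = TRUE,
                     tarred = is_tarred(trace),
                     smoothed = attr(trace, "smoothed") %||% 0L)
  out
}

#' Tare a trace to its baseline
#'
#' Subtracts the minimum force from every sample, so the unloaded baseline
#' (the value seen when the device is not connected to a dog) reads zero.
#' The direction channel is unchanged. Idempotent.
#'
#' @param trace A non-empty `leash_trace`.
#' @return The tarred trace (`min(force) == 0`).
#' @export
tare <- function(trace) {
  if (nrow(trace) == 0) {
    rlang::abort("cannot tare an empty trace", class = "leashwalk_empty_error")
  }
  trace$force_kgf <- trace$force_kgf - min(trace$force_kgf)
  attr(trace, "tarred") <- TRUE
  trace
}

#' Smooth a trace with a centered moving average
#'
#' The filter applied before event detection: a centered moving average of
#' odd `window` length, truncated at the edges (the mean runs over the
#' samples actually available inside the window). `window = 1` is the
#' identity and disables smoothing.
#'
#' @param trace A `leash_trace`.
#' @param window Odd positive window length in samples (default 3, i.e.
#'   0.3 s at 10 Hz).
#' @return The smoothed trace, with the window recorded in its metadata.
#' @export
smooth_trace <- function(trace, window = 3) {
  if (!is.numeric(window) || length(window) != 1 || window < 1 ||
      window %% 2 != 1) {
    rlang::abort("window must be a positive odd sample count",
                 class = "leashwalk_parameter_error")
  }
  window <- as.integer(window)
  if (window > 1L && nrow(trace) > 0) {
    trace$force_kgf <- moving_average(trace$force_kgf, window)
  }
  attr(trace, "smoothed") <- window
  trace
}

# centered moving average with edge truncation, via cumulative sums
moving_average <- function(x, window) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Standard walk-segment preparation
#'
#' Convenience chain: interpolate to an even grid, tare, then smooth —
#' the default order used throughout the package (taring before smoothing;
#' the order is configurable by calling the steps directly).
#'
#' @inheritParams interpolate_uniform
#' @inheritParams smooth_trace
#' @return A uniform, tarred, smoothed `leash_trace`.
#' @export
prepare_walk <- function(trace, rate = 10, window = 3) {
  trace |>
    interpolate_uniform(rate = rate) |>
    tare() |>
    smooth_trace(window = window)
}
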