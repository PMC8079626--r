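#' Construct a leash-tension trace
#'
#' A trace is a tibble with one row per sample and columns `time_s` (seconds
#' since recording start), `force_kgf` (leash tension in kilogram-force) and
#' `dir` (signed direction scalar in \[-1, 1\]; positive values indicate a
#' dog-ward pull, negative a handler-ward pull). Device metadata and
#' processing state travel as attributes so the tibble itself stays tidy.
#'
#' The reference device samples at 10 Hz over a 0--100 kgf range with 100 g
#' resolution; those are the metadata defaults.
#'
#' @param time_s Numeric vector of sample times, strictly increasing.
#' @param force_kgf Numeric vector of tension values, within the device range.
#' @param dir Numeric vector of signed direction values in \[-1, 1\].
#' @param session_id Identifier for the recording session.
#' @param rate_hz Nominal device sampling rate (Hz).
#' @param range_kgf Length-2 numeric, the device measuring range in kgf.
#' @param resolution_kgf Device resolution in kgf (must be positive).
#' @param uniform Logical; `TRUE` once the trace is on an even time grid.
#' @param tarred Logical; `TRUE` once the minimum has been subtracted.
#' @param smoothed Integer smoothing window in samples (0 = raw).
#' @return A tibble of class `leash_trace`.
#' @examples
#' leash_trace(c(0, 0.1, 0.2), c(1.2, 1.3, 1.1), c(0.5, 0.4, -0.2))
#' @export
leash_trace <- function(time_s, force_kgf, dir = rep(0, length(time_s)),
                        session_id = "session",
                        rate_hz = 10, range_kgf = c(0, 100),
                        resolution_kgf = 0.1,
                        uniform = FALSE, tarred = FALSE, smoothed = 0L) {
  out <- tibble::tibble(time_s = as.numeric(time_s),
                        force_kgf = as.numeric(force_kgf),
                        dir = as.numeric(dir))
  attr(out, "session_id") <- as.character(session_id)
  attr(out, "meta") <- list(rate_hz = rate_hz, range_kgf = range_kgf,
                            resolution_kgf = resolution_kgf)
  attr(out, "uniform") <- isTRUE(uniform)
  attr(out, "tarred") <- isTRUE(tarred)
  attr(out, "smoothed") <- as.integer(smoothed)
  class(out) <- c("leash_trace", class(out))
  validate_trace(out)
}

#' Validate a leash trace against its invariants
#'
#' Checks strictly increasing time, forces within the device range, equal
#' column lengths and positive resolution metadata. Returns the trace
#' invisibly usable in a pipe; aborts with a classed condition on violation.
#'
#' @param trace A `leash_trace`.
#' @param allow_negative Permit negative forces (used transiently before
#'   taring checks; the device itself never reports below range).
#' @return The validated trace (invisibly its input).
#' @export
validate_trace <- function(trace, allow_negative = FALSE) {
  if (!all(c("time_s", "force_kgf", "dir") %in% names(trace))) {
    rlang::abort("trace must have columns time_s, force_kgf, dir",
                 class = "leashwalk_format_error")
  }
  meta <- trace_meta(trace)
  if (!is.numeric(meta$resolution_kgf) || meta$resolution_kgf <= 0) {
    rlang::abort("device resolution must be positive",
                 class = "leashwalk_format_error")
  }
  if (nrow(trace) > 0) {
    if (any(diff(trace$time_s) <= 0)) {
      rlang::abort("sample times must be strictly increasing",
                   class = "leashwalk_format_error")
    }
    lo <- if (allow_negative) -Inf else meta$range_kgf[1]
    if (any(trace$force_kgf < lo | trace$force_kgf > meta$range_kgf[2])) {
      rlang::abort(
        sprintf("force outside device range [%g, %g] kgf",
                meta$range_kgf[1], meta$range_kgf[2]),
        class = "leashwalk_range_error")
    }
  }
  trace
}

trace_meta <- function(trace) {
  meta <- attr(trace, "meta", exact = TRUE)
  if (is.null(meta)) meta <- list(rate_hz = 10, range_kgf = c(0, 100),
                                  resolution_kgf = 0.1)
  meta
}

trace_session <- function(trace) {
  sid <- attr(trace, "session_id", exact = TRUE)
  if (is.null(sid)) "session" else sid
}

is_tarred <- function(trace) isTRUE(attr(trace, "tarred", exact = TRUE))

#' @exportS3Method base::print
print.leash_trace <- function(x, ...) {
  meta <- trace_meta(x)
  cat(sprintf(
    "<leash_trace> session '%s': %d samples, %g Hz nominal%s%s\n",
    trace_session(x), nrow(x), meta$rate_hz,
    if (is_tarred(x)) ", tarred" else "",
    if (attr(x, "smoothed") %||% 0L > 0L)
      sprintf(", smoothed (window %d)", attr(x, "smoothed")) else ""))
  NextMethod()
}

#' Read a device trace log
#'
#' Reads the CSV trace dialect with header `time_s,force_kgf,dir`. In strict
#' mode any non-increasing timestamp aborts; in lenient mode offending rows
#' are dropped with a message reporting the count.
#'
#' @param path Path to a trace CSV.
#' @param strict Abort on malformed rows (default) instead of dropping them.
#' @param session_id Session identifier; defaults to the file name.
#' @inheritParams leash_trace
#' @return A `leash_trace`.
#' @export
read_trace <- function(path, strict = TRUE, session_id = NULL,
                       rate_hz = 10, range_kgf = c(0, 100),
                       resolution_kgf = 0.1) {
  if (!file.exists(path)) {
    rlang::abort(paste0("no such trace file: ", path),
                 class = "leashwalk_format_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0 && ncol(df) == 0) {
    rlang::abort("empty trace file", class = "leashwalk_empty_error")
  }
  missing <- setdiff(c("time_s", "force_kgf", "dir"), names(df))
  if (length(missing)) {
    rlang::abort(paste0("trace file missing column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "leashwalk_format_error")
  }
  bad <- !is.finite(df$time_s) | !is.finite(df$force_kgf) | !is.finite(df$dir)
  bad[-1] <- bad[-1] | diff(df$time_s) <= 0
  if (any(bad)) {
    if (strict) {
      rlang::abort(sprintf(
        "%d malformed row(s) (non-finite or non-increasing time); use strict = FALSE to drop",
        sum(bad)), class = "leashwalk_format_error")
    }
    rlang::inform(sprintf("dropping %d malformed row(s)", sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  leash_trace(df$time_s, df$force_kgf, df$dir,
              session_id = session_id %||% sub("\\.[^.]*$", "", basename(path)),
              rate_hz = rate_hz, range_kgf = range_kgf,
              resolution_kgf = resolution_kgf)
}

#' Write a trace in the device CSV dialect
#'
#' Forces are quantized to the device resolution (100 g by default) on the
#' way out, so a write/read round trip is the identity up to that rounding.
#'
#' @param trace A `leash_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  validate_trace(trace)
  res <- trace_meta(trace)$resolution_kgf
  out <- tibble::tibble(
    time_s = trace$time_s,
    force_kgf = round(trace$force_kgf / res) * res,
    dir = trace$dir)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Locate the calibration hold, sync pulls and walk segment
#'
#' A recording starts with a 10 s vertical calibration hold, followed by
#' three deliberate 3 s pulls used to synchronize the tension record with
#' the video, then the walk itself. Sync pulls are found as maximal runs
#' with force at or above `min_force` lasting at least `min_duration`
#' seconds; exactly three must be present. The calibration segment is
#' everything before the first pull; the walk starts `guard_gap` seconds
#' after the last pull ends.
#'
#' Intervals are half-open on 1-based sample indices: `[start, end)` covers
#' rows `start` to `end - 1`.
#'
#' @param trace A `leash_trace` covering the pre-walk protocol.
#' @param min_force Minimum pull amplitude in kgf (default 5).
#' @param min_duration Minimum pull duration in seconds (default 2).
#' @param guard_gap Seconds between the last pull end and the walk start.
#' @return A tibble of class `segment_map` with columns `segment`, `start`,
#'   `end` (rows: calibration, sync1..sync3, walk).
#' @export
find_sync_pulses <- function(trace, min_force = 5, min_duration = 2,
                             guard_gap = 1) {
  validate_trace(trace)
  t <- trace$time_s
  above <- trace$force_kgf >= min_force
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- tibble::tibble(start = starts[r$values], end = ends[r$values] + 1L)
  if (nrow(cand)) {
    # run duration measured between its first and last sample
    cand$duration_s <- vapply(seq_len(nrow(cand)), function(i) {
      last <- min(cand$end[i] - 1L, length(t))
      t[last] - t[cand$start[i]]
    }, numeric(1))
    cand$qualifies <- cand$duration_s >= min_duration
  } else {
    cand$duration_s <- numeric(0)
    cand$qualifies <- logical(0)
  }
  pulses <- cand[cand$qualifies, , drop = FALSE]
  if (nrow(pulses) != 3L) {
    rlang::abort(
      sprintf("expected 3 sync pulses, found %d qualifying (of %d candidate runs)",
              nrow(pulses), nrow(cand)),
      class = "leashwalk_sync_error",
      candidates = cand)
  }
  walk_t0 <- t[pulses$end[3] - 1L] + guard_gap
  walk_start <- match(TRUE, t >= walk_t0)
  if (is.na(walk_start) || walk_start > nrow(trace)) {
    rlang::abort("no walk samples after the last sync pulse",
                 class = "leashwalk_sync_error", candidates = cand)
  }
  out <- tibble::tibble(
    segment = c("calibration", "sync1", "sync2", "sync3", "walk"),
    start = c(1L, pulses$start, walk_start),
    end = c(pulses$start[1], pulses$end, nrow(trace) + 1L))
  class(out) <- c("segment_map", class(out))
  out
}

#' Extract one segment of a trace
#'
#' @param trace A `leash_trace`.
#' @param segments A `segment_map` from [find_sync_pulses()].
#' @param which Segment name, e.g. `"walk"` or `"calibration"`.
#' @return A `leash_trace` restricted to that segment.
#' @export
trace_segment <- function(trace, segments, which = "walk") {
  row <- segments[segments$segment == which, ]
  if (nrow(row) != 1) {
    rlang::abort(paste0("unknown segment: ", which),
                 class = "leashwalk_parameter_error")
  }
  idx <- seq.int(row$start, row$end - 1L)
  out <- trace[idx, , drop = FALSE]
  for (a in c("session_id", "meta", "uniform", "tarred", "smoothed")) {
    attr(out, a) <- attr(trace, a, exact = TRUE)
  }
  class(out) <- unique(c("leash_trace", class(out)))
  out
}
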