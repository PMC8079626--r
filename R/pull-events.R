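#' Pull-detection threshold from body weight
#'
#' The detection threshold is 0.1% of the dog's body-weight force: a 20 kg
#' dog gives 0.02 kgf; a 100 kg dog gives 0.1 kgf, which equals the device
#' resolution (100 g force).
#'
#' @param body_weight Dog body weight in kg (> 0).
#' @param threshold_fraction Fraction of body weight (default 0.001).
#' @return Threshold in kgf.
#' @examples
#' compute_threshold(20) # 0.02 kgf
#' @export
compute_threshold <- function(body_weight, threshold_fraction = 0.001) {
  if (!is.numeric(body_weight) || length(body_weight) != 1 || body_weight <= 0) {
    rlang::abort("body_weight must be a single positive number",
                 class = "leashwalk_parameter_error")
  }
  if (!is.numeric(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction >= 1) {
    rlang::abort("threshold_fraction must be in (0, 1)",
                 class = "leashwalk_parameter_error")
  }
  body_weight * threshold_fraction
}

#' Detect pull events on a prepared trace
#'
#' A pull event starts at the first sample where the filtered tension is
#' strictly above the threshold after a sample at or below it (or after a
#' prior event's end), and ends at the first sample where either the
#' tension drops strictly below the threshold or the discrete gradient
#' changes sign from negative to positive — the latter marks the onset of
#' a new pull within the same burst, and that sample starts a new event if
#' it is still above threshold. Ties at the threshold extend the event; a
#' zero gradient is not a sign change. Events still open at the end of the
#' walk are closed at the final sample and flagged `truncated`.
#'
#' Each event's initiator is attributed from the direction channel at the
#' sample immediately before onset: dog if `dir > margin`, handler if
#' `dir < -margin`, both otherwise (see [attribute_direction()]).
#'
#' @param trace A tarred (and normally smoothed) uniform `leash_trace`.
#' @param body_weight Dog body weight in kg.
#' @param threshold_fraction Threshold as a fraction of body weight
#'   (default 0.001).
#' @param direction_margin Attribution dead-band for the direction signal
#'   (default 0.1).
#' @return Tibble with one row per event: `start`, `end` (half-open 1-based
#'   sample indices), `start_s`, `end_s`, `peak_index`, `peak_kgf`,
#'   `direction` and `truncated`.
#' @export
detect_pull_events <- function(trace, body_weight, threshold_fraction = 0.001,
                               direction_margin = 0.1) {
  if (!is_tarred(trace)) {
    rlang::abort("trace must be tarred before event detection",
                 class = "leashwalk_contract_error")
  }
  thr <- compute_threshold(body_weight, threshold_fraction)
  f <- trace$force_kgf
  n <- length(f)
  starts <- integer(0); ends <- integer(0); truncated <- logical(0)
  start <- NA_integer_
  last_sign <- 0L
  i <- 1L
  while (i <= n) {
    if (is.na(start)) {
      if (f[i] > thr) {
        start <- i
        last_sign <- 0L
      }
      i <- i + 1L
    } else if (f[i] < thr) {
      starts <- c(starts, start); ends <- c(ends, i); truncated <- c(truncated, FALSE)
      start <- NA_integer_
      i <- i + 1L
    } else {
      g <- f[i] - f[i - 1L]
      if (g > 0 && last_sign < 0L) {
        # negative-to-positive gradient flip: burst splits here
        starts <- c(starts, start); ends <- c(ends, i); truncated <- c(truncated, FALSE)
        if (f[i] > thr) {
          start <- i
          last_sign <- 0L
        } else {
          start <- NA_integer_
        }
        i <- i + 1L
      } else {
        if (g != 0) last_sign <- if (g > 0) 1L else -1L
        i <- i + 1L
      }
    }
  }
  if (!is.na(start)) {
    starts <- c(starts, start); ends <- c(ends, n + 1L); truncated <- c(truncated, TRUE)
  }
  rate <- trace_meta(trace)$rate_hz
  ev <- tibble::tibble(start = starts, end = ends, truncated = truncated)
  ev <- dplyr::mutate(ev,
    peak_index = purrr::map2_int(start, end, function(s, e) {
      seg <- f[s:(e - 1L)]
      s + which.max(seg) - 1L
    }),
    peak_kgf = f[.data$peak_index],
    start_s = trace$time_s[start],
    end_s = ifelse(end <= n, trace$time_s[pmin(end, n)],
                   trace$time_s[n] + 1 / rate),
    direction = vapply(start, function(s)
      attribute_direction(s, trace, margin = direction_margin), character(1)))
  ev[, c("start", "end", "start_s", "end_s", "peak_index", "peak_kgf",
         "direction", "truncated")]
}

#' Attribute a pull event to dog, handler or both
#'
#' Reads the signed direction signal at the sample immediately prior to
#' event onset: dog-ward if it exceeds `margin`, handler-ward if below
#' `-margin`, otherwise attributed to both. An event starting at the very
#' first sample has no prior sample; the onset sample itself is used, with
#' a warning.
#'
#' @param start Event onset sample index (1-based).
#' @param trace The `leash_trace` the event was detected on.
#' @param margin Dead-band half-width in \[0, 1) (default 0.1).
#' @return `"dog"`, `"handler"` or `"both"`.
#' @export
attribute_direction <- function(start, trace, margin = 0.1) {
  if (!is.numeric(margin) || margin < 0 || margin >= 1) {
    rlang::abort("margin must be in [0, 1)",
                 class = "leashwalk_parameter_error")
  }
  if (start < 1 || start > nrow(trace)) {
    rlang::abort("event start outside trace", class = "leashwalk_contract_error")
  }
  if (start == 1L) {
    rlang::warn("event starts at the first sample; using its own direction value")
    d <- trace$dir[1L]
  } else {
    d <- trace$dir[start - 1L]
  }
  if (d > margin) "dog" else if (d < -margin) "handler" else "both"
}

#' Walk-level tension metrics
#'
#' Computes the eight walk outcomes from a detected event table: net,
#' dog-attributed and handler-attributed maximal and mean peak tensions
#' (NT/DT/HT max and mean, kgf) and the dog and handler pulling
#' frequencies (DPF/HPF, events per second of walking). Mean tensions
#' average the event peak forces above threshold; events attributed to
#' both ends contribute to the net metrics and the event count only.
#' A samplewise mean of the trace is reported as an auxiliary diagnostic.
#'
#' @param events Event tibble from [detect_pull_events()].
#' @param trace The trace the events were detected on.
#' @return One-row tibble: `session_id`, `duration_s`, `n_events`, `n_dog`,
#'   `n_handler`, `n_both`, `nt_max`, `nt_mean`, `dt_max`, `dt_mean`,
#'   `ht_max`, `ht_mean`, `dpf`, `hpf`, `mean_tension_samplewise`.
#' @export
summarize_walk <- function(events, trace) {
  n <- nrow(trace)
  rate <- trace_meta(trace)$rate_hz
  duration <- n / rate
  if (n == 0 || duration <= 0) {
    rlang::abort("zero-duration walk", class = "leashwalk_empty_error")
  }
  peak_of <- function(x) if (length(x)) max(x) else 0
  mean_of <- function(x) if (length(x)) mean(x) else 0
  dog <- events$peak_kgf[events$direction == "dog"]
  hand <- events$peak_kgf[events$direction == "handler"]
  both <- events$peak_kgf[events$direction == "both"]
  tibble::tibble(
    session_id = trace_session(trace),
    duration_s = duration,
    n_events = nrow(events),
    n_dog = length(dog),
    n_handler = length(hand),
    n_both = length(both),
    nt_max = peak_of(events$peak_kgf),
    nt_mean = mean_of(events$peak_kgf),
    dt_max = peak_of(dog),
    dt_mean = mean_of(dog),
    ht_max = peak_of(hand),
    ht_mean = mean_of(hand),
    dpf = length(dog) / duration,
    hpf = length(hand) / duration,
    mean_tension_samplewise = mean(trace$force_kgf))
}

#' One-call walk metrics from a raw walk segment
#'
#' Chains [prepare_walk()], [detect_pull_events()] and [summarize_walk()].
#'
#' @inheritParams detect_pull_events
#' @inheritParams prepare_walk
#' @return As [summarize_walk()].
#' @export
walk_metrics <- function(trace, body_weight, threshold_fraction = 0.001,
                         direction_margin = 0.1, rate = 10, window = 3) {
  prepped <- prepare_walk(trace, rate = rate, window = window)
  ev <- detect_pull_events(prepped, body_weight,
                           threshold_fraction = threshold_fraction,
                           direction_margin = direction_margin)
  summarize_walk(ev, prepped)
}
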