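# Independent brute-force pull-event scanner, written against the event
# definition itself (threshold crossings + negative-to-positive gradient
# splits) and kept deliberately separate from the package implementation.
# Returns a data.frame of half-open [start, end) sample intervals with the
# peak of each event.
oracle_scan_events <- function(f, thr) {
  n <- length(f)
  out <- data.frame(start = integer(), end = integer(), peak = numeric())
  close_event <- function(s, e) {
    seg <- f[s:(e - 1L)]
    out[nrow(out) + 1L, ] <<- list(s, e, max(seg))
  }
  open_at <- NA_integer_
  neg_seen <- FALSE # a strictly negative gradient observed since event start
  for (i in seq_len(n)) {
    if (is.na(open_at)) {
      if (f[i] > thr) {
        open_at <- i
        neg_seen <- FALSE
      }
      next
    }
    if (f[i] < thr) {
      close_event(open_at, i)
      open_at <- NA_integer_
      next
    }
    step <- f[i] - f[i - 1L]
    if (step > 0) {
      if (neg_seen) {
        close_event(open_at, i)
        if (f[i] > thr) {
          open_at <- i
          neg_seen <- FALSE
        } else {
          open_at <- NA_integer_
        }
      }
    } else if (step < 0) {
      neg_seen <- TRUE
    }
  }
  if (!is.na(open_at)) close_event(open_at, n + 1L)
  out
}

# Build a processed (uniform/tarred/smoothed) trace directly from a force
# vector at 10 Hz, bypassing the signal-prep chain where a test wants full
# control of the detection input.
processed_trace <- function(force, dir = rep(0, length(force)), window = 0L) {
  leash_trace(seq_along(force) / 10, force, dir,
              uniform = TRUE, tarred = TRUE, smoothed = window)
}

# A noisy random trace rich in threshold crossings and gradient flips,
# for detector-vs-oracle equivalence sweeps.
random_rough_trace <- function(n = 1000, thr = 0.02, seed = 1) {
  withr::with_seed(seed, {
    base <- abs(stats::rnorm(n, 0, 3 * thr))
    bursts <- leashwalk::random_pull_scenario(
      5, n / 10, peak_range = c(5 * thr, 50 * thr))
    f <- base
    for (i in seq_len(nrow(bursts))) {
      i0 <- round(bursts$start_s[i] * 10) + 1
      k <- max(3, round(bursts$duration_s[i] * 10))
      idx <- i0:min(i0 + k - 1, n)
      s <- seq(0, 1, length.out = length(idx))
      f[idx] <- f[idx] + bursts$peak_kgf[i] * sin(pi * s)^2
    }
    f <- f - min(f)
    processed_trace(f)
  })
}
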