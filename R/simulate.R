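#' @importFrom rlang %||% .data
NULL

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# parametric burst templates on s in [0, 1], scaled to `peak`
pull_shape <- function(shape, k, peak) {
  s <- seq(0, 1, length.out = k)
  switch(shape,
    triangle = peak * (1 - abs(2 * s - 1)),
    hump = peak * sin(pi * s)^2,
    # two local maxima with a valley at half the peak, to exercise the
    # gradient-sign split rule; stays well above any realistic threshold
    double_hump = peak * (0.5 * sin(pi * s)^2 + 0.5 * sin(2 * pi * s)^2),
    # trapezoid used for sync pulls: ~15% rise/fall, flat top
    plateau = peak * pmin(1, s / 0.15, (1 - s) / 0.15),
    rlang::abort(paste0("unknown pull shape: ", shape),
                 class = "leashwalk_parameter_error"))
}

#' Random planted-pull scenario
#'
#' Draws a non-overlapping set of pull events for [simulate_walk()]:
#' uniformly spaced slots with jittered onsets, peak forces, shapes and
#' directions sampled from the supplied menus.
#'
#' @param n_events Number of planted events.
#' @param duration_s Walk duration in seconds.
#' @param peak_range Peak force range in kgf (default 0.3--3).
#' @param event_duration_range Event length range in seconds (default 1--3).
#' @param shapes Shape menu (default all three templates).
#' @param directions Direction menu with replacement (default dog/handler/
#'   both equally likely via sampling).
#' @param seed Optional RNG seed.
#' @return Events tibble for [simulate_walk()].
#' @export
random_pull_scenario <- function(n_events, duration_s,
                                 peak_range = c(0.3, 3),
                                 event_duration_range = c(1, 3),
                                 shapes = c("triangle", "hump", "double_hump"),
                                 directions = c("dog", "handler", "both"),
                                 seed = NULL) {
  with_optional_seed(seed, {
    if (n_events == 0) {
      return(tibble::tibble(start_s = numeric(), duration_s = numeric(),
                            peak_kgf = numeric(), direction = character(),
                            shape = character()))
    }
    slot <- duration_s / n_events
    lo_len <- min(event_duration_range[1], slot * 0.5)
    hi_len <- max(lo_len, min(event_duration_range[2], slot * 0.6))
    len <- stats::runif(n_events, lo_len, hi_len)
    start <- (seq_len(n_events) - 1) * slot +
      stats::runif(n_events, 0.05 * slot, pmax(0.06 * slot, slot * 0.9 - len))
    tibble::tibble(
      start_s = start,
      duration_s = len,
      peak_kgf = stats::runif(n_events, peak_range[1], peak_range[2]),
      direction = sample(directions, n_events, replace = TRUE),
      shape = sample(shapes, n_events, replace = TRUE))
  })
}

#' Simulate a leash-tension recording with planted pull events
#'
#' Emulates the device output: a 10 Hz force trace riding on a baseline
#' offset, with parametric pull bursts (triangle, hump or double-hump
#' templates) added at planted times, Gaussian sensor noise, and a signed
#' direction channel set to +1 (dog), -1 (handler) or 0 (both) from
#' shortly before each burst's onset through its end. Optionally prepends
#' the recording protocol: a 10 s vertical calibration hold and three 3 s
#' synchronization pulls separated by rests.
#'
#' The returned ground truth lists one row per event the detector should
#' find: a double-hump burst contributes two rows because its interior
#' negative-to-positive gradient flip splits it.
#'
#' @param duration_s Walk duration in seconds (default 300, the designated
#'   pathway takes about five minutes).
#' @param body_weight Dog body weight in kg (default 20).
#' @param events Planted events tibble (`start_s`, `duration_s`,
#'   `peak_kgf`, `direction`, `shape`) or NULL for an event-free walk.
#' @param baseline_kgf Baseline offset in kgf (default 1, removed by
#'   taring).
#' @param noise_sd Gaussian noise SD in kgf (default 0).
#' @param dir_lead_s Seconds before onset at which the direction channel
#'   switches on (default 0.3).
#' @param include_protocol Prepend calibration hold and sync pulls.
#' @param sync_peak_kgf Sync pull amplitude (default 8 kgf).
#' @param rate_hz Sampling rate (default 10).
#' @param jitter_frac Optional uniform timestamp jitter as a fraction of
#'   the sample interval (default 0; at most 0.45 to keep times
#'   monotone), exercising interpolation.
#' @param session_id Session identifier.
#' @param seed Optional RNG seed; the result is deterministic given it.
#' @return List with `trace` (a raw `leash_trace`) and `truth` (tibble of
#'   expected events: `start_s`, `end_s`, `peak_kgf`, `direction`,
#'   `shape`, `planted_id`).
#' @export
simulate_walk <- function(duration_s = 300, body_weight = 20, events = NULL,
                          baseline_kgf = 1, noise_sd = 0, dir_lead_s = 0.3,
                          include_protocol = FALSE, sync_peak_kgf = 8,
                          rate_hz = 10, jitter_frac = 0,
                          session_id = "walk", seed = NULL) {
  with_optional_seed(seed, {
    if (is.null(events)) {
      events <- random_pull_scenario(0, duration_s)
    }
    events <- tibble::as_tibble(events)
    if (nrow(events) > 1) {
      o <- order(events$start_s)
      events <- events[o, ]
      if (any(events$start_s[-1] < (events$start_s + events$duration_s)[-nrow(events)])) {
        rlang::abort("planted events overlap", class = "leashwalk_scenario_error")
      }
    }
    if (any(events$start_s < 0) ||
        any(events$start_s + events$duration_s > duration_s)) {
      rlang::abort("planted events outside the walk",
                   class = "leashwalk_scenario_error")
    }
    dt <- 1 / rate_hz
    n_walk <- round(duration_s * rate_hz)
    force <- rep(baseline_kgf, n_walk)
    dir <- rep(0, n_walk)
    truth <- list()
    for (i in seq_len(nrow(events))) {
      i0 <- round(events$start_s[i] * rate_hz) + 1L
      k <- max(3L, round(events$duration_s[i] * rate_hz))
      idx <- i0:(min(i0 + k - 1L, n_walk))
      shp <- pull_shape(events$shape[i], length(idx), events$peak_kgf[i])
      force[idx] <- force[idx] + shp
      d0 <- max(1L, i0 - round(dir_lead_s * rate_hz))
      dval <- switch(events$direction[i], dog = 1, handler = -1, both = 0,
                     rlang::abort("direction must be dog/handler/both",
                                  class = "leashwalk_scenario_error"))
      dir[d0:max(idx)] <- dval
      t_start <- (i0 - 1L) * dt
      t_end <- max(idx) * dt
      if (events$shape[i] == "double_hump") {
        mid <- t_start + (t_end - t_start) / 2
        truth[[i]] <- tibble::tibble(
          start_s = c(t_start, mid), end_s = c(mid, t_end),
          peak_kgf = rep(0.75 * events$peak_kgf[i], 2),
          direction = events$direction[i], shape = events$shape[i],
          planted_id = i)
      } else {
        truth[[i]] <- tibble::tibble(
          start_s = t_start, end_s = t_end,
          peak_kgf = events$peak_kgf[i],
          direction = events$direction[i], shape = events$shape[i],
          planted_id = i)
      }
    }
    truth <- if (length(truth)) dplyr::bind_rows(truth) else
      tibble::tibble(start_s = numeric(), end_s = numeric(),
                     peak_kgf = numeric(), direction = character(),
                     shape = character(), planted_id = integer())
    if (include_protocol) {
      hold <- rep(0.8, 10 * rate_hz)
      rest <- rep(baseline_kgf, round(1.5 * rate_hz))
      pulse <- pull_shape("plateau", 3 * rate_hz, sync_peak_kgf) + baseline_kgf
      pre <- c(hold, rest, pulse, rest, pulse, rest, pulse, rest)
      offset_s <- length(pre) * dt
      force <- c(pre, force)
      dir <- c(rep(0, length(pre)), dir)
      truth$start_s <- truth$start_s + offset_s
      truth$end_s <- truth$end_s + offset_s
    }
    n <- length(force)
    if (noise_sd > 0) force <- force + stats::rnorm(n, 0, noise_sd)
    force <- pmin(pmax(force, 0), 100)
    t <- (seq_len(n) - 1L) * dt
    if (jitter_frac > 0) {
      if (jitter_frac > 0.45) {
        rlang::abort("jitter_frac must be <= 0.45",
                     class = "leashwalk_parameter_error")
      }
      t <- t + c(0, stats::runif(n - 2L, -jitter_frac * dt, jitter_frac * dt), 0)
    }
    list(trace = leash_trace(t, force, dir, session_id = session_id,
                             rate_hz = rate_hz),
         truth = truth)
  })
}

#' Simulate a coded behavior log
#'
#' Point behaviors arrive as homogeneous Poisson processes at the stated
#' rates; state behaviors alternate on/off intervals with exponential
#' durations calibrated so the expected fraction of time in the behavior
#' matches the target percentage.
#'
#' @param point_rates Named numeric vector, events per second per point
#'   behavior.
#' @param state_fractions Named numeric vector, target percent of walk
#'   time (0--100) per state behavior.
#' @param duration_s Walk duration in seconds.
#' @param mean_bout_s Mean on-bout duration for state behaviors (default
#'   4 s).
#' @param session_id Session identifier.
#' @param catalog Ethogram catalog.
#' @param seed Optional RNG seed.
#' @return A `behavior_log`.
#' @export
simulate_behavior_log <- function(point_rates = NULL, state_fractions = NULL,
                                  duration_s = 300, mean_bout_s = 4,
                                  session_id = "walk",
                                  catalog = ethogram_catalog(), seed = NULL) {
  with_optional_seed(seed, {
    point_rates <- point_rates %||% numeric()
    state_fractions <- state_fractions %||% numeric()
    if (any(point_rates < 0)) {
      rlang::abort("rates must be non-negative",
                   class = "leashwalk_parameter_error")
    }
    if (any(state_fractions < 0 | state_fractions > 100)) {
      rlang::abort("state fractions must be percentages in [0, 100]",
                   class = "leashwalk_parameter_error")
    }
    rows <- list()
    for (b in names(point_rates)) {
      n <- stats::rpois(1, point_rates[[b]] * duration_s)
      if (n > 0) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          behavior = b, start_s = sort(stats::runif(n, 0, duration_s)),
          end_s = NA_real_)
      }
    }
    for (b in names(state_fractions)) {
      p <- state_fractions[[b]] / 100
      if (p <= 0) next
      mean_off <- if (p >= 1) 0 else mean_bout_s * (1 - p) / p
      t <- stats::rexp(1, 1 / max(mean_off, 1e-9))
      while (t < duration_s) {
        on <- stats::rexp(1, 1 / mean_bout_s)
        e <- min(t + on, duration_s)
        if (e > t) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            behavior = b, start_s = t, end_s = e)
        }
        t <- e + stats::rexp(1, 1 / max(mean_off, 1e-9))
      }
    }
    events <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(behavior = character(), start_s = numeric(),
                     end_s = numeric())
    behavior_log(events, duration_s = duration_s, session_id = session_id,
                 catalog = catalog)
  })
}

#' Simulate exit-questionnaire responses
#'
#' Generates 13 items from a discretized latent two-factor model: each
#' respondent draws latent factor levels for H and D; member items load on
#' their factor with the configured loading, pick up independent noise,
#' and are rounded and clamped to the 1--5 scale. Items in a spec's
#' reversed set are stored negatively worded (reflected), so reverse
#' coding at scoring time recovers the factor.
#'
#' @param n Number of respondents.
#' @param factor_means Named numeric, latent means on the 1--5 scale
#'   (default `c(h = 3.5, d = 3.5)`).
#' @param factor_sd Latent factor SD (default 0.8).
#' @param loading Item-factor loading in \[0, 1\] (default 0.8).
#' @param specs Factor specs (default [default_factor_specs()]).
#' @param seed Optional RNG seed.
#' @return Tibble with columns `q1`..`q13`.
#' @export
simulate_questionnaire <- function(n, factor_means = c(h = 3.5, d = 3.5),
                                   factor_sd = 0.8, loading = 0.8,
                                   specs = default_factor_specs(),
                                   seed = NULL) {
  if (loading < 0 || loading > 1) {
    rlang::abort("loading must be in [0, 1]",
                 class = "leashwalk_parameter_error")
  }
  with_optional_seed(seed, {
    n_items <- specs[[1]]$n_items
    items <- matrix(NA_real_, nrow = n, ncol = n_items)
    for (nm in names(specs)) {
      spec <- specs[[nm]]
      mu <- factor_means[[nm]]
      f <- stats::rnorm(n, mu, factor_sd)
      noise_sd <- if (loading > 0 && loading < 1) {
        factor_sd * sqrt(1 - loading^2) / loading
      } else {
        0
      }
      for (j in spec$items) {
        v <- if (loading == 0) stats::rnorm(n, mu, factor_sd) else
          f + stats::rnorm(n, 0, noise_sd)
        v <- pmin(pmax(round(v), 1), 5)
        if (j %in% spec$reversed) v <- 6 - v
        items[, j] <- v
      }
    }
    # items not claimed by any factor: uniform filler
    for (j in which(apply(items, 2, function(x) all(is.na(x))))) {
      items[, j] <- sample(1:5, n, replace = TRUE)
    }
    colnames(items) <- paste0("q", seq_len(n_items))
    tibble::as_tibble(items)
  })
}

#' Simulate a whole cohort with planted personality effects
#'
#' Emulates the study's crossed structure: volunteers (with NEO-FFI
#' domain scores drawn from the cohort's observed means and SDs,
#' truncated to the instrument range) repeatedly walk dogs whose
#' behavioral level does not exceed the volunteer's training level.
#' Outcomes are generated on the transformed analysis scale as a linear
#' combination of planted fixed effects plus volunteer and dog random
#' intercepts and residual noise, then back-transformed to the natural
#' scale. The returned truth record carries every planted coefficient
#' and variance component.
#'
#' @param n_volunteers,n_dogs,n_walks Cohort sizes (defaults 74, 111,
#'   370 — the study's).
#' @param effects Named list: `effects[[outcome]][[predictor]] = beta` on
#'   the transformed scale. Default plants nothing.
#' @param outcome_transforms Named list of `transform_spec`s per outcome;
#'   default a single log10 outcome `nt_max`.
#' @param intercepts Named numeric of transformed-scale intercepts
#'   (default 0.3 for `nt_max`, i.e. about 2 kgf).
#' @param sd_volunteer,sd_dog Random-intercept SDs on the transformed
#'   scale (defaults 0.15 each).
#' @param sd_resid Residual SD on the transformed scale (default 0.35).
#' @param seed Optional RNG seed.
#' @return List with `data` (tibble, one row per walk: ids, personality,
#'   demographics, outcomes on natural and transformed scales) and
#'   `truth` (planted betas, intercepts and variance components).
#' @export
simulate_cohort <- function(n_volunteers = 74, n_dogs = 111, n_walks = 370,
                            effects = list(),
                            outcome_transforms = list(
                              nt_max = transform_spec("log10")),
                            intercepts = NULL,
                            sd_volunteer = 0.15, sd_dog = 0.15,
                            sd_resid = 0.35, seed = NULL) {
  if (n_walks < n_volunteers) {
    rlang::abort("need at least one walk per volunteer",
                 class = "leashwalk_scenario_error")
  }
  with_optional_seed(seed, {
    personality_means <- c(neuroticism = 24.97, extraversion = 27.24,
                           openness = 29.59, agreeableness = 34.35,
                           conscientiousness = 30.54)
    personality_sds <- c(neuroticism = 8.80, extraversion = 7.77,
                         openness = 6.41, agreeableness = 5.97,
                         conscientiousness = 7.23)
    volunteers <- tibble::tibble(
      volunteer_id = sprintf("V%03d", seq_len(n_volunteers)),
      volunteer_age = round(stats::rnorm(n_volunteers, 28, 14.6)),
      training_level = sample(2:4, n_volunteers, replace = TRUE,
                              prob = c(0.4, 0.4, 0.2)))
    volunteers$volunteer_age <- pmax(volunteers$volunteer_age, 18)
    for (p in names(personality_means)) {
      volunteers[[p]] <- pmin(pmax(
        round(stats::rnorm(n_volunteers, personality_means[[p]],
                           personality_sds[[p]])), 0), 48)
    }
    dogs <- tibble::tibble(
      dog_id = sprintf("D%03d", seq_len(n_dogs)),
      behavioral_level = sample(1:4, n_dogs, replace = TRUE,
                                prob = c(0.15, 0.4, 0.3, 0.15)),
      dog_weight = round(exp(stats::rnorm(n_dogs, log(20), 0.35)), 1),
      dog_age = round(stats::runif(n_dogs, 0.5, 10), 1),
      dog_sex = sample(c(0, 1), n_dogs, replace = TRUE))
    # every volunteer walks at least once; dogs drawn among compatible levels
    vol_idx <- c(seq_len(n_volunteers),
                 sample(seq_len(n_volunteers), n_walks - n_volunteers,
                        replace = TRUE))
    vol_idx <- sample(vol_idx)
    walks <- volunteers[vol_idx, ]
    walks$dog_row <- vapply(walks$training_level, function(lv) {
      ok <- which(dogs$behavioral_level <= lv)
      ok[sample.int(length(ok), 1)]
    }, integer(1))
    walks <- dplyr::bind_cols(walks, dogs[walks$dog_row, ])
    walks$dog_row <- NULL
    walks$session_id <- sprintf("W%04d", seq_len(n_walks))
    u_vol <- stats::rnorm(n_volunteers, 0, sd_volunteer)
    u_dog <- stats::rnorm(n_dogs, 0, sd_dog)
    names(u_vol) <- volunteers$volunteer_id
    names(u_dog) <- dogs$dog_id
    default_intercepts <- stats::setNames(rep(0.3, length(outcome_transforms)),
                                          names(outcome_transforms))
    intercepts <- intercepts %||% default_intercepts
    for (oc in names(outcome_transforms)) {
      eta <- rep(intercepts[[oc]] %||% 0, n_walks)
      for (pred in names(effects[[oc]] %||% list())) {
        eta <- eta + effects[[oc]][[pred]] * walks[[pred]]
      }
      eta <- eta + u_vol[walks$volunteer_id] + u_dog[walks$dog_id]
      if (sd_resid > 0) eta <- eta + stats::rnorm(n_walks, 0, sd_resid)
      walks[[paste0(oc, "_tr")]] <- eta
      walks[[oc]] <- back_transform(eta, outcome_transforms[[oc]])
    }
    first <- c("session_id", "volunteer_id", "dog_id")
    walks <- walks[, c(first, setdiff(names(walks), first))]
    list(data = walks,
         truth = list(effects = effects, intercepts = intercepts,
                      outcome_transforms = outcome_transforms,
                      sd_volunteer = sd_volunteer, sd_dog = sd_dog,
                      sd_resid = sd_resid))
  })
}
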