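#' The shipped ethogram catalog
#'
#' The controlled vocabulary used for video coding: nine canine behaviors,
#' seven human verbal cues and three human body-language behaviors, each a
#' point event (counted) or a state event (timed interval).
#'
#' @return Tibble with columns `behavior`, `category`
#'   (`canine`/`human_verbal`/`human_body`) and `type` (`point`/`state`).
#' @export
ethogram_catalog <- function() {
  tibble::tribble(
    ~behavior,            ~category,      ~type,
    "track",              "canine",       "state",
    "sniff",              "canine",       "state",
    "eliminate_mark",     "canine",       "point",
    "shake",              "canine",       "point",
    "pant",               "canine",       "state",
    "gaze",               "canine",       "point",
    "lip_lick",           "canine",       "point",
    "tail_wag",           "canine",       "state",
    "tail_high",          "canine",       "state",
    "sit",                "human_verbal", "point",
    "command",            "human_verbal", "point",
    "attention_seeking",  "human_verbal", "point",
    "high_pitched_voice", "human_verbal", "point",
    "praise",             "human_verbal", "point",
    "negative_verbal_cue","human_verbal", "point",
    "communication",      "human_verbal", "point",
    "gestural",           "human_body",   "point",
    "physical_contact",   "human_body",   "point",
    "food_reward",        "human_body",   "point")
}

#' Construct a behavior log
#'
#' A behavior log holds the coded events of one walk: point events carry a
#' single timestamp (`start_s`, `end_s = NA`); state events carry an
#' interval. All behaviors must exist in the catalog with a matching type
#' and all times must lie within `[0, duration_s]`.
#'
#' @param events Tibble/data frame with columns `behavior`, `start_s` and
#'   optionally `end_s` (NA for point events). A `type` column, if present,
#'   is checked against the catalog.
#' @param duration_s Walk duration in seconds (> 0).
#' @param session_id Session identifier.
#' @param catalog Ethogram catalog tibble.
#' @return A tibble of class `behavior_log` with columns `behavior`, `type`,
#'   `start_s`, `end_s`.
#' @export
behavior_log <- function(events, duration_s, session_id = "session",
                         catalog = ethogram_catalog()) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    rlang::abort("duration_s must be positive",
                 class = "leashwalk_parameter_error")
  }
  events <- tibble::as_tibble(events)
  if (nrow(events) == 0) {
    events <- tibble::tibble(behavior = character(), start_s = numeric(),
                             end_s = numeric())
  }
  if (!"end_s" %in% names(events)) events$end_s <- NA_real_
  unknown <- setdiff(unique(events$behavior), catalog$behavior)
  if (length(unknown)) {
    rlang::abort(paste0("behavior(s) not in catalog: ",
                        paste(unknown, collapse = ", ")),
                 class = "leashwalk_catalog_error")
  }
  type <- catalog$type[match(events$behavior, catalog$behavior)]
  if ("type" %in% names(events) && any(events$type != type)) {
    rlang::abort("event type disagrees with catalog",
                 class = "leashwalk_catalog_error")
  }
  events$type <- type
  is_state <- events$type == "state"
  bad_time <- events$start_s < 0 | events$start_s > duration_s |
    (is_state & (is.na(events$end_s) | events$end_s <= events$start_s |
                   events$end_s > duration_s)) |
    (!is_state & !is.na(events$end_s))
  if (any(bad_time)) {
    rlang::abort(sprintf("%d event(s) with invalid times", sum(bad_time)),
                 class = "leashwalk_format_error")
  }
  out <- events[, c("behavior", "type", "start_s", "end_s")]
  attr(out, "duration_s") <- duration_s
  attr(out, "session_id") <- as.character(session_id)
  class(out) <- c("behavior_log", class(out))
  out
}

log_duration <- function(log) attr(log, "duration_s", exact = TRUE)

#' Read / write a behavior log CSV
#'
#' Dialect `behavior,type,start_s,end_s`, with `end_s` empty for point
#' events — the shape of common observation-software exports.
#'
#' @param path CSV path.
#' @param duration_s Walk duration in seconds.
#' @inheritParams behavior_log
#' @return A `behavior_log`.
#' @export
read_behavior_log <- function(path, duration_s, session_id = NULL,
                              catalog = ethogram_catalog()) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  behavior_log(df, duration_s = duration_s,
               session_id = session_id %||% sub("\\.[^.]*$", "", basename(path)),
               catalog = catalog)
}

#' @rdname read_behavior_log
#' @param log A `behavior_log`.
#' @export
write_behavior_log <- function(log, path) {
  readr::write_csv(tibble::as_tibble(log), path, progress = FALSE)
  invisible(path)
}

# merge overlapping [start, end) intervals; returns total covered time
merged_state_time <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  total <- 0; cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e) {
      cur_e <- max(cur_e, end[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- start[i]; cur_e <- end[i]
    }
  }
  total + (cur_e - cur_s)
}

#' Summarise a behavior log into rates and time fractions
#'
#' Point behaviors are reported as events per second (count / walk
#' duration); state behaviors as the percentage of walk time spent in the
#' behavior, with overlapping same-behavior intervals merged before
#' summing. Grouped totals (`total_verbal_cue`, `total_body_language`) sum
#' the member point rates of the human-verbal and human-body categories.
#'
#' @param log A `behavior_log`.
#' @param catalog Ethogram catalog tibble.
#' @return Tibble with columns `behavior`, `category`, `measure`
#'   (`"rate_per_s"` or `"pct_time"`) and `value`; every catalog behavior
#'   appears (zero when unobserved), plus the two total rows.
#' @export
summarize_behaviors <- function(log, catalog = ethogram_catalog()) {
  dur <- log_duration(log)
  if (is.null(dur) || dur <= 0) {
    rlang::abort("behavior log has no positive duration",
                 class = "leashwalk_empty_error")
  }
  unknown <- setdiff(unique(log$behavior), catalog$behavior)
  if (length(unknown)) {
    rlang::abort(paste0("behavior(s) not in catalog: ",
                        paste(unknown, collapse = ", ")),
                 class = "leashwalk_catalog_error")
  }
  per <- catalog |>
    dplyr::mutate(value = purrr::map2_dbl(.data$behavior, .data$type,
      function(b, ty) {
        rows <- log[log$behavior == b, , drop = FALSE]
        if (ty == "point") {
          nrow(rows) / dur
        } else if (nrow(rows) == 0) {
          0
        } else {
          100 * merged_state_time(rows$start_s, rows$end_s) / dur
        }
      }),
      measure = ifelse(.data$type == "point", "rate_per_s", "pct_time")) |>
    dplyr::select("behavior", "category", "measure", "value")
  totals <- tibble::tibble(
    behavior = c("total_verbal_cue", "total_body_language"),
    category = c("human_verbal", "human_body"),
    measure = "rate_per_s",
    value = c(sum(per$value[per$category == "human_verbal"]),
              sum(per$value[per$category == "human_body"])))
  dplyr::bind_rows(per, totals)
}

#' Discretize a behavior log onto fixed-width time bins
#'
#' Supports agreement statistics on continuously coded records: each bin
#' `[k*bin, (k+1)*bin)` receives one label — the behavior (from
#' `behaviors`) with the greatest presence in the bin (covered time for
#' state events, event count for point events), `"none"` if nothing is
#' present. Ties break deterministically by catalog order. Point events on
#' a bin boundary belong to the later bin (half-open convention).
#'
#' @param log A `behavior_log`.
#' @param bin Bin width in seconds (> 0, and no longer than the walk).
#' @param behaviors Behaviors to consider; default all in the catalog.
#' @param catalog Ethogram catalog tibble.
#' @return Character vector with one label per bin.
#' @export
bin_timeline <- function(log, bin = 1, behaviors = NULL,
                         catalog = ethogram_catalog()) {
  dur <- log_duration(log)
  if (!is.numeric(bin) || bin <= 0) {
    rlang::abort("bin must be positive", class = "leashwalk_parameter_error")
  }
  if (bin > dur) {
    rlang::abort("bin width exceeds walk duration",
                 class = "leashwalk_parameter_error")
  }
  behaviors <- behaviors %||% catalog$behavior
  behaviors <- catalog$behavior[catalog$behavior %in% behaviors] # catalog order
  n_bins <- floor(dur / bin + 1e-9)
  edges <- (seq_len(n_bins) - 1) * bin
  score <- matrix(0, nrow = n_bins, ncol = length(behaviors),
                  dimnames = list(NULL, behaviors))
  for (i in seq_len(nrow(log))) {
    b <- log$behavior[i]
    if (!b %in% behaviors) next
    if (log$type[i] == "point") {
      k <- floor(log$start_s[i] / bin) + 1
      if (k >= 1 && k <= n_bins) score[k, b] <- score[k, b] + 1
    } else {
      for (k in seq_len(n_bins)) {
        lo <- edges[k]; hi <- edges[k] + bin
        cover <- min(hi, log$end_s[i]) - max(lo, log$start_s[i])
        if (cover > 0) score[k, b] <- score[k, b] + cover
      }
    }
  }
  labels <- apply(score, 1, function(s) {
    if (all(s == 0)) "none" else behaviors[which.max(s)]
  })
  as.character(labels)
}

#' Cohen's kappa for two categorical sequences
#'
#' Chance-corrected agreement, \eqn{\kappa = (p_o - p_e) / (1 - p_e)},
#' with expected agreement \eqn{p_e} from the marginal label frequencies
#' of each sequence. If both sequences are constant on the same label,
#' \eqn{p_e = 1} and the degenerate value 1 is returned (perfect agreement
#' convention). Symmetric in its arguments and invariant to label
#' renaming.
#'
#' @param seq_a,seq_b Equal-length categorical vectors (length >= 1).
#' @return Kappa in \[-1, 1\].
#' @examples
#' cohens_kappa(c("A", "A", "B", "B"), c("A", "B", "A", "B")) # 0
#' @export
cohens_kappa <- function(seq_a, seq_b) {
  if (length(seq_a) != length(seq_b)) {
    rlang::abort("sequences must have equal length",
                 class = "leashwalk_parameter_error")
  }
  if (length(seq_a) == 0) {
    rlang::abort("sequences must be non-empty",
                 class = "leashwalk_empty_error")
  }
  seq_a <- as.character(seq_a); seq_b <- as.character(seq_b)
  labs <- union(seq_a, seq_b)
  n <- length(seq_a)
  po <- mean(seq_a == seq_b)
  pa <- tabulate(match(seq_a, labs), length(labs)) / n
  pb <- tabulate(match(seq_b, labs), length(labs)) / n
  pe <- sum(pa * pb)
  if (1 - pe < .Machine$double.eps) {
    return(if (po == 1) 1 else 0)
  }
  (po - pe) / (1 - pe)
}
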