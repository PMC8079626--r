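#' Reverse-score a Likert item
#'
#' Half of the 13 exit-questionnaire items are negatively worded; their
#' scores are reflected before averaging: `scale_max + 1 - x`. The map is
#' an involution (applying it twice is the identity) and 3 is its fixed
#' point on a 5-point scale.
#'
#' @param x Item value(s), each in `1..scale_max`.
#' @param scale_max Top of the response scale (default 5).
#' @return Reversed value(s).
#' @export
reverse_score <- function(x, scale_max = 5) {
  if (any(!is.finite(x)) || any(x < 1 | x > scale_max)) {
    rlang::abort(sprintf("item values must lie in [1, %d]", scale_max),
                 class = "leashwalk_parameter_error")
  }
  scale_max + 1 - x
}

#' Factor specification for questionnaire scoring
#'
#' Which of the 13 items belong to a factor and which of those are
#' negatively worded (reverse-coded before averaging).
#'
#' @param name Factor name.
#' @param items 1-based item indices belonging to the factor.
#' @param reversed Subset of `items` to reverse-code.
#' @param n_items Total items on the instrument (default 13).
#' @return A list of class `factor_spec`.
#' @export
factor_spec <- function(name, items, reversed = integer(), n_items = 13L) {
  items <- as.integer(items); reversed <- as.integer(reversed)
  if (length(items) == 0 || any(items < 1) || any(items > n_items) ||
      anyDuplicated(items)) {
    rlang::abort(sprintf("items must be distinct indices in 1..%d", n_items),
                 class = "leashwalk_parameter_error")
  }
  if (!all(reversed %in% items)) {
    rlang::abort("reversed items must be a subset of the factor's items",
                 class = "leashwalk_parameter_error")
  }
  structure(list(name = name, items = items, reversed = reversed,
                 n_items = n_items), class = "factor_spec")
}

#' Default two-factor mapping for the exit questionnaire
#'
#' The instrument's published description names the two factors — handler
#' satisfaction (H) and perception of the dog (D) — but not the item-level
#' loadings, so this shipped mapping is an assumption derived from item
#' wording and is configurable: H covers the handler-experience items with
#' the negatively worded ones reversed, D the dog-perception items
#' likewise. Treat it as a sensible default, not ground truth.
#'
#' @return Named list of two `factor_spec`s (`h`, `d`).
#' @export
default_factor_specs <- function() {
  list(h = factor_spec("h", items = c(2, 3, 4, 5, 6, 10, 11),
                       reversed = c(2, 4, 6, 10)),
       d = factor_spec("d", items = c(1, 7, 8, 9, 12, 13),
                       reversed = c(7, 8, 12)))
}

#' Score one response against a factor spec
#'
#' Reverse-codes the spec's negatively worded items, then returns the
#' arithmetic mean of the factor's member items; always in \[1, 5\].
#'
#' @param items Numeric vector of the 13 item responses (1--5).
#' @param spec A `factor_spec`.
#' @param scale_max Top of the response scale (default 5).
#' @return Mean factor score.
#' @export
score_factor <- function(items, spec, scale_max = 5) {
  if (length(items) != spec$n_items) {
    rlang::abort(sprintf("expected %d items", spec$n_items),
                 class = "leashwalk_parameter_error")
  }
  if (any(!is.finite(items)) || any(items < 1 | items > scale_max)) {
    rlang::abort(sprintf("item values must lie in [1, %d]", scale_max),
                 class = "leashwalk_parameter_error")
  }
  vals <- items
  vals[spec$reversed] <- reverse_score(vals[spec$reversed], scale_max)
  mean(vals[spec$items])
}

#' Score a table of questionnaire responses
#'
#' Data-frame-first scoring: takes one row per walk with item columns
#' `q1..q13` and appends one score column per factor (`factor_h`,
#' `factor_d` under the default specs).
#'
#' @param data Data frame with columns `q1`..`q13` (plus any id columns,
#'   which pass through untouched).
#' @param specs Named list of `factor_spec`s (default
#'   [default_factor_specs()]).
#' @param scale_max Top of the response scale (default 5).
#' @return `data` with `factor_<name>` columns appended.
#' @export
score_responses <- function(data, specs = default_factor_specs(),
                            scale_max = 5) {
  n_items <- specs[[1]]$n_items
  qcols <- paste0("q", seq_len(n_items))
  missing <- setdiff(qcols, names(data))
  if (length(missing)) {
    rlang::abort(paste0("missing item column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "leashwalk_format_error")
  }
  mat <- as.matrix(data[, qcols])
  out <- tibble::as_tibble(data)
  for (nm in names(specs)) {
    out[[paste0("factor_", nm)]] <- apply(mat, 1, score_factor,
                                          spec = specs[[nm]],
                                          scale_max = scale_max)
  }
  out
}

#' Cronbach's alpha
#'
#' Internal consistency of a set of items:
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i s_i^2}{s_T^2}\right)}
#' where \eqn{s_i^2} are the item variances and \eqn{s_T^2} the variance of
#' the item sums. Items listed in `reversed` are reflected
#' (`scale_max + 1 - x`) before the computation.
#'
#' @param responses n x k numeric matrix (respondents x items), k >= 2,
#'   n >= 2.
#' @param reversed Column indices to reverse-code first.
#' @param scale_max Scale top used for reversal (default 5).
#' @return Alpha (at most 1; can be negative).
#' @export
cronbach_alpha <- function(responses, reversed = integer(), scale_max = 5) {
  responses <- as.matrix(responses)
  if (nrow(responses) < 2 || ncol(responses) < 2) {
    rlang::abort("need at least 2 respondents and 2 items",
                 class = "leashwalk_parameter_error")
  }
  if (length(reversed)) {
    responses[, reversed] <- scale_max + 1 - responses[, reversed]
  }
  k <- ncol(responses)
  total_var <- stats::var(rowSums(responses))
  if (total_var <= .Machine$double.eps) {
    rlang::abort("total score has zero variance; alpha undefined",
                 class = "leashwalk_degenerate_error")
  }
  k / (k - 1) * (1 - sum(apply(responses, 2, stats::var)) / total_var)
}

#' Validate NEO-FFI domain-score profiles
#'
#' Domain scores must lie in the instrument's 0--48 range; values at or
#' beyond the observed cohort envelope \[3, 48\] are flagged (not rejected)
#' so unusual profiles surface without blocking the pipeline.
#'
#' @param data Data frame with columns `neuroticism`, `extraversion`,
#'   `openness`, `agreeableness`, `conscientiousness` (one row per person).
#' @param observed_range Envelope used for flagging (default `c(3, 48)`).
#' @return `data` as a tibble with a logical `personality_flagged` column.
#' @export
validate_personality <- function(data, observed_range = c(3, 48)) {
  domains <- c("neuroticism", "extraversion", "openness", "agreeableness",
               "conscientiousness")
  missing <- setdiff(domains, names(data))
  if (length(missing)) {
    rlang::abort(paste0("missing personality column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "leashwalk_format_error")
  }
  mat <- as.matrix(data[, domains])
  if (!is.numeric(mat) || any(!is.finite(mat))) {
    rlang::abort("personality scores must be numeric and finite",
                 class = "leashwalk_format_error")
  }
  if (any(mat < 0 | mat > 48)) {
    rlang::abort("domain score outside the instrument range [0, 48]",
                 class = "leashwalk_range_error")
  }
  out <- tibble::as_tibble(data)
  out$personality_flagged <- apply(
    mat <= observed_range[1] | mat >= observed_range[2], 1, any)
  out
}
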