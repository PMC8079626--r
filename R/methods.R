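#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixed-model fit
#'
#' @param x A `walk_mixfit`.
#' @param ... Unused.
#' @return Tibble with one row per fixed effect: `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`.
#' @export
tidy.walk_mixfit <- function(x, ...) x$coefficients

#' @rdname tidy.walk_mixfit
#' @export
glance.walk_mixfit <- function(x, ...) {
  sds <- stats::setNames(x$varcor$sd, paste0("sd_", x$varcor$group))
  dplyr::bind_cols(tibble::tibble(nobs = x$nobs, bic = x$bic),
                   tibble::as_tibble(as.list(sds)))
}

#' Tidy an elimination result
#'
#' @param x A `walk_elimination`.
#' @param ... Unused.
#' @return The final model's coefficient tibble, with a `forced` column.
#' @export
tidy.walk_elimination <- function(x, ...) {
  out <- tidy(x$final)
  out$forced <- out$term %in% x$forced
  out
}

#' @rdname tidy.walk_elimination
#' @export
glance.walk_elimination <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_candidates = length(x$candidates),
                   n_removed = nrow(x$trace),
                   n_retained = length(x$retained)),
    glance(x$final))
}
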