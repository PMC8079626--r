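#' Outcome transformation specification
#'
#' Walk outcomes are transformed before model fitting to meet residual
#' normality: tension metrics on the log10 scale, behavior rates and
#' fractions by a power law (exponents between 0.3 and 10 across the
#' outcome families), or left untouched.
#'
#' @param kind One of `"identity"`, `"log10"`, `"power"`.
#' @param exponent Exponent for `kind = "power"` (non-zero).
#' @return A list of class `transform_spec`.
#' @export
transform_spec <- function(kind = c("identity", "log10", "power"),
                           exponent = NULL) {
  kind <- match.arg(kind)
  if (kind == "power") {
    if (is.null(exponent) || !is.numeric(exponent) || exponent == 0) {
      rlang::abort("power transform needs a non-zero exponent",
                   class = "leashwalk_parameter_error")
    }
  } else {
    exponent <- NULL
  }
  structure(list(kind = kind, exponent = exponent), class = "transform_spec")
}

#' Apply an outcome transformation
#'
#' @param values Numeric vector.
#' @param spec A `transform_spec`.
#' @return Transformed values; monotone on positive inputs for positive
#'   exponents.
#' @export
transform_outcome <- function(values, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  if (spec$kind == "identity") return(values)
  if (spec$kind == "log10") {
    bad <- which(!is.na(values) & values <= 0)
    if (length(bad)) {
      rlang::abort(paste0("log10 of non-positive value at row(s): ",
                          paste(utils::head(bad, 5), collapse = ", ")),
                   class = "leashwalk_range_error")
    }
    return(log10(values))
  }
  values^spec$exponent
}

#' Invert an outcome transformation
#'
#' @inheritParams transform_outcome
#' @return Values on the natural scale.
#' @export
back_transform <- function(values, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  switch(spec$kind,
         identity = values,
         log10 = 10^values,
         power = values^(1 / spec$exponent))
}

#' Bivariate predictor screen
#'
#' One single-predictor linear model per candidate against the (already
#' transformed) outcome; candidates with p below `alpha_screen` pass.
#' Predictors listed in `forced` — human personality scores and the dog's
#' behavioral level, which are expected to matter regardless of their
#' bivariate p — are always kept. Constant candidates are flagged and
#' excluded with a warning.
#'
#' @param data Data frame, one row per walk.
#' @param outcome Name of the (transformed) outcome column.
#' @param candidates Character vector of candidate predictor columns.
#' @param forced Character vector of always-kept predictor columns.
#' @param alpha_screen Screening level (default 0.2).
#' @return Tibble with columns `term`, `p_value`, `forced`, `kept`.
#' @export
bivariate_screen <- function(data, outcome, candidates,
                             forced = character(), alpha_screen = 0.2) {
  terms <- union(forced, candidates)
  res <- purrr::map_dfr(terms, function(v) {
    x <- data[[v]]
    is_forced <- v %in% forced
    if (is.numeric(x) && stats::var(x, na.rm = TRUE) < .Machine$double.eps) {
      rlang::warn(paste0("constant candidate excluded from screen: ", v))
      return(tibble::tibble(term = v, p_value = NA_real_,
                            forced = is_forced, kept = is_forced))
    }
    fit <- stats::lm(stats::reformulate(v, response = outcome), data = data)
    p <- stats::coef(summary(fit))[2, "Pr(>|t|)"]
    tibble::tibble(term = v, p_value = p, forced = is_forced,
                   kept = is_forced | p < alpha_screen)
  })
  res
}

#' Fit a linear mixed model with crossed random intercepts
#'
#' Walks are repeated measurements: the same volunteer walks several dogs
#' and the same dog is walked by several volunteers, so volunteer and dog
#' identities enter as crossed random intercepts. Estimation is by maximum
#' likelihood (so BIC comparisons across fixed-effect sets are valid);
#' fixed-effect p-values are large-sample Wald z tests.
#'
#' @param data Data frame containing the outcome, predictors and both id
#'   columns.
#' @param outcome Outcome column name (already transformed).
#' @param fixed Character vector of fixed-effect columns (may be empty for
#'   an intercept-only model).
#' @param groups Character vector of the two grouping columns
#'   (default `c("volunteer_id", "dog_id")`).
#' @return An object of class `walk_mixfit` with elements `coefficients`
#'   (tibble: term, estimate, std_error, statistic, p_value), `bic`,
#'   `varcor` (random-effect standard deviations), `vif`, `nobs`, `fit`
#'   (the underlying lme4 fit, or NULL for a degenerate constant outcome).
#' @export
fit_mixed <- function(data, outcome, fixed = character(),
                      groups = c("volunteer_id", "dog_id")) {
  missing <- setdiff(c(outcome, fixed, groups), names(data))
  if (length(missing)) {
    rlang::abort(paste0("missing column(s): ", paste(missing, collapse = ", ")),
                 class = "leashwalk_format_error")
  }
  y <- data[[outcome]]
  rhs_fixed <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  if (length(fixed)) {
    X <- stats::model.matrix(stats::reformulate(fixed), data = data)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      aliased <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
      rlang::abort(paste0("singular design; aliased column(s): ",
                          paste(aliased, collapse = ", ")),
                   class = "leashwalk_singular_error")
    }
  }
  if (stats::var(y) < .Machine$double.eps) {
    # constant outcome: degenerate closed form, no estimation needed
    coefs <- tibble::tibble(term = "(Intercept)", estimate = y[1],
                            std_error = 0, statistic = NA_real_,
                            p_value = NA_real_)
    out <- list(outcome = outcome, fixed = character(), groups = groups,
                coefficients = coefs, bic = -Inf,
                varcor = tibble::tibble(group = c(groups, "residual"), sd = 0),
                vif = NULL, nobs = length(y), fit = NULL)
    class(out) <- "walk_mixfit"
    return(out)
  }
  fml <- stats::as.formula(paste(
    outcome, "~", rhs_fixed, "+",
    paste(sprintf("(1 | %s)", groups), collapse = " + ")))
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(fml, data = data, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore"))))
  cf <- summary(fit)$coefficients
  coefs <- tibble::tibble(
    term = rownames(cf),
    estimate = unname(cf[, "Estimate"]),
    std_error = unname(cf[, "Std. Error"]),
    statistic = unname(cf[, "t value"]),
    p_value = unname(2 * stats::pnorm(-abs(cf[, "t value"]))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcor <- tibble::tibble(
    group = sub("^Residual$", "residual", vc$grp),
    sd = vc$sdcor)
  vif <- if (length(fixed) >= 2) vif_check(data, fixed) else NULL
  out <- list(outcome = outcome, fixed = fixed, groups = groups,
              coefficients = coefs, bic = stats::BIC(fit),
              varcor = varcor, vif = vif, nobs = stats::nobs(fit), fit = fit)
  class(out) <- "walk_mixfit"
  out
}

#' @exportS3Method base::print
print.walk_mixfit <- function(x, ...) {
  cat(sprintf("<walk_mixfit> %s ~ %s  (n = %d, BIC = %.2f)\n",
              x$outcome,
              if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "1",
              x$nobs, x$bic))
  print(x$coefficients)
  invisible(x)
}

#' Backward elimination with BIC tracking
#'
#' Starts from the full model (forced plus screened candidates) and
#' repeatedly removes the non-forced predictor with the largest Wald p at
#' or above `alpha_keep`, refitting after each removal and recording the
#' BIC before and after. Stops when every remaining non-forced predictor
#' has p below `alpha_keep` (or none remain). Forced predictors are never
#' removed. The procedure is deterministic: identical data yield an
#' identical trace.
#'
#' @inheritParams fit_mixed
#' @param forced Fixed effects kept regardless of p (personality scores,
#'   behavioral level).
#' @param candidates Screened, removable fixed effects.
#' @param alpha_keep Retention level (default 0.05).
#' @return An object of class `walk_elimination`: `final` (a
#'   `walk_mixfit`), `trace` (tibble: step, removed, p_at_removal,
#'   bic_before, bic_after), `bic_path`, plus the call parameters.
#' @export
backward_eliminate <- function(data, outcome, forced, candidates = character(),
                               alpha_keep = 0.05,
                               groups = c("volunteer_id", "dog_id")) {
  keep <- candidates
  fit <- fit_mixed(data, outcome, fixed = c(forced, keep), groups = groups)
  trace <- tibble::tibble(step = integer(), removed = character(),
                          p_at_removal = numeric(), bic_before = numeric(),
                          bic_after = numeric())
  bic_path <- fit$bic
  step <- 0L
  repeat {
    if (!length(keep)) break
    ps <- fit$coefficients$p_value[match(keep, fit$coefficients$term)]
    worst <- which.max(ps)
    if (!length(worst) || is.na(ps[worst]) || ps[worst] < alpha_keep) break
    step <- step + 1L
    removed <- keep[worst]
    keep <- setdiff(keep, removed)
    new_fit <- fit_mixed(data, outcome, fixed = c(forced, keep),
                         groups = groups)
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      step = step, removed = removed, p_at_removal = ps[worst],
      bic_before = fit$bic, bic_after = new_fit$bic))
    bic_path <- c(bic_path, new_fit$bic)
    fit <- new_fit
  }
  out <- list(final = fit, trace = trace, bic_path = bic_path,
              outcome = outcome, forced = forced,
              candidates = candidates, retained = keep,
              alpha_keep = alpha_keep)
  class(out) <- "walk_elimination"
  out
}

#' @exportS3Method base::print
print.walk_elimination <- function(x, ...) {
  cat(sprintf("<walk_elimination> %s: removed %d of %d candidate(s); final BIC %.2f\n",
              x$outcome, nrow(x$trace), length(x$candidates), x$final$bic))
  if (nrow(x$trace)) print(x$trace)
  print(x$final)
  invisible(x)
}

#' Variance inflation factors
#'
#' For each predictor j, \eqn{VIF_j = 1 / (1 - R^2_j)} where \eqn{R^2_j}
#' comes from regressing predictor j on the remaining predictors.
#' Predictors at or above the collinearity bound (default 2) are flagged;
#' a perfectly collinear column reports `Inf`.
#'
#' @param data Data frame holding the predictor columns.
#' @param predictors Character vector of at least two predictor columns.
#' @param bound Flagging bound (default 2).
#' @return Tibble with columns `term`, `vif`, `flagged`.
#' @export
vif_check <- function(data, predictors, bound = 2) {
  if (length(predictors) < 2) {
    rlang::abort("need at least two predictors for VIF",
                 class = "leashwalk_parameter_error")
  }
  X <- stats::model.matrix(stats::reformulate(predictors), data = data)[, -1, drop = FALSE]
  if (nrow(X) <= ncol(X)) {
    rlang::abort("need more observations than predictors for VIF",
                 class = "leashwalk_parameter_error")
  }
  vifs <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble::tibble(term = colnames(X), vif = vifs, flagged = vifs >= bound)
}

#' Screen, fit and eliminate in one call
#'
#' The full association protocol for one outcome: transform, bivariate
#' screen at `alpha_screen` with forced predictors always retained, fit
#' the mixed model, backward-eliminate at `alpha_keep`, and attach the
#' VIF table and Shapiro-Wilk residual diagnostics (reported, never used
#' as a gate).
#'
#' @inheritParams backward_eliminate
#' @param transform A `transform_spec` applied to the outcome first
#'   (default identity). The transformed outcome is stored in
#'   `<outcome>_tr`.
#' @param alpha_screen Bivariate screening level (default 0.2).
#' @return A `walk_elimination` with extra elements `screen` (the screen
#'   table) and `diagnostics` (Shapiro-Wilk W and p of final-model
#'   residuals).
#' @export
associate <- function(data, outcome, forced, candidates = character(),
                      transform = transform_spec("identity"),
                      alpha_screen = 0.2, alpha_keep = 0.05,
                      groups = c("volunteer_id", "dog_id")) {
  tr_col <- paste0(outcome, "_tr")
  data[[tr_col]] <- transform_outcome(data[[outcome]], transform)
  screen <- bivariate_screen(data, tr_col, candidates, forced = forced,
                             alpha_screen = alpha_screen)
  kept <- screen$term[screen$kept & !screen$forced]
  res <- backward_eliminate(data, tr_col, forced = forced, candidates = kept,
                            alpha_keep = alpha_keep, groups = groups)
  res$screen <- screen
  res$outcome <- outcome
  if (!is.null(res$final$fit)) {
    r <- stats::residuals(res$final$fit)
    if (length(r) >= 3 && length(r) <= 5000 && stats::sd(r) > 0) {
      sw <- stats::shapiro.test(r)
      res$diagnostics <- tibble::tibble(statistic = unname(sw$statistic),
                                        p_value = sw$p.value)
    }
  }
  res
}
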