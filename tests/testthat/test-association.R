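test_that("outcome transforms follow their table footnotes", {
  expect_equal(transform_outcome(0.04, transform_spec("power", 0.5)), 0.2)
  expect_equal(transform_outcome(1, transform_spec("log10")), 0)
  expect_equal(transform_outcome(c(2, 20), transform_spec("log10")),
               log10(c(2, 20)))
  x <- c(0.2, 1.7, 4)
  p10 <- transform_spec("power", 10)
  expect_equal(back_transform(transform_outcome(x, p10), p10), x)
  expect_error(transform_outcome(c(1, 0, 2), transform_spec("log10")),
               class = "leashwalk_range_error")
  expect_error(transform_spec("power", 0), class = "leashwalk_parameter_error")
})

test_that("the bivariate screen keeps p < 0.2 candidates and all forced terms", {
  withr::with_seed(5, {
    n <- 200
    d <- tibble::tibble(
      y = rnorm(n),
      strong = NA, weak = rnorm(n), forced_junk = rnorm(n),
      flat = rep(1, n))
    d$strong <- d$y * 0.8 + rnorm(n, 0, 0.5)
    scr <- suppressWarnings(bivariate_screen(
      d, "y", candidates = c("strong", "weak", "flat"),
      forced = "forced_junk"))
    expect_true(scr$kept[scr$term == "strong"])
    expect_true(scr$kept[scr$term == "forced_junk"]) # forced regardless of p
    expect_false(scr$kept[scr$term == "flat"])       # constant: excluded
    expect_true(is.na(scr$p_value[scr$term == "flat"]))
    # the keep rule is exactly p < 0.2 for non-forced candidates
    expect_equal(scr$kept[!scr$forced],
                 !is.na(scr$p_value[!scr$forced]) &
                   scr$p_value[!scr$forced] < 0.2)
  })
})

test_that("a true predictor passes the screen in nearly all replicates", {
  withr::with_seed(77, {
    hits <- 0
    for (i in 1:50) {
      coh <- simulate_cohort(
        n_volunteers = 74, n_dogs = 111, n_walks = 370,
        effects = list(nt_max = list(neuroticism = 0.01)),
        seed = sample.int(2^31 - 1, 1))
      scr <- bivariate_screen(coh$data, "nt_max_tr",
                              candidates = "neuroticism")
      hits <- hits + scr$kept[1]
    }
    expect_gte(hits / 50, 0.95)
  })
})

test_that("mixed fits collapse to OLS when random-effect variance is zero", {
  withr::with_seed(21, {
    n <- 150
    d <- tibble::tibble(
      volunteer_id = sample(sprintf("V%02d", 1:25), n, replace = TRUE),
      dog_id = sample(sprintf("D%02d", 1:30), n, replace = TRUE),
      x1 = rnorm(n), x2 = rnorm(n))
    e <- rnorm(n, 0, 0.4)
    # project group means out of the noise so the RE variance estimates
    # sit exactly at their zero boundary
    for (k in 1:100) {
      e <- e - stats::ave(e, d$volunteer_id)
      e <- e - stats::ave(e, d$dog_id)
    }
    d$y <- 1 + 0.5 * d$x1 - 0.3 * d$x2 + e
    fit <- fit_mixed(d, "y", c("x1", "x2"))
    expect_lt(max(fit$varcor$sd[fit$varcor$group != "residual"]), 1e-6)
    ols <- stats::lm(y ~ x1 + x2, data = d)
    expect_equal(fit$coefficients$estimate,
                 unname(stats::coef(ols)), tolerance = 1e-6)
    expect_s3_class(generics::tidy(fit), "tbl_df")
    expect_true(all(c("nobs", "bic") %in% names(generics::glance(fit))))
  })
})

test_that("planted fixed effects are recovered within 2 SE most of the time", {
  withr::with_seed(33, {
    hits <- 0
    for (i in 1:20) {
      coh <- simulate_cohort(
        n_volunteers = 40, n_dogs = 50, n_walks = 250,
        effects = list(nt_max = list(extraversion = 0.01)),
        seed = sample.int(2^31 - 1, 1))
      fit <- fit_mixed(coh$data, "nt_max_tr", "extraversion")
      b <- fit$coefficients[fit$coefficients$term == "extraversion", ]
      hits <- hits + (abs(b$estimate - 0.01) <= 2 * b$std_error)
    }
    expect_gte(hits / 20, 0.8)
  })
})

test_that("degenerate and singular designs are handled explicitly", {
  d <- tibble::tibble(volunteer_id = rep(c("a", "b"), 10),
                      dog_id = rep(c("p", "q"), each = 10),
                      y = rep(2.5, 20), x = rnorm(20))
  fit <- fit_mixed(d, "y")
  expect_equal(fit$coefficients$estimate, 2.5)
  expect_equal(sum(fit$varcor$sd), 0)

  d$y <- rnorm(20)
  d$x2 <- d$x * 2
  err <- expect_error(fit_mixed(d, "y", c("x", "x2")),
                      class = "leashwalk_singular_error")
  expect_match(conditionMessage(err), "x2")
})

test_that("backward elimination removes junk, keeps forced terms, and is deterministic", {
  coh <- simulate_cohort(
    n_volunteers = 50, n_dogs = 60, n_walks = 300,
    effects = list(nt_max = list(neuroticism = 0.012)),
    seed = 424)
  forced <- c("neuroticism", "extraversion", "openness", "agreeableness",
              "conscientiousness", "behavioral_level")
  res <- backward_eliminate(coh$data, "nt_max_tr", forced = forced,
                            candidates = c("volunteer_age", "dog_age",
                                           "dog_weight"))
  # forced terms always in the final model
  expect_true(all(forced %in% res$final$coefficients$term))
  # all surviving candidates significant at alpha_keep
  surv_p <- res$final$coefficients$p_value[
    res$final$coefficients$term %in% res$retained]
  expect_true(all(surv_p < 0.05))
  # removal order strictly follows the largest-p-first rule
  if (nrow(res$trace) > 1) {
    expect_true(all(res$trace$step == seq_len(nrow(res$trace))))
  }
  expect_equal(length(res$bic_path), nrow(res$trace) + 1)
  # byte-level determinism on identical data
  res2 <- backward_eliminate(coh$data, "nt_max_tr", forced = forced,
                             candidates = c("volunteer_age", "dog_age",
                                            "dog_weight"))
  expect_identical(res$trace, res2$trace)
  expect_identical(res$final$coefficients, res2$final$coefficients)
})

test_that("elimination leaves an all-significant model untouched", {
  withr::with_seed(9, {
    n <- 300
    d <- tibble::tibble(
      volunteer_id = sample(sprintf("V%02d", 1:30), n, replace = TRUE),
      dog_id = sample(sprintf("D%02d", 1:40), n, replace = TRUE),
      x1 = rnorm(n), x2 = rnorm(n))
    d$y <- 0.9 * d$x1 + 0.8 * d$x2 + rnorm(n, 0, 0.3)
    res <- backward_eliminate(d, "y", forced = character(),
                              candidates = c("x1", "x2"))
    expect_equal(nrow(res$trace), 0)
    expect_equal(sort(res$retained), c("x1", "x2"))
  })
})

test_that("VIF matches its closed form and the car implementation", {
  withr::with_seed(61, {
    n <- 400
    z1 <- as.numeric(scale(rnorm(n)))
    raw2 <- rnorm(n)
    # orthogonalize then mix for an exact sample correlation of 0.6
    z2 <- as.numeric(scale(stats::residuals(stats::lm(raw2 ~ z1))))
    x2 <- 0.6 * z1 + sqrt(1 - 0.36) * z2
    d <- tibble::tibble(a = z1, b = x2, y = rnorm(n))
    v <- vif_check(d, c("a", "b"))
    expect_equal(v$vif, rep(1 / (1 - 0.36), 2), tolerance = 1e-9)
    expect_false(any(v$flagged))
    skip_if_not_installed("car")
    cv <- car::vif(stats::lm(y ~ a + b, data = d))
    expect_equal(v$vif, unname(cv), tolerance = 1e-9)
  })
})

test_that("VIF flags exact collinearity and is 1 for orthogonal designs", {
  withr::with_seed(62, {
    n <- 100
    x1 <- as.numeric(scale(rnorm(n)))
    x2 <- as.numeric(scale(stats::residuals(stats::lm(rnorm(n) ~ x1))))
    d <- tibble::tibble(a = x1, b = x2)
    expect_equal(vif_check(d, c("a", "b"))$vif, c(1, 1), tolerance = 1e-9)
    d$c <- d$a
    v <- vif_check(d, c("a", "b", "c"))
    expect_true(all(is.infinite(v$vif[v$term %in% c("a", "c")])))
    expect_true(all(v$flagged[v$term %in% c("a", "c")]))
  })
})

test_that("the one-call protocol wires screen, elimination and diagnostics", {
  coh <- simulate_cohort(
    n_volunteers = 40, n_dogs = 50, n_walks = 220,
    effects = list(nt_max = list(neuroticism = 0.01)),
    seed = 7)
  res <- associate(coh$data, "nt_max",
                   forced = c("neuroticism", "extraversion",
                              "behavioral_level"),
                   candidates = c("volunteer_age", "dog_age"),
                   transform = transform_spec("log10"))
  expect_s3_class(res, "walk_elimination")
  expect_true(all(c("term", "p_value", "kept") %in% names(res$screen)))
  expect_true(all(res$screen$kept[res$screen$forced]))
  expect_s3_class(res$diagnostics, "tbl_df")
  td <- generics::tidy(res)
  expect_true("forced" %in% names(td))
  gl <- generics::glance(res)
  expect_equal(gl$n_retained + gl$n_removed,
               sum(res$screen$kept & !res$screen$forced))
})
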