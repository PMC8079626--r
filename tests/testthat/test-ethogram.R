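test_that("the shipped catalog matches the coding vocabulary", {
  cat <- ethogram_catalog()
  expect_equal(sum(cat$category == "canine"), 9)
  expect_equal(sum(cat$category == "human_verbal"), 7)
  expect_equal(sum(cat$category == "human_body"), 3)
  expect_false(anyDuplicated(cat$behavior) > 0)
  expect_equal(cat$type[cat$behavior == "shake"], "point")
  expect_equal(cat$type[cat$behavior == "pant"], "state")
  expect_equal(cat$type[cat$behavior == "gaze"], "point")
  expect_equal(cat$type[cat$behavior == "tail_wag"], "state")
  expect_true(all(cat$type[cat$category != "canine"] == "point"))
})

test_that("behavior logs validate times and vocabulary", {
  expect_error(
    behavior_log(data.frame(behavior = "flying", start_s = 1), 100),
    class = "leashwalk_catalog_error")
  expect_error(
    behavior_log(data.frame(behavior = "gaze", start_s = 150), 100),
    class = "leashwalk_format_error")
  expect_error(
    behavior_log(data.frame(behavior = "sniff", start_s = 10, end_s = 5), 100),
    class = "leashwalk_format_error")
  log <- behavior_log(data.frame(behavior = c("gaze", "sniff"),
                                 start_s = c(5, 10), end_s = c(NA, 30)), 100)
  expect_equal(log$type, c("point", "state"))
})

test_that("behavior logs round-trip through their CSV dialect", {
  log <- simulate_behavior_log(point_rates = c(gaze = 0.05),
                               state_fractions = c(sniff = 25),
                               duration_s = 120, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_behavior_log(log, path)
  back <- read_behavior_log(path, duration_s = 120)
  expect_equal(back$behavior, log$behavior)
  expect_equal(back$start_s, log$start_s)
  expect_equal(back$end_s, log$end_s)
})

test_that("summaries compute rates, fractions and grouped totals", {
  log <- behavior_log(
    data.frame(behavior = c(rep("gaze", 12), "sniff", "sniff"),
               start_s = c(seq(10, 230, by = 20), 0, 60),
               end_s = c(rep(NA, 12), 30, 90)),
    duration_s = 300)
  s <- summarize_behaviors(log)
  expect_equal(s$value[s$behavior == "gaze"], 0.04)
  expect_equal(s$value[s$behavior == "sniff"], 20)
  expect_equal(s$measure[s$behavior == "sniff"], "pct_time")
  expect_equal(s$value[s$behavior == "total_verbal_cue"], 0)
})

test_that("overlapping same-behavior intervals are merged before summing", {
  log <- behavior_log(
    data.frame(behavior = rep("pant", 3), start_s = c(0, 5, 20),
               end_s = c(10, 15, 25)),
    duration_s = 100)
  s <- summarize_behaviors(log)
  expect_equal(s$value[s$behavior == "pant"], 20) # [0,15) + [20,25)
})

test_that("totals equal independent per-behavior sums on random logs", {
  for (seed in 1:5) {
    log <- simulate_behavior_log(
      point_rates = c(praise = 0.02, command = 0.03, gestural = 0.01,
                      physical_contact = 0.02, gaze = 0.05),
      duration_s = 200, seed = seed)
    s <- summarize_behaviors(log)
    verbal <- sum(table(log$behavior[log$behavior %in%
      c("sit", "command", "attention_seeking", "high_pitched_voice",
        "praise", "negative_verbal_cue", "communication")])) / 200
    body <- sum(log$behavior %in%
      c("gestural", "physical_contact", "food_reward")) / 200
    expect_equal(s$value[s$behavior == "total_verbal_cue"], verbal)
    expect_equal(s$value[s$behavior == "total_body_language"], body)
  }
})

test_that("rates recombine as duration-weighted means under concatenation", {
  l1 <- simulate_behavior_log(point_rates = c(gaze = 0.05),
                              duration_s = 100, seed = 1)
  l2 <- simulate_behavior_log(point_rates = c(gaze = 0.02),
                              duration_s = 300, seed = 2)
  shifted <- tibble::as_tibble(l2)
  shifted$start_s <- shifted$start_s + 100
  joint <- behavior_log(dplyr::bind_rows(tibble::as_tibble(l1), shifted), 400)
  s1 <- summarize_behaviors(l1); s2 <- summarize_behaviors(l2)
  r1 <- s1$value[s1$behavior == "gaze"]
  r2 <- s2$value[s2$behavior == "gaze"]
  rj <- summarize_behaviors(joint)
  expect_equal(rj$value[rj$behavior == "gaze"],
               (r1 * 100 + r2 * 300) / 400)
})

test_that("timelines bin with the half-open convention and catalog tie-break", {
  log <- behavior_log(data.frame(behavior = "sniff", start_s = 0, end_s = 100),
                      duration_s = 100)
  expect_equal(bin_timeline(log, bin = 10), rep("sniff", 10))

  empty <- behavior_log(data.frame(behavior = character(),
                                   start_s = numeric()), 50)
  expect_equal(bin_timeline(empty, bin = 10), rep("none", 5))

  # point event exactly on a bin boundary goes to the later bin
  log <- behavior_log(data.frame(behavior = "gaze", start_s = 10), 20)
  expect_equal(bin_timeline(log, bin = 10), c("none", "gaze"))

  # tie between two states breaks by catalog order (track before sniff)
  log <- behavior_log(data.frame(behavior = c("sniff", "track"),
                                 start_s = c(0, 5), end_s = c(5, 10)),
                      duration_s = 10)
  expect_equal(bin_timeline(log, bin = 10), "track")
  expect_error(bin_timeline(log, bin = 20),
               class = "leashwalk_parameter_error")
})

test_that("kappa matches hand-computed and degenerate cases", {
  expect_equal(cohens_kappa(c("A", "B", "A"), c("A", "B", "A")), 1)
  expect_equal(cohens_kappa(c("A", "A", "B", "B"), c("A", "B", "A", "B")), 0)
  expect_equal(cohens_kappa(rep("A", 5), rep("A", 5)), 1) # p_e = 1 convention
  expect_error(cohens_kappa("A", c("A", "B")),
               class = "leashwalk_parameter_error")
  # full disagreement on two balanced labels
  expect_equal(cohens_kappa(c("A", "B"), c("B", "A")), -1)
})

test_that("kappa is symmetric, relabeling-invariant, and near zero for independent sequences", {
  withr::with_seed(42, {
    a <- sample(c("x", "y", "z"), 500, replace = TRUE)
    b <- sample(c("x", "y", "z"), 500, replace = TRUE)
    expect_equal(cohens_kappa(a, b), cohens_kappa(b, a))
    relab <- c(x = "q", y = "r", z = "s")
    expect_equal(cohens_kappa(relab[a], relab[b]), cohens_kappa(a, b))
    big_a <- sample(c("u", "v"), 1e4, replace = TRUE)
    big_b <- sample(c("u", "v"), 1e4, replace = TRUE)
    expect_lt(abs(cohens_kappa(big_a, big_b)), 0.05)
  })
})

test_that("binned double-coded logs give high kappa for similar codings", {
  log <- simulate_behavior_log(state_fractions = c(sniff = 30, tail_wag = 20),
                               duration_s = 300, seed = 9)
  seq_a <- bin_timeline(log, bin = 1)
  # a second coder shifting every interval by 1 s still agrees strongly
  shifted <- tibble::as_tibble(log)
  shifted$start_s <- pmin(shifted$start_s + 1, 300)
  shifted$end_s <- pmin(shifted$end_s + 1, 300)
  shifted <- shifted[shifted$end_s > shifted$start_s, ]
  seq_b <- bin_timeline(behavior_log(shifted[, c("behavior", "start_s", "end_s")],
                                     300), bin = 1)
  expect_gt(cohens_kappa(seq_a, seq_b), 0.7)
})
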