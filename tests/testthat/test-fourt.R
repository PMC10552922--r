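test_that("classic presentations score at the rubric extremes", {
  high <- four_t_score(four_t_inputs(60, 45, 7, thrombosis = "confirmed",
                                     other_cause = "none"))
  expect_equal(high$score, 8L)
  expect_equal(high$category, "high")

  low <- four_t_score(four_t_inputs(10, 150, 2, thrombosis = "none",
                                    other_cause = "definite"))
  expect_equal(low$score, 0L)
  expect_equal(low$category, "low")
})

test_that("per-criterion scoring follows the published bands", {
  # thrombocytopenia: middle band by fall or by nadir
  s <- four_t_score(four_t_inputs(c(40, 60, 60), c(80, 15, 5), 7,
                                  thrombosis = "none", other_cause = "none"))
  expect_equal(s$t_thrombocytopenia, c(1L, 1L, 0L))
  # timing: day-1 fall scores 2 only with recent heparin exposure
  s <- four_t_score(four_t_inputs(60, 40, c(1, 1, 12, 3),
                                  recent_heparin = c(TRUE, FALSE, FALSE, FALSE),
                                  thrombosis = "none", other_cause = "none"))
  expect_equal(s$t_timing, c(2L, 0L, 1L, 0L))
  # category boundaries
  s <- four_t_score(four_t_inputs(c(40, 40, 60), c(80, 80, 40), c(7, 7, 7),
                                  thrombosis = c("none", "possible", "confirmed"),
                                  other_cause = c("definite", "possible", "none")))
  expect_equal(s$score, c(3L, 5L, 8L))
  expect_equal(s$category, c("low", "intermediate", "high"))
})

test_that("the total is the sum of four sub-scores, each in 0..2", {
  grid <- withr::with_seed(77, four_t_inputs(
    platelet_fall_pct = runif(60, 0, 100),
    nadir_plt = runif(60, 1, 200),
    onset_day = sample(0:20, 60, replace = TRUE),
    recent_heparin = sample(c(TRUE, FALSE), 60, replace = TRUE),
    thrombosis = sample(c("none", "possible", "confirmed"), 60, replace = TRUE),
    other_cause = sample(c("definite", "possible", "none"), 60, replace = TRUE)
  ))
  s <- four_t_score(grid)
  subs <- as.matrix(s[, c("t_thrombocytopenia", "t_timing", "t_thrombosis",
                          "t_other")])
  expect_true(all(subs >= 0 & subs <= 2))
  expect_equal(s$score, as.integer(rowSums(subs)))
})

test_that("worsening any single criterion never decreases the score", {
  base <- four_t_inputs(35, 60, 12, thrombosis = "possible",
                        other_cause = "possible")
  s0 <- four_t_score(base)$score
  worse <- list(
    four_t_inputs(60, 60, 12, thrombosis = "possible", other_cause = "possible"),
    four_t_inputs(35, 60, 7, thrombosis = "possible", other_cause = "possible"),
    four_t_inputs(35, 60, 12, thrombosis = "confirmed", other_cause = "possible"),
    four_t_inputs(35, 60, 12, thrombosis = "possible", other_cause = "none")
  )
  for (w in worse) expect_gte(four_t_score(w)$score, s0)
})

test_that("missing criteria yield an explicit missing score, never imputation", {
  s <- four_t_score(four_t_inputs(NA_real_, 40, 7, thrombosis = "confirmed",
                                  other_cause = "none"))
  expect_true(is.na(s$score))
  expect_true(is.na(s$category))
  expect_match(s$missing_criteria, "thrombocytopenia")
})
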