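test_that("the packaged fixture reproduces every published marginal exactly", {
  cases <- hit_case_series()
  expect_equal(nrow(cases), 43)
  chk <- check_case_series(cases)
  expect_true(chk$ok)
  expect_equal(nrow(chk$mismatches), 0)
})

test_that("headline frequency rows match the published tables", {
  ft <- frequency_tables(hit_case_series())
  ov <- function(block, level) ft[ft$block == block & ft$level == level &
                                    is.na(ft$drug), ]
  drug <- ft[ft$block == "drug" & is.na(ft$drug), ]
  expect_equal(drug$n[match(c("enoxaparin", "nadroparin", "dalteparin",
                              "tinzaparin", "bemiparin"), drug$level)],
               c(21L, 14L, 4L, 2L, 2L))
  expect_equal(ov("drug", "enoxaparin")$pct, 48.84)
  expect_equal(ov("alt_anticoagulants", "fondaparinux")$n, 17L)
  expect_equal(ov("alt_anticoagulants", "fondaparinux")$pct, 43.59)
  expect_equal(ov("treatments", "withdrawal")$n, 43L)
  expect_equal(ov("treatments", "withdrawal")$pct, 100)
  expect_equal(ov("combined_drugs", "none")$pct, 85.71)  # 36/42
  onset <- ft[ft$block == "onset_band" & is.na(ft$drug), ]
  expect_equal(onset$n[match(c("<5", "5-10", ">10"), onset$level)],
               c(5L, 24L, 14L))
})

test_that("per-drug breakdown rows share the block denominator and sum to the level total", {
  ft <- frequency_tables(hit_case_series())
  strat <- ft[!is.na(ft$drug), ]
  for (b in unique(strat$block)) {
    for (lv in unique(strat$level[strat$block == b])) {
      rows <- strat[strat$block == b & strat$level == lv, ]
      overall <- ft[ft$block == b & ft$level == lv & is.na(ft$drug), ]
      expect_equal(sum(rows$n), overall$n)
      expect_true(all(rows$denom == overall$denom))
    }
  }
})

test_that("single-level blocks partition their non-missing denominator", {
  ft <- frequency_tables(hit_case_series(), by_drug = FALSE)
  for (b in c("sex", "age_band", "drug", "onset_band", "nadir_plt_band",
              "plt_decrease_band", "four_t_band", "recovery_band", "outcome")) {
    rows <- ft[ft$block == b, ]
    expect_equal(sum(rows$n), rows$denom[1])
  }
})

test_that("the narrative summary reports the published headline numbers", {
  s <- summarize_series(hit_case_series())
  expect_equal(s$n, 43)
  expect_equal(s$symptoms$level[1], "thrombus")
  expect_equal(s$symptoms$label[1], "39/43")
  expect_equal(s$anti_pf4_positive, 36)
  expect_equal(s$four_t$scored, 21)
  expect_equal(s$four_t$high, 18)
  expect_equal(s$four_t$high_share, 85.71)
  # onset is banded only: modal band with an explicit marker, no median
  expect_true(s$onset$binned_only)
  expect_equal(s$onset$modal_band, "5-10")
})

test_that("degenerate inputs produce empty tables, not errors", {
  empty <- hit_case_series()[0, ]
  expect_equal(nrow(frequency_tables(empty)), 0)
  one <- hit_case_series()[1, ]
  one$outcome <- "death"
  ft <- frequency_tables(one)
  death <- ft[ft$block == "outcome" & ft$level == "death", ]
  expect_equal(death$n, 1L)
  expect_equal(death$pct, 100)
})

test_that("fixture construction is deterministic and matches the shipped CSV", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_case_series(build_case_fixture(101L), f1)
  write_case_series(build_case_fixture(101L), f2)
  expect_identical(readLines(f1), readLines(f2))
  shipped <- system.file("extdata", "hit_cases_43.csv", package = "hitsignal")
  expect_identical(readLines(f1), readLines(shipped))
})

test_that("case CSV validation reports row-level problems", {
  cases <- hit_case_series()
  f <- withr::local_tempfile(fileext = ".csv")
  raw <- readLines(system.file("extdata", "hit_cases_43.csv",
                               package = "hitsignal"))
  raw[3] <- sub("^case02,enoxaparin", "case02,heparinoid", raw[3])
  writeLines(raw, f)
  expect_error(read_case_series(f), "row 2: invalid drug")
})
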