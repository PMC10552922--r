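test_that("a toy quarter joins demographics, drugs and reactions per case", {
  paths <- write_toy_quarter(
    withr::local_tempdir(),
    demo_rows = c("1-1$1$1$20210101$65$F$HO$US",
                  "2-1$2$1$20210202$40$M$DE,HO$FR"),
    drug_rows = c("1-1$LOVENOX$PS", "1-1$warfarin$C", "2-1$FRAGMIN$SS"),
    reac_rows = c("1-1$Heparin-induced thrombocytopenia", "2-1$Nausea",
                  "2-1$Rash")
  )
  rep <- read_faers_reports(paths["demo"], paths["drug"], paths["reac"])
  expect_equal(nrow(rep), 2)
  expect_equal(rep$drug_names[[1]], c("LOVENOX", "warfarin"))
  expect_equal(rep$reactions[[2]], c("Nausea", "Rash"))
  expect_equal(rep$sex, c("female", "male"))
  # multiple outcome codes collapse by severity precedence
  expect_equal(rep$outcome_code, c("hospitalization", "death"))
  expect_equal(attr(rep, "exclusions")$orphan_drug_rows, 0)
})

test_that("orphan child rows are excluded and counted, not silently dropped", {
  paths <- write_toy_quarter(
    withr::local_tempdir(),
    demo_rows = "1-1$1$1$20210101$65$F$HO$US",
    drug_rows = c("1-1$LOVENOX$PS", "9-9$FRAGMIN$PS"),
    reac_rows = "1-1$Heparin-induced thrombocytopenia"
  )
  expect_warning(
    rep <- read_faers_reports(paths["demo"], paths["drug"], paths["reac"]),
    "no matching demographics"
  )
  expect_equal(nrow(rep), 1)
  expect_equal(attr(rep, "exclusions")$orphan_drug_rows, 1)
})

test_that("a missing mandatory column is a hard error naming the column", {
  dir <- withr::local_tempdir()
  paths <- write_toy_quarter(dir, "1-1$1$1$20210101$65$F$HO$US",
                             "1-1$LOVENOX$PS", "1-1$Nausea")
  writeLines(c("primaryid$caseid$caseversion$fda_dt$age$sex$occr_country",
               "1-1$1$1$20210101$65$F$US"), paths["demo"])
  expect_error(read_faers_reports(paths["demo"], paths["drug"], paths["reac"]),
               "outc_cod")
})

test_that("deduplication keeps the highest version and is idempotent", {
  rep <- make_reports(3, case_ids = c("A", "A", "A"))
  rep$case_version <- c(1L, 3L, 2L)
  dd <- deduplicate_reports(rep)
  expect_equal(nrow(dd), 1)
  expect_equal(dd$case_version, 3L)

  two <- make_reports(2, case_ids = c("A", "B"))
  expect_equal(nrow(deduplicate_reports(two)), 2)

  sim <- generate_reports(sim_config(n_reports = 500, seed = 5,
                                     duplicate_rate = 0.3))
  once <- deduplicate_reports(sim$reports)
  expect_lte(nrow(once), nrow(sim$reports))
  expect_identical(deduplicate_reports(once), once)
})

test_that("version ties fall back to receipt date", {
  rep <- make_reports(2, case_ids = c("A", "A"))
  rep$receipt_date <- as.Date(c("2021-01-01", "2021-06-01"))
  rep$age_years <- c(50, 60)
  dd <- deduplicate_reports(rep)
  expect_equal(dd$age_years, 60)
})

test_that("drug names normalize across brand, salt and punctuation variants", {
  expect_equal(normalize_drug("LOVENOX"), "enoxaparin")
  expect_equal(normalize_drug("ENOXAPARIN SODIUM."), "enoxaparin")
  expect_equal(normalize_drug(" Fragmin  "), "dalteparin")
  expect_true(is.na(normalize_drug("warfarin")))
})

test_that("HIT preferred-term matching is exact, case-insensitive, closed", {
  expect_true(match_hit_pt("Heparin-induced thrombocytopenia"))
  expect_true(match_hit_pt("HEPARIN-INDUCED THROMBOCYTOPENIA TEST POSITIVE"))
  expect_false(match_hit_pt("Thrombocytopenia"))
  expect_false(match_hit_pt("Heparin-induced thrombocytopenia aggravated"))
  expect_equal(match_hit_pt(list("Nausea", c("Rash", "heparin-induced thrombocytopenia test"))),
               c(FALSE, TRUE))
})

test_that("baseline table matches an independent tally and partitions reports", {
  sim <- generate_reports(sim_config(n_reports = 800, seed = 9))
  rep <- deduplicate_reports(sim$reports)
  tab <- baseline_table(rep)
  # independent tally with plain table() arithmetic
  age <- ifelse(is.na(rep$age_years), "unknown",
                ifelse(rep$age_years < 18, "<18",
                       ifelse(rep$age_years <= 60, "18-60", ">60")))
  for (lv in unique(age)) {
    expect_equal(tab$n[tab$block == "age" & tab$level == lv],
                 sum(age == lv))
  }
  us <- sum(!is.na(rep$reporter_country) & rep$reporter_country == "US")
  expect_equal(tab$n[tab$block == "country" & tab$level == "US"], us)
  expect_equal(tab$pct[tab$block == "country" & tab$level == "US"],
               round_half_up(100 * us / nrow(rep), 2))
  # each block partitions the corpus exactly once
  for (b in unique(tab$block)) {
    expect_equal(sum(tab$n[tab$block == b]), nrow(rep))
  }
})

test_that("93 US reports among 242 give a 38.43% US share", {
  rep <- make_reports(242, country = c(rep("US", 93), rep("FR", 149)))
  tab <- baseline_table(rep)
  expect_equal(tab$pct[tab$block == "country" & tab$level == "US"], 38.43)
})

test_that("uniform age 70 lands entirely in the >60 band; empty input is all-zero", {
  tab <- baseline_table(make_reports(20, age = 70))
  expect_equal(tab$pct[tab$block == "age" & tab$level == ">60"], 100)
  empty <- baseline_table(make_reports(0))
  expect_true(all(empty$n == 0))
})

test_that("write -> read round-trips a synthetic corpus field by field", {
  sim <- generate_reports(sim_config(n_reports = 250, seed = 13,
                                     target_or = 5))
  paths <- write_faers_reports(sim$reports, withr::local_tempdir())
  back <- read_faers_reports(paths["demo"], paths["drug"], paths["reac"])
  expect_equal(nrow(back), nrow(sim$reports))
  for (col in names(sim$reports)) {
    expect_equal(unname(as.list(back[[col]])),
                 unname(as.list(sim$reports[[col]])), info = col)
  }
})
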