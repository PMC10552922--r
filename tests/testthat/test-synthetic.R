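test_that("the generator is reproducible under a fixed seed", {
  a <- generate_reports(sim_config(n_reports = 400, seed = 21, target_or = 3))
  b <- generate_reports(sim_config(n_reports = 400, seed = 21, target_or = 3))
  expect_identical(a$reports, b$reports)
  expect_identical(a$truth$table, b$truth$table)
  c <- generate_reports(sim_config(n_reports = 400, seed = 22, target_or = 3))
  expect_false(identical(a$reports$reactions, c$reports$reactions))
})

test_that("the empirical odds ratio converges to the injected one", {
  for (n in c(1e4, 1e5)) {
    sim <- generate_reports(sim_config(n_reports = n, seed = 31,
                                       target_or = 10))
    tt <- sim$truth$table
    emp <- (tt$a * tt$d) / (tt$b * tt$c)
    se <- sqrt(1 / tt$a + 1 / tt$b + 1 / tt$c + 1 / tt$d)
    expect_lt(abs(log(emp) - log(10)), 3 * se)
  }
})

test_that("a null corpus screens near independence", {
  sim <- generate_reports(sim_config(n_reports = 5e4, seed = 41, target_or = 1))
  sc <- screen_pairs(deduplicate_reports(sim$reports), "enoxaparin")
  expect_lt(abs(log(sc$ror)), 0.3)
})

test_that("deduplication removes exactly the injected duplicates", {
  sim <- generate_reports(sim_config(n_reports = 1000, seed = 51,
                                     duplicate_rate = 0.2))
  expect_equal(nrow(sim$reports), 1200)
  dd <- deduplicate_reports(sim$reports)
  expect_equal(nrow(dd), 1000)
  # the retained version is 2 exactly for the duplicated ids
  expect_setequal(dd$case_id[dd$case_version == 2L],
                  sim$truth$duplicated_case_ids)
})

test_that("the ground-truth table matches screening of the deduplicated corpus", {
  sim <- generate_reports(sim_config(n_reports = 3000, seed = 61,
                                     target_or = 8))
  sc <- screen_pairs(deduplicate_reports(sim$reports), "enoxaparin")
  tt <- sim$truth$table
  expect_equal(c(sc$a, sc$b, sc$c, sc$d), c(tt$a, tt$b, tt$c, tt$d))
})

test_that("invalid configurations are rejected up front", {
  expect_error(sim_config(n_reports = 0), "n_reports")
  expect_error(sim_config(drugs = c(0.5, 0.5)), "named")
  expect_error(sim_config(drugs = c(a = 0.6, b = 0.6)), "summing to 1")
  expect_error(sim_config(target_drug = "argatroban"), "target_drug")
  expect_error(sim_config(duplicate_rate = 1), "duplicate_rate")
  expect_error(sim_config(background_event_prob = 0), "probability")
})
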