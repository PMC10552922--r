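test_that("PRR and ROR match hand arithmetic", {
  t <- contingency_table(10, 90, 10, 890)
  expect_equal(compute_prr(t), 9)                    # (10/100)/(10/900)
  expect_equal(compute_ror(t), 8900 / 900)           # ad/bc
  expect_equal(compute_prr(contingency_table(5, 5, 5, 5)), 1)
  expect_equal(compute_ror(contingency_table(4, 8, 10, 20)), 1) # ad = bc
})

test_that("chi-square agrees with expected-count summation and chisq.test", {
  t <- contingency_table(10, 90, 10, 890)
  expect_equal(compute_chi2(t), oracle_chi2(10, 90, 10, 890), tolerance = 1e-12)
  expect_equal(compute_chi2(t, yates = TRUE),
               oracle_chi2(10, 90, 10, 890, yates = TRUE), tolerance = 1e-12)
  m <- matrix(c(10, 90, 10, 890), 2, 2, byrow = TRUE)
  # suppress chisq.test's small-expected-count advisory; the comparison is
  # about the statistic, not the asymptotic p-value
  expect_equal(compute_chi2(t),
               unname(suppressWarnings(stats::chisq.test(m, correct = FALSE))$statistic))
  expect_equal(compute_chi2(t, yates = TRUE),
               unname(suppressWarnings(stats::chisq.test(m, correct = TRUE))$statistic))
  # exact independence: proportional rows
  expect_equal(compute_chi2(contingency_table(10, 90, 20, 180)), 0)
})

test_that("Wald CI follows the log-scale formulas and is geometrically centred", {
  t <- contingency_table(10, 90, 10, 890)
  ror <- compute_ror(t)
  ci <- wald_ci(ror, t, "ror")
  expect_equal(unname(ci), oracle_wald(ror, 10, 90, 10, 890, "ror"),
               tolerance = 1e-12)
  for (tab in rand_tables(50)) {
    for (kind in c("ror", "prr")) {
      pt <- if (kind == "ror") compute_ror(tab) else compute_prr(tab)
      ci <- wald_ci(pt, tab, kind)
      expect_equal(sqrt(ci[["lower"]] * ci[["upper"]]), pt,
                   tolerance = 1e-9)
    }
  }
})

test_that("screening rules use strict thresholds on PRR, chi-square and N", {
  base <- tibble::tibble(prr = 2.5, chi2 = 5, ror = 3, ror_l95 = 1.5,
                         n_reports = 3)
  expect_true(apply_signal_criteria(base)$prr_signal)
  expect_false(apply_signal_criteria(dplyr::mutate(base, n_reports = 2))$prr_signal)
  expect_false(apply_signal_criteria(dplyr::mutate(base, prr = 2))$prr_signal)
  expect_false(apply_signal_criteria(dplyr::mutate(base, chi2 = 4))$prr_signal)
  expect_true(apply_signal_criteria(base)$ror_signal)
  expect_false(apply_signal_criteria(dplyr::mutate(base, ror_l95 = 1))$ror_signal)
})

test_that("undefined statistics come back as reasoned NAs, never silent zeros", {
  t <- contingency_table(3, 20, 0, 100)
  expect_true(is.na(compute_prr(t)))
  expect_match(value_reason(compute_prr(t)), "c = 0")
  expect_true(is.na(compute_ror(t)))
  expect_true(is.na(compute_chi2(contingency_table(0, 0, 3, 5))))
  # signal_stats applies the Haldane-Anscombe correction instead
  st <- signal_stats(t)
  expect_true(st$corrected)
  expect_false(is.na(st$ror))
  st2 <- signal_stats(contingency_table(3, 20, 5, 100))
  expect_false(st2$corrected)
})

test_that("ROR exceeds PRR exactly when ROR exceeds 1", {
  for (tab in rand_tables(200)) {
    ror <- compute_ror(tab)
    prr <- compute_prr(tab)
    if (abs(ror - 1) < 1e-12) next
    expect_equal(ror > prr, ror > 1)
  }
})

test_that("PRR and ROR increase strictly in a with b, c, d fixed", {
  for (tab in rand_tables(25, seed = 4)) {
    up <- contingency_table(tab$a + 1, tab$b, tab$c, tab$d)
    expect_gt(compute_prr(up), compute_prr(tab))
    expect_gt(compute_ror(up), compute_ror(tab))
  }
})

test_that("chi-square is invariant under simultaneous row and column swap", {
  for (tab in rand_tables(25, seed = 8)) {
    swapped <- contingency_table(tab$d, tab$c, tab$b, tab$a)
    expect_equal(compute_chi2(tab), compute_chi2(swapped), tolerance = 1e-12)
    expect_equal(compute_chi2(tab, TRUE), compute_chi2(swapped, TRUE),
                 tolerance = 1e-12)
  }
})

test_that("screen_pairs partitions the corpus for every drug", {
  rep <- dplyr::bind_rows(
    make_reports(40, drug = "enoxaparin", hit = TRUE,
                 case_ids = sprintf("E%03d", 1:40)),
    make_reports(60, drug = "enoxaparin", hit = FALSE,
                 case_ids = sprintf("F%03d", 1:60)),
    make_reports(10, drug = "tinzaparin", hit = TRUE,
                 case_ids = sprintf("G%03d", 1:10)),
    make_reports(90, drug = "warfarin", hit = FALSE,
                 case_ids = sprintf("H%03d", 1:90))
  )
  sc <- screen_pairs(rep, c("enoxaparin", "tinzaparin", "parnaparin"))
  expect_equal(sc$a + sc$b + sc$c + sc$d, rep(nrow(rep), 3))
  expect_equal(sc$a[sc$drug == "enoxaparin"] + sc$b[sc$drug == "enoxaparin"], 100)
  expect_equal(sc$a[sc$drug == "tinzaparin"] + sc$b[sc$drug == "tinzaparin"], 10)
  # drug absent from the corpus: row emitted, no flags
  row <- sc[sc$drug == "parnaparin", ]
  expect_equal(row$n_reports, 0)
  expect_false(row$prr_signal || row$ror_signal)
})

test_that("concomitant roles count only when requested", {
  rep <- make_reports(10, case_ids = sprintf("C%02d", 1:10))
  rep$drug_roles <- rep(list("C"), 10)
  sc <- screen_pairs(rep, "enoxaparin")
  expect_equal(sc$a + sc$b, 0)
  sc2 <- screen_pairs(rep, "enoxaparin", roles = c("PS", "SS", "C"))
  expect_equal(sc2$a + sc2$b, 10)
})
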