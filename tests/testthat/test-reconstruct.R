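# round-trip property: print a table's statistics at 2 decimals, reconstruct
# integer cells from them, and the reconstructed table must reproduce every
# supplied statistic to within half a unit in its last printed decimal

roundtrip_case <- function(tab, kind) {
  st <- signal_stats(tab)
  if (kind == "ror") {
    point <- round(st$ror, 2); ci <- round(c(st$ror_l95, st$ror_u95), 2)
  } else {
    point <- round(st$prr, 2); ci <- round(c(st$prr_l95, st$prr_u95), 2)
  }
  chi2 <- round(st$chi2, 2)
  rec <- reconstruct_table(tab$a, point, ci, chi2, kind = kind)
  got <- rec$stats
  if (kind == "ror") {
    expect_lte(abs(got$ror - point), 0.005)
    expect_lte(abs(got$ror_l95 - ci[1]), 0.005)
    expect_lte(abs(got$ror_u95 - ci[2]), 0.005)
  } else {
    expect_lte(abs(got$prr - point), 0.005)
    expect_lte(abs(got$prr_l95 - ci[1]), 0.005)
    expect_lte(abs(got$prr_u95 - ci[2]), 0.005)
  }
  expect_lte(abs(got$chi2 - chi2), 0.005)
  rec
}

test_that("reconstruction round-trips random tables at printed precision", {
  # strongly associated tables, as in real signal-detection use: a weak
  # association leaves the cells underdetermined at printed precision and
  # the enumeration reports a truncated sliver instead
  tabs <- withr::with_seed(2209, {
    lapply(1:4, function(i) {
      contingency_table(sample(30:60, 1), sample(200:1500, 1),
                        sample(30:300, 1), sample(20000:80000, 1))
    })
  })
  for (tab in tabs) {
    roundtrip_case(tab, "ror")
    roundtrip_case(tab, "prr")
  }
})

test_that("reconstruction reports the feasible spread of the held-out statistic", {
  tab <- contingency_table(20, 700, 80, 40000)
  st <- signal_stats(tab)
  rec <- roundtrip_case(tab, "prr")
  rng <- rec$diagnostics$held_out_range
  expect_lte(rng[1], st$ror)
  expect_gte(rng[2], st$ror)
  expect_gte(rec$diagnostics$feasible_mass, 1)
})

test_that("inconsistent statistics fail with a diagnostic, not a wrong table", {
  # chi-square far from anything the CI allows
  expect_error(
    reconstruct_table(20, point = 5.0, ci = c(3.1, 8.2), chi2 = 9e5,
                      kind = "ror"),
    "no integer table|no contingency table"
  )
  # CI bounds whose geometric mean is far from the point estimate
  expect_warning(
    try(reconstruct_table(20, point = 5.0, ci = c(2.0, 6.0), chi2 = 50,
                          kind = "ror"), silent = TRUE),
    "geometric mean"
  )
})

test_that("joint reconstruction under a shared corpus identifies both totals", {
  # two drugs drawn from one synthetic database snapshot
  base <- list(Tt = 500, N = 2e6)
  t1 <- contingency_table(40, 4000, base$Tt - 40, base$N - 40 - 4000 - (base$Tt - 40))
  t2 <- contingency_table(25, 700, base$Tt - 25, base$N - 25 - 700 - (base$Tt - 25))
  mk_spec <- function(tab, kind) {
    st <- signal_stats(tab)
    if (kind == "ror") {
      list(a = tab$a, kind = kind, point = round(st$ror, 2),
           ci = round(c(st$ror_l95, st$ror_u95), 2), chi2 = round(st$chi2, 2))
    } else {
      list(a = tab$a, kind = kind, point = round(st$prr, 2),
           ci = round(c(st$prr_l95, st$prr_u95), 2), chi2 = round(st$chi2, 2))
    }
  }
  js <- reconstruct_table_set(list(d1 = mk_spec(t1, "ror"),
                                   d2 = mk_spec(t2, "prr")))
  expect_equal(js$event_total, base$Tt)
  expect_equal(js$grand_total, base$N, tolerance = 2e-5)
})
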