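# independent brute-force oracles and small fixtures shared across tests

# chi-square by explicit expected-count summation over the four cells
oracle_chi2 <- function(a, b, c, d, yates = FALSE) {
  obs <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  n <- sum(obs)
  expected <- outer(rowSums(obs), colSums(obs)) / n
  dev <- abs(obs - expected)
  if (yates) dev <- pmax(0, dev - 0.5)
  sum(dev^2 / expected)
}

# log-scale Wald bounds by direct formula evaluation
oracle_wald <- function(point, a, b, c, d, kind, z = 1.96) {
  se <- if (kind == "ror") {
    sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  } else {
    sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  }
  c(point * exp(-z * se), point * exp(z * se))
}

# random strictly-positive 2x2 tables
rand_tables <- function(n, seed = 20230920) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      contingency_table(sample(1:50, 1), sample(1:500, 1),
                        sample(1:200, 1), sample(100:20000, 1))
    })
  })
}

# minimal in-memory AE report tibble for unit tests
make_reports <- function(n, drug = "enoxaparin", hit = TRUE,
                         age = 70, sex = "male", outcome = "death",
                         country = "US", case_ids = NULL) {
  tibble::tibble(
    case_id = case_ids %||% sprintf("T%04d", seq_len(n)),
    case_version = 1L,
    receipt_date = as.Date("2021-06-01"),
    age_years = rep_len(age, n),
    sex = rep_len(sex, n),
    outcome_code = rep_len(outcome, n),
    reporter_country = rep_len(country, n),
    drug_names = rep(list(drug), n),
    drug_roles = rep(list(rep("PS", length(drug))), n),
    reactions = rep(list(if (hit) "Heparin-induced thrombocytopenia" else "Nausea"), n)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# write a tiny FAERS-style quarter; returns the three paths
write_toy_quarter <- function(dir, demo_rows, drug_rows, reac_rows) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(demo = file.path(dir, "demo.txt"),
             drug = file.path(dir, "drug.txt"),
             reac = file.path(dir, "reac.txt"))
  writeLines(c("primaryid$caseid$caseversion$fda_dt$age$sex$outc_cod$occr_country",
               demo_rows), paths["demo"])
  writeLines(c("primaryid$drugname$role_cod", drug_rows), paths["drug"])
  writeLines(c("primaryid$pt", reac_rows), paths["reac"])
  paths
}
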