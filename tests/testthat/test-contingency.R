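toy_reports <- function(drugs, pts) {
  n <- length(drugs)
  tibble::tibble(
    report_id = sprintf("R%d", seq_len(n)),
    case_id = sprintf("C%d", seq_len(n)),
    receipt_date = as.Date("2020-01-01") + seq_len(n),
    drugs = lapply(drugs, function(d) c(primary_suspect = d)),
    pts = pts,
    sex = "female", age_years = NA_real_, country = NA_character_,
    indication = NA_character_, outcomes = rep(list(character(0)), n),
    dose_mg_per_day = NA_real_, year = 2020L)
}

test_that("the enumerated four-report example yields the expected cells", {
  r <- toy_reports(c("X", "X", "Y", "Y"),
                   list("diarrhoea", "nausea", "diarrhoea", "rash"))
  tab <- build_table(r, "X", "diarrhoea")
  expect_equal(unlist(tab[c("a", "b", "c", "d")]), c(a = 1, b = 1, c = 1, d = 1))
})

test_that("absent drugs give zero drug-row cells, and cell sums are conserved", {
  r <- toy_reports(c("X", "X", "Y"), list("diarrhoea", "nausea", "rash"))
  tab <- build_table(r, "NOSUCH", "diarrhoea")
  expect_equal(tab$a + tab$b, 0)
  expect_equal(tab$c + tab$d, 3)
  expect_equal(nrow(build_all_tables(r, "NOSUCH")), 0)

  sim <- simulate_reports(test_config(300, seed = 21))
  tabs <- build_all_tables(sim$reports, "TYVERINE")
  expect_true(all(tabs$a + tabs$b + tabs$c + tabs$d == 300))
  expect_true(all(tabs[c("a", "b", "c", "d")] >= 0))
})

test_that("a report with the drug in two roles counts once in the drug row", {
  r <- toy_reports(c("X", "Y"), list("rash", "rash"))
  r$drugs[[1]] <- c(primary_suspect = "X", concomitant = "X")
  tab <- build_table(r, "X", "rash")
  expect_equal(unlist(tab[c("a", "b", "c", "d")]), c(a = 1, b = 0, c = 1, d = 0))
})

test_that("build_all_tables equals the double-loop recount on random sets", {
  # property: exact equality against the naive oracle across >= 50
  # randomly parameterised synthetic configurations
  for (k in seq_len(50)) {
    set.seed(3000 + k)
    n <- sample(40:150, 1)
    drugs <- demo_drug_vocabulary()[seq_len(sample(3:8, 1)), ]
    drugs$prob <- drugs$prob / sum(drugs$prob)
    pts <- demo_pt_vocabulary()[sample.int(40, sample(8:15, 1)), ]
    pts$prob <- pts$prob / sum(pts$prob)
    epr <- min(runif(1, 1, 3), 0.9 / max(pts$prob))
    cfg <- sim_config(n_cases = n, drugs = drugs, pts = pts,
                      events_per_report = epr, seed = 3000 + k)
    r <- simulate_reports(cfg)$reports
    drug <- sample(drugs$name, 1)
    got <- build_all_tables(r, drug)
    want <- brute_tables(r, drug)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
    }
  }
})

test_that("permuting report order never changes a table", {
  sim <- simulate_reports(test_config(200, seed = 31))
  tabs <- build_all_tables(sim$reports, "TYVERINE")
  set.seed(1)
  shuffled <- sim$reports[sample.int(200), ]
  expect_equal(build_all_tables(shuffled, "TYVERINE"), tabs)
})

test_that("per-PT report counts recount to total drug incidences", {
  sim <- simulate_reports(test_config(1000, seed = 41))
  r <- sim$reports
  tabs <- build_all_tables(r, "TYVERINE")
  drug_set <- filter_primary_suspect(r, "TYVERINE")
  expect_equal(sum(tabs$a), sum(lengths(drug_set$pts)))
  # and each row agrees with the scalar builder
  for (i in sample.int(nrow(tabs), 5)) {
    expect_equal(build_table(r, "TYVERINE", tabs$pt[i]),
                 tabs[i, ], ignore_attr = TRUE)
  }
})
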