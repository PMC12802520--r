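test_that("identical configurations give byte-identical report sets", {
  cfg <- function() test_config(1000, seed = 7,
                                planted = tibble::tibble(drug = "TYVERINE",
                                                         pt = "Milia",
                                                         lambda = 5),
                                duplicate_fraction = 0.15)
  s1 <- simulate_reports(cfg())
  s2 <- simulate_reports(cfg())
  expect_identical(s1$reports, s2$reports)
  expect_identical(s1$ground_truth, s2$ground_truth)
})

test_that("generated reports satisfy the structural contract", {
  sim <- simulate_reports(test_config(400, seed = 3))
  r <- sim$reports
  expect_equal(nrow(r), 400)
  expect_false(anyDuplicated(r$report_id) > 0)
  # exactly one primary suspect per report, at least one distinct PT
  n_ps <- vapply(r$drugs, function(d) sum(names(d) == "primary_suspect"),
                 integer(1))
  expect_true(all(n_ps == 1L))
  expect_true(all(lengths(r$pts) >= 1L))
  expect_true(all(vapply(r$pts, anyDuplicated, integer(1)) == 0L))
  expect_true(all(r$sex %in% c("female", "male", "not_specified")))
  expect_true(all(is.na(r$age_years) | r$age_years >= 0))
})

test_that("realized ground-truth tables agree with a brute-force recount", {
  planted <- tibble::tibble(drug = c("TYVERINE", "COMPARATOR_01"),
                            pt = c("Milia", "Pneumonia"),
                            lambda = c(8, 3))
  sim <- simulate_reports(test_config(600, seed = 11, planted = planted))
  for (k in seq_len(nrow(planted))) {
    brute <- brute_tables(sim$reports, planted$drug[k])
    brute <- brute[brute$pt == planted$pt[k], ]
    got <- sim$ground_truth$realized_tables[k, ]
    expect_equal(unlist(got[c("a", "b", "c", "d")]),
                 unlist(brute[c("a", "b", "c", "d")]),
                 ignore_attr = TRUE)
  }
})

test_that("planted configuration errors are caught", {
  expect_error(test_config(10, 1,
                           planted = tibble::tibble(drug = "NOSUCH",
                                                    pt = "Milia", lambda = 2)),
               "unknown vocabulary")
  expect_error(test_config(10, 1,
                           planted = tibble::tibble(drug = "TYVERINE",
                                                    pt = "Milia", lambda = -1)),
               "lambda")
  bad_drugs <- demo_drug_vocabulary()
  bad_drugs$prob[1] <- bad_drugs$prob[1] + 0.1
  expect_error(sim_config(10, drugs = bad_drugs, seed = 1), "sum to 1")
})

test_that("duplicate injection adds superseded versions and dedup removes them", {
  sim <- simulate_reports(test_config(300, seed = 5))
  r <- sim$reports

  expect_identical(inject_duplicates(r, 0, seed = 1), r)

  all_dup <- inject_duplicates(r, 1, seed = 2)
  expect_equal(nrow(all_dup), 600)
  expect_true(all(table(all_dup$case_id) == 2L))

  some <- inject_duplicates(r, 0.2, seed = 3)
  n_extra <- nrow(some) - 300
  expect_true(n_extra > 0)
  expect_equal(sum(table(some$case_id) == 2L), n_extra)
  # duplicates differ only in report id and receipt date
  dups <- some[grepl("-0$", some$report_id), ]
  orig <- r[match(dups$case_id, r$case_id), ]
  expect_true(all(dups$receipt_date < orig$receipt_date))
  expect_identical(dups$pts, orig$pts)

  dd <- deduplicate(some)
  expect_equal(nrow(dd), 300)
  expect_setequal(dd$report_id, r$report_id)
})

test_that("duplicate_fraction outside [0, 1] is rejected", {
  sim <- simulate_reports(test_config(10, seed = 1))
  expect_error(inject_duplicates(sim$reports, 1.5), "\\[0, 1\\]")
})

test_that("fixture round-trips preserve every field in both dialects", {
  sim <- simulate_reports(test_config(500, seed = 13, duplicate_fraction = 0.1))
  r <- sim$reports
  for (dialect in c("wide", "long")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_reports(r, path, dialect = dialect)
    back <- read_reports(path, dialect = dialect)
    expect_equal(nrow(back), nrow(r))
    expect_equal(nrow(reject_report(back)), 0)
    for (col in c("report_id", "case_id", "sex", "country", "indication")) {
      expect_identical(back[[col]], r[[col]], label = paste(dialect, col))
    }
    expect_equal(back$age_years, r$age_years)
    expect_equal(back$dose_mg_per_day, r$dose_mg_per_day)
    expect_identical(back$receipt_date, r$receipt_date)
    expect_identical(back$year, as.integer(r$year))
    expect_identical(lapply(back$pts, sort), lapply(r$pts, sort))
    expect_identical(back$outcomes, r$outcomes)
    expect_identical(back$drugs, r$drugs)
  }
})

test_that("an empty report set writes a header-only fixture", {
  sim <- simulate_reports(test_config(5, seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture(sim$reports[0, ], path)
  expect_equal(length(readLines(path)), 1L)
  back <- read_reports(path)
  expect_equal(nrow(back), 0)
})

test_that("with all lambda = 1 the realized odds ratio is centred on 1", {
  # 200 replicates; expected a ~ 35 per replicate. The mean of the realized
  # ROR is allowed a margin of 3 Monte-Carlo standard errors plus the
  # O(s^2/2) upward bias of a ratio estimator (~2% here).
  rors <- vapply(seq_len(200), function(rep) {
    sim <- simulate_reports(
      test_config(2000, seed = 1000 + rep,
                  planted = tibble::tibble(drug = "TYVERINE",
                                           pt = "Diarrhoea", lambda = 1))
    )
    tab <- sim$ground_truth$realized_tables
    with(tab, a * d / (b * c))
  }, numeric(1))
  expect_lt(abs(mean(rors) - 1), 0.08)
})

test_that("the realized ROR recovers a planted odds multiplier of 10", {
  # background inclusion probability 0.01 for the planted term, n = 5000
  # with a 20% drug share: expected a is ~ 90, and the realized 95% CI
  # should cover the planted value in at least 93 of 100 replicates
  # (nominal coverage 95%).
  pts <- tibble::tibble(pt = sprintf("PT%03d", 1:100), prob = rep(0.01, 100))
  drugs <- demo_drug_vocabulary()
  drugs$prob <- c(0.2, rep(0.8 / 9, 9))
  hits <- 0L
  rors <- numeric(100)
  for (rep in seq_len(100)) {
    cfg <- sim_config(n_cases = 5000, drugs = drugs, pts = pts,
                      planted = tibble::tibble(drug = "TYVERINE",
                                               pt = "PT050", lambda = 10),
                      events_per_report = 1, seed = 2000 + rep)
    tab <- simulate_reports(cfg)$ground_truth$realized_tables
    est <- ror_statistic(tab$a, tab$b, tab$c, tab$d)
    rors[rep] <- est$ror
    if (!is.na(est$ror_low) && est$ror_low <= 10 && est$ror_high >= 10) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 93)
  expect_lt(abs(mean(rors) - 10) / 10, 0.10)
})
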