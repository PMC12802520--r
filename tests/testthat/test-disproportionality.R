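# Frozen hand evaluations of the published formulas on (10, 90, 100, 9900):
#   ROR = 10*9900/(90*100) = 11;  s = sqrt(1/10+1/90+1/100+1/9900) = 0.348155
#   CI  = exp(ln 11 -/+ 1.96 s)  = (5.5595, 21.7645)
#   PRR = 10*10000/(100*100) = 10; chi2 = 74.4472
#   IC  = log2(10*10100/(110*100)) = 3.19878; IC025 = exp(ln IC - 1.96 s) = 1.61670
#   EBGM = 9.18182; EBGM05 = exp(ln EBGM - 1.64 s) = 5.18749
test_that("the worked 2x2 example reproduces the printed-formula values", {
  expect_equal(ror_statistic(10, 90, 100, 9900),
               tibble::tibble(ror = 11, ror_low = 5.559515, ror_high = 21.764489,
                              ror_defined = TRUE),
               tolerance = 1e-6)
  p <- prr_statistic(10, 90, 100, 9900)
  expect_equal(p$prr, 10)
  expect_equal(p$chi2, 74.447174, tolerance = 1e-6)
  bc <- bcpnn_statistic(10, 90, 100, 9900)
  expect_equal(bc$ic, 3.198780, tolerance = 1e-6)
  expect_equal(bc$ic025, 1.616697, tolerance = 1e-6)
  mg <- mgps_statistic(10, 90, 100, 9900)
  expect_equal(mg$ebgm, 9.181818, tolerance = 1e-6)
  expect_equal(mg$ebgm05, 5.187493, tolerance = 1e-6)
})

test_that("balanced tables are null under every algorithm", {
  st <- signal_statistics(tibble::tibble(a = 5, b = 5, c = 5, d = 5))
  expect_equal(st$ror, 1)
  expect_equal(st$prr, 1)
  expect_equal(st$chi2, 0)
  expect_equal(st$ic, 0)
  expect_equal(st$ebgm, 1)
  expect_true(is.na(st$ic025))  # IC <= 0: no multiplicative lower bound
  dec <- evaluate_significance(st)
  expect_false(any(dec$sig_ror, dec$sig_prr, dec$sig_bcpnn, dec$sig_mgps))
})

test_that("zero cells flag statistics undefined unless continuity-corrected", {
  st <- ror_statistic(0, 10, 10, 100)
  expect_false(st$ror_defined)
  expect_true(is.na(st$ror))
  cc <- ror_statistic(0, 10, 10, 100, continuity = TRUE)
  expect_true(cc$ror_defined)
  expect_equal(cc$ror, 0.5 * 100.5 / (10.5 * 10.5))
  # undefined statistics are never significant
  dec <- evaluate_significance(signal_statistics(
    tibble::tibble(a = 0, b = 10, c = 10, d = 100)))
  expect_false(dec$sig_all)
})

test_that("all four statistics match the independent oracle on random tables", {
  set.seed(42)
  n <- 1000
  tabs <- tibble::tibble(a = sample(1:500, n, TRUE), b = sample(1:5000, n, TRUE),
                         c = sample(1:5000, n, TRUE), d = sample(1:50000, n, TRUE))
  st <- signal_statistics(tabs)
  for (i in seq_len(n)) {
    o <- oracle_stats(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    for (f in c("ror", "ror_low", "ror_high", "prr", "prr_low", "prr_high",
                "chi2", "ic", "ebgm", "ebgm05", "s")) {
      expect_equal(st[[f]][i], o[[f]], tolerance = 1e-10)
    }
    if (!is.na(o$ic025)) expect_equal(st$ic025[i], o$ic025, tolerance = 1e-10)
    else expect_true(is.na(st$ic025[i]))
  }
  # algebraic identity: the unshrunk EBGM is exactly 2^IC
  expect_equal(st$ebgm, 2^st$ic, tolerance = 1e-12)
})

test_that("chi-square is invariant under the (a<->d, b<->c) symmetry", {
  set.seed(7)
  a <- sample(1:50, 20, TRUE); b <- sample(1:500, 20, TRUE)
  c_ <- sample(1:500, 20, TRUE); d <- sample(1:5000, 20, TRUE)
  expect_equal(prr_statistic(a, b, c_, d)$chi2, prr_statistic(d, c_, b, a)$chi2)
})

test_that("IC is invariant under doubling all cells; monotone in a", {
  bc1 <- bcpnn_statistic(12, 88, 140, 9000)
  bc2 <- bcpnn_statistic(24, 176, 280, 18000)
  expect_equal(bc1$ic, bc2$ic)
  # increasing a with b, c, d fixed strictly increases every point estimate
  a <- 5:40
  st <- signal_statistics(tibble::tibble(a = a, b = 100, c = 50, d = 5000))
  expect_true(all(diff(st$ror) > 0))
  expect_true(all(diff(st$prr) > 0))
  expect_true(all(diff(st$ic) > 0))
  expect_true(all(diff(st$ebgm) > 0))
})

test_that("interval bounds bracket the point estimates when s > 0", {
  set.seed(11)
  tabs <- tibble::tibble(a = sample(2:100, 200, TRUE), b = sample(1:1000, 200, TRUE),
                         c = sample(1:1000, 200, TRUE), d = sample(1:20000, 200, TRUE))
  st <- signal_statistics(tabs)
  expect_true(all(st$ror_low < st$ror & st$ror < st$ror_high))
  expect_true(all(st$prr_low < st$prr & st$prr < st$prr_high))
  expect_true(all(st$ebgm05 < st$ebgm))
})

test_that("significance gates apply the printed criteria", {
  st <- evaluate_significance(signal_statistics(
    tibble::tibble(a = 10, b = 90, c = 100, d = 9900)))
  expect_true(all(st$sig_ror, st$sig_prr, st$sig_bcpnn, st$sig_mgps, st$sig_all))

  # n = 2 with otherwise strong statistics fails the N >= 3 gate
  st2 <- evaluate_significance(signal_statistics(
    tibble::tibble(a = 2, b = 10, c = 10, d = 10000)))
  expect_true(st2$ror > 1)
  expect_false(st2$sig_all)
})

test_that("intensity bands follow the published cut-points", {
  grade <- function(a, b, c, d) {
    grade_intensity(evaluate_significance(signal_statistics(
      tibble::tibble(a = a, b = b, c = c, d = d))))
  }
  # ROR 11 lands in the medium band (10, 50]
  g <- grade(10, 90, 100, 9900)
  expect_equal(as.character(g$int_ror), "medium")
  expect_equal(as.character(g$int_prr), "weak")     # PRR 10 is in (2, 10]
  expect_equal(as.character(g$int_bcpnn), "medium") # IC025 1.62 in (1.5, 3]
  expect_equal(as.character(g$int_mgps), "weak")    # EBGM05 5.19 in (2, 10]

  # a large-ROR pair grades strong on the ROR scale
  g2 <- grade(12, 5, 30, 17000)
  expect_gt(g2$ror, 50)
  expect_equal(as.character(g2$int_ror), "strong")

  # nonsignificant pairs always grade none
  g3 <- grade(5, 5, 5, 5)
  expect_true(all(g3$int_ror == "none", g3$int_prr == "none",
                  g3$int_bcpnn == "none", g3$int_mgps == "none"))
})

# Reference rows from a published lapatinib FAERS disproportionality profile
# (the five highest-count terms). Values as printed at two decimals.
reference_rows <- tibble::tribble(
  ~pt,        ~n,    ~ic,  ~ebgm,
  "Diarrhea",  2444, 3.48, 11.13,
  "Nausea",     886, 1.63, 3.09,
  "Fatigue",    680, 1.31, 2.48,
  "Vomiting",   623, 1.94, 3.84,
  "Rash",       614, 1.92, 3.80
)

test_that("2^IC is consistent with printed EBGM within rounding on reference rows", {
  # both columns are rounded to 2 decimals, so the intervals
  # 2^[ic - 0.005, ic + 0.005] and [ebgm - 0.005, ebgm + 0.005] must overlap
  for (i in seq_len(nrow(reference_rows))) {
    lo <- 2^(reference_rows$ic[i] - 0.005)
    hi <- 2^(reference_rows$ic[i] + 0.005)
    expect_true(lo <= reference_rows$ebgm[i] + 0.005 &&
                  hi >= reference_rows$ebgm[i] - 0.005,
                label = reference_rows$pt[i])
  }
})

test_that("the shared s recovered from a printed ROR CI reproduces EBGM05", {
  # diarrhoea row: ROR CI (14.60, 16.04), EBGM 11.13, printed EBGM05 10.70
  s <- log(16.04 / 14.60) / (2 * 1.96)
  ebgm05 <- exp(log(11.13) - 1.64 * s)
  expect_lt(abs(ebgm05 - 10.70), 0.01)
})
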