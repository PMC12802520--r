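#' Disproportionality statistics for 2x2 report counts
#'
#' The four classical signal-detection algorithms of pharmacovigilance,
#' computed exactly from the report-level 2x2 table (see [build_table()]):
#'
#' * **ROR** (reporting odds ratio): `ad / bc`, with
#'   `95% CI = exp(ln ROR +/- 1.96 s)` where
#'   `s = sqrt(1/a + 1/b + 1/c + 1/d)` is the shared standard-error term.
#' * **PRR** (proportional reporting ratio): `a(c+d) / (c(a+b))`, same
#'   multiplicative interval, plus the chi-square statistic
#'   `(ad - bc)^2 (a+b+c+d) / ((a+b)(c+d)(a+c)(b+d))` (no continuity
#'   correction).
#' * **BCPNN information component**: `IC = log2(a T / ((a+c)(a+b)))` with
#'   `T = a+b+c+d`; the lower bound is the multiplicative interval applied
#'   to the IC point value itself, `IC025 = exp(ln IC - 1.96 s)`, defined
#'   only when `IC > 0`. (The conventional additive interval
#'   `IC - 1.96 s` is available via `bcpnn_interval = "additive"`; the
#'   multiplicative form is the default because it is what the package's
#'   reference tables use. Under it, `IC025 > 0` whenever `IC > 0`.)
#' * **MGPS EBGM**: the unshrunk relative reporting ratio
#'   `EBGM = a T / ((a+c)(a+b))`, so `EBGM = 2^IC` exactly, with
#'   `EBGM05 = exp(ln EBGM - 1.64 s)`. Gamma-Poisson shrinkage with a
#'   fitted prior is deliberately out of scope.
#'
#' Zero cells leave the affected statistic flagged undefined (all
#' `*_defined` flags require the shared standard error to be finite, i.e.
#' all four cells positive) unless `continuity = TRUE`, which applies the
#' Haldane-Anscombe correction (adds 0.5 to every cell) before computing.
#' Undefined statistics are never significant.
#'
#' All functions are vectorized over `a`, `b`, `c`, `d`.
#'
#' @param a,b,c,d Cell counts (equal-length numeric vectors).
#' @param continuity Apply the +0.5 continuity correction first.
#' @param bcpnn_interval `"multiplicative"` (default) or `"additive"`
#'   form of the IC lower bound.
#' @return Each `*_statistic` function returns a tibble with the point
#'   estimate(s), interval bound(s), and a `*_defined` flag.
#' @name disproportionality
#' @examples
#' ror_statistic(10, 90, 100, 9900)
#' with(prr_statistic(10, 90, 100, 9900), c(prr, chi2))
NULL

correct_cells <- function(a, b, c, d, continuity) {
  if (continuity) list(a = a + 0.5, b = b + 0.5, c = c + 0.5, d = d + 0.5)
  else list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
            d = as.numeric(d))
}

#' Shared standard-error term of the 2x2 table
#'
#' `s = sqrt(1/a + 1/b + 1/c + 1/d)`, the term shared by all four
#' algorithms' interval formulas. Infinite when any cell is zero.
#'
#' @inheritParams disproportionality
#' @return Numeric vector.
#' @export
shared_se <- function(a, b, c, d) {
  sqrt(1 / a + 1 / b + 1 / c + 1 / d)
}

#' @rdname disproportionality
#' @export
ror_statistic <- function(a, b, c, d, continuity = FALSE) {
  x <- correct_cells(a, b, c, d, continuity)
  defined <- x$a > 0 & x$b > 0 & x$c > 0 & x$d > 0
  s <- shared_se(x$a, x$b, x$c, x$d)
  ror <- x$a * x$d / (x$b * x$c)
  tibble(
    ror = ifelse(defined, ror, NA_real_),
    ror_low = ifelse(defined, exp(log(ror) - 1.96 * s), NA_real_),
    ror_high = ifelse(defined, exp(log(ror) + 1.96 * s), NA_real_),
    ror_defined = defined
  )
}

#' @rdname disproportionality
#' @export
prr_statistic <- function(a, b, c, d, continuity = FALSE) {
  x <- correct_cells(a, b, c, d, continuity)
  defined <- x$a > 0 & x$b > 0 & x$c > 0 & x$d > 0
  s <- shared_se(x$a, x$b, x$c, x$d)
  t_ <- x$a + x$b + x$c + x$d
  prr <- x$a * (x$c + x$d) / (x$c * (x$a + x$b))
  chi2 <- (x$a * x$d - x$b * x$c)^2 * t_ /
    ((x$a + x$b) * (x$c + x$d) * (x$a + x$c) * (x$b + x$d))
  tibble(
    prr = ifelse(defined, prr, NA_real_),
    prr_low = ifelse(defined, exp(log(prr) - 1.96 * s), NA_real_),
    prr_high = ifelse(defined, exp(log(prr) + 1.96 * s), NA_real_),
    chi2 = ifelse(defined, chi2, NA_real_),
    prr_defined = defined
  )
}

#' @rdname disproportionality
#' @export
bcpnn_statistic <- function(a, b, c, d, continuity = FALSE,
                            bcpnn_interval = c("multiplicative", "additive")) {
  bcpnn_interval <- match.arg(bcpnn_interval)
  x <- correct_cells(a, b, c, d, continuity)
  defined <- x$a > 0 & x$b > 0 & x$c > 0 & x$d > 0
  s <- shared_se(x$a, x$b, x$c, x$d)
  t_ <- x$a + x$b + x$c + x$d
  ic <- log2(x$a * t_ / ((x$a + x$c) * (x$a + x$b)))
  ic025 <- if (bcpnn_interval == "multiplicative") {
    # multiplicative interval on the IC point value; requires IC > 0
    out <- rep(NA_real_, length(ic))
    pos <- !is.na(ic) & ic > 0
    out[pos] <- exp(log(ic[pos]) - 1.96 * s[pos])
    out
  } else {
    ic - 1.96 * s
  }
  tibble(
    ic = ifelse(defined, ic, NA_real_),
    ic025 = ifelse(defined, ic025, NA_real_),
    ic_defined = defined
  )
}

#' @rdname disproportionality
#' @export
mgps_statistic <- function(a, b, c, d, continuity = FALSE) {
  x <- correct_cells(a, b, c, d, continuity)
  defined <- x$a > 0 & x$b > 0 & x$c > 0 & x$d > 0
  s <- shared_se(x$a, x$b, x$c, x$d)
  t_ <- x$a + x$b + x$c + x$d
  ebgm <- x$a * t_ / ((x$a + x$c) * (x$a + x$b))
  tibble(
    ebgm = ifelse(defined, ebgm, NA_real_),
    ebgm05 = ifelse(defined, exp(log(ebgm) - 1.64 * s), NA_real_),
    ebgm_defined = defined
  )
}

#' Compute all four disproportionality statistics for a table set
#'
#' Binds the output of [ror_statistic()], [prr_statistic()],
#' [bcpnn_statistic()] and [mgps_statistic()] onto a table of 2x2 counts
#' (as produced by [build_all_tables()]), together with `n = a` and the
#' shared standard error. Full precision is retained; rounding happens
#' only at presentation.
#'
#' @param tables Tibble with columns `a`, `b`, `c`, `d` (and typically
#'   `drug`, `pt`).
#' @inheritParams disproportionality
#' @return `tables` with statistic columns appended.
#' @export
signal_statistics <- function(tables, continuity = FALSE,
                              bcpnn_interval = "multiplicative") {
  x <- correct_cells(tables$a, tables$b, tables$c, tables$d, continuity)
  out <- dplyr::bind_cols(
    tables,
    tibble(n = as.integer(tables$a),
           s = shared_se(x$a, x$b, x$c, x$d)),
    ror_statistic(tables$a, tables$b, tables$c, tables$d, continuity),
    prr_statistic(tables$a, tables$b, tables$c, tables$d, continuity),
    bcpnn_statistic(tables$a, tables$b, tables$c, tables$d, continuity,
                    bcpnn_interval),
    mgps_statistic(tables$a, tables$b, tables$c, tables$d, continuity)
  )
  out
}

#' Apply the four significance criteria
#'
#' The positivity gates used for signal detection, applied per method with
#' a global minimum report count of `n >= 3`:
#'
#' * ROR: lower 95% bound > 1;
#' * PRR: lower 95% bound > 1, `PRR >= 2`, `chi2 >= 4`;
#' * BCPNN: `IC > 0` and `IC025 > 0`;
#' * MGPS: `EBGM05 > 2`.
#'
#' A pair is a combined signal only when all four methods are positive.
#' Undefined statistics are nonsignificant.
#'
#' @param stats Tibble from [signal_statistics()].
#' @return `stats` with logical columns `sig_ror`, `sig_prr`, `sig_bcpnn`,
#'   `sig_mgps`, `sig_all`.
#' @export
evaluate_significance <- function(stats) {
  def <- function(x) !is.na(x)
  n_ok <- stats$n >= 3
  stats$sig_ror <- def(stats$ror_low) & stats$ror_low > 1 & n_ok
  stats$sig_prr <- def(stats$prr_low) & stats$prr_low > 1 &
    stats$prr >= 2 & stats$chi2 >= 4 & n_ok
  stats$sig_bcpnn <- def(stats$ic) & stats$ic > 0 &
    def(stats$ic025) & stats$ic025 > 0 & n_ok
  stats$sig_mgps <- def(stats$ebgm05) & stats$ebgm05 > 2 & n_ok
  stats$sig_all <- stats$sig_ror & stats$sig_prr & stats$sig_bcpnn &
    stats$sig_mgps
  stats
}

intensity_band <- function(x, edges, significant) {
  out <- rep("none", length(x))
  ok <- significant & !is.na(x)
  out[ok & x > edges[1] & x <= edges[2]] <- "weak"
  out[ok & x > edges[2] & x <= edges[3]] <- "medium"
  out[ok & x > edges[3]] <- "strong"
  factor(out, levels = c("none", "weak", "medium", "strong"))
}

#' Grade per-method signal intensity
#'
#' Band membership per method (nonsignificant pairs grade `none`):
#'
#' | method | scale   | weak        | medium      | strong |
#' |--------|---------|-------------|-------------|--------|
#' | ROR    | `ror`   | (2, 10]     | (10, 50]    | > 50   |
#' | PRR    | `prr`   | (2, 10]     | (10, 50]    | > 50   |
#' | BCPNN  | `ic025` | (0, 1.5]    | (1.5, 3]    | > 3    |
#' | MGPS   | `ebgm05`| (2, 10]     | (10, 30]    | > 30   |
#'
#' @param stats Tibble from [evaluate_significance()].
#' @return `stats` with ordered-factor columns `int_ror`, `int_prr`,
#'   `int_bcpnn`, `int_mgps`.
#' @export
grade_intensity <- function(stats) {
  stats$int_ror <- intensity_band(stats$ror, c(2, 10, 50), stats$sig_ror)
  stats$int_prr <- intensity_band(stats$prr, c(2, 10, 50), stats$sig_prr)
  stats$int_bcpnn <- intensity_band(stats$ic025, c(0, 1.5, 3), stats$sig_bcpnn)
  stats$int_mgps <- intensity_band(stats$ebgm05, c(2, 10, 30), stats$sig_mgps)
  stats
}
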