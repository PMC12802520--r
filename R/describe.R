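#' Default country-to-region assignment
#'
#' Reads the small region lookup shipped with the package (ISO-3166
#' alpha-2 codes for the most frequent reporter countries, mapped to
#' continental regions). Users with other country codings supply their
#' own named vector.
#'
#' @return Named character vector, `country -> region`.
#' @export
default_region_map <- function() {
  path <- system.file("extdata", "country_regions.tsv", package = "pvsignal")
  map <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  setNames(map$region, map$country)
}

#' Descriptive summary of a report set
#'
#' Clinical-characteristics summary in the conventional layout: counts and
#' two-decimal percentages for sex levels, age bands (`<18`, `18-64`,
#' `>=65`, not specified), reporter regions and named countries, top
#' indications, reporting years, and the six outcome classes. Every
#' percentage uses the full report total as denominator, including
#' not-specified levels; a report with several outcome classes counts once
#' per class, so outcome percentages need not sum to 100.
#'
#' @param reports Deduplicated report tibble.
#' @param region_map Named character vector assigning countries to
#'   regions; unmapped countries are summarised as `not_specified` with a
#'   warning.
#' @param top_indications Number of indication levels to report.
#' @return Tibble with columns `section`, `level`, `count`, `percent`;
#'   the first row carries the report total.
#' @export
describe_reports <- function(reports, region_map = default_region_map(),
                             top_indications = 5) {
  total <- nrow(reports)
  pc <- function(n) percent_of(n, total)
  row_block <- function(section, level, count) {
    tibble(section = section, level = level,
           count = as.integer(count), percent = pc(count))
  }
  out <- list(tibble(section = "total", level = "total",
                     count = total, percent = if (total > 0) 100 else 0))

  sex_counts <- vapply(.sex_levels, function(s) sum(reports$sex == s, na.rm = TRUE),
                       numeric(1))
  out$sex <- row_block("sex", .sex_levels, sex_counts)

  age <- reports$age_years
  age_counts <- c("<18" = sum(age < 18, na.rm = TRUE),
                  "18-64" = sum(age >= 18 & age < 65, na.rm = TRUE),
                  ">=65" = sum(age >= 65, na.rm = TRUE),
                  "not_specified" = sum(is.na(age)))
  out$age <- row_block("age", names(age_counts), age_counts)

  country <- reports$country
  region <- unname(region_map[country])
  unmapped <- !is.na(country) & is.na(region)
  if (any(unmapped)) {
    warning("unmapped reporter countries summarised as not_specified: ",
            paste(unique(country[unmapped]), collapse = ", "), call. = FALSE)
  }
  region[is.na(region)] <- "not_specified"
  reg_tab <- sort(table(region), decreasing = TRUE)
  reg_tab <- c(reg_tab[setdiff(names(reg_tab), "not_specified")],
               reg_tab[intersect(names(reg_tab), "not_specified")])
  out$region <- row_block("region", names(reg_tab), as.integer(reg_tab))

  ctry_tab <- sort(table(country[!is.na(country)]), decreasing = TRUE)
  if (length(ctry_tab) > 0) {
    out$country <- row_block("country", names(ctry_tab), as.integer(ctry_tab))
  }

  ind <- ifelse(is.na(reports$indication), "not_specified", reports$indication)
  ind_tab <- sort(table(ind), decreasing = TRUE)
  ind_tab <- head(ind_tab, top_indications)
  out$indication <- row_block("indication", names(ind_tab), as.integer(ind_tab))

  if (total > 0) {
    yr_tab <- table(factor(reports$year))
    out$year <- row_block("year", rev(names(yr_tab)), rev(as.integer(yr_tab)))
  }

  outc <- unlist(reports$outcomes)
  outc_counts <- vapply(.outcome_levels, function(o) sum(outc == o), numeric(1))
  out$outcome <- row_block("outcome", .outcome_levels, outc_counts)

  bind_rows(out)
}
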