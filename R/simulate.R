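#' Configuration for the synthetic report generator
#'
#' Builds and validates the configuration object consumed by
#' [simulate_reports()]. The generator emulates the seven record classes of
#' a spontaneous-report extract (demographics, drug records, indications,
#' adverse-event terms, outcomes, therapy dates, report source) for a
#' dominant-indication, female-skewed population, and can plant drug-event
#' disproportionality of known magnitude.
#'
#' Signals are planted on the odds scale: for a planted `(drug, pt, lambda)`
#' triple, the per-report odds of listing `pt` among reports whose primary
#' suspect is `drug` are `lambda` times the background odds, so the
#' population reporting odds ratio of the pair equals `lambda` exactly.
#'
#' @param n_cases Number of unique cases to generate (before optional
#'   duplicate injection).
#' @param drugs Tibble with columns `name` and `prob` (primary-suspect
#'   marginal probabilities, summing to 1).
#' @param pts Tibble with columns `pt`, `prob` (background categorical
#'   probabilities summing to 1) and optionally `soc`, `soc_code`.
#' @param planted Tibble with columns `drug`, `pt`, `lambda`
#'   (odds multipliers, `lambda >= 0`). Defaults to no planted signals.
#' @param events_per_report Mean number of PTs per report. Each PT is
#'   included independently with probability `prob * events_per_report`
#'   (all such probabilities must stay below 1); reports that draw no PT
#'   receive one PT from the background categorical, so every report
#'   carries at least one event.
#' @param concomitant_prob Probability that a report lists one additional
#'   concomitant drug besides the primary suspect.
#' @param sex_probs Named probabilities for `female`, `male`,
#'   `not_specified`.
#' @param age_mean,age_sd Normal age model in years, truncated at 0.
#' @param age_missing_prob Fraction of reports with missing age.
#' @param countries Tibble with columns `country`, `prob`; the country
#'   `"not_specified"` models a missing reporter country.
#' @param indications Tibble with columns `indication`, `prob`, including
#'   an unknown-indication level.
#' @param outcome_probs Named probabilities over the six outcome classes
#'   (`death`, `disability`, `hospitalisation`, `life_threatening`,
#'   `required_intervention`, `other`) plus `none`.
#' @param dose_levels,dose_probs Daily-dose levels (mg) and their
#'   probabilities; an `NA` level models missing dose.
#' @param duplicate_fraction Probability in `[0, 1]` that a case emits an
#'   extra superseded report version (see [inject_duplicates()]).
#' @param year_range Inclusive receipt-year span, length-2 integer.
#' @param seed Integer seed; identical configurations give byte-identical
#'   output.
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_cases = 500, seed = 1)
#' sim <- simulate_reports(cfg)
#' nrow(sim$reports)
sim_config <- function(n_cases,
                       drugs = demo_drug_vocabulary(),
                       pts = demo_pt_vocabulary(),
                       planted = tibble(drug = character(), pt = character(),
                                        lambda = numeric()),
                       events_per_report = 2,
                       concomitant_prob = 0.3,
                       sex_probs = c(female = 0.78, male = 0.04, not_specified = 0.18),
                       age_mean = 58, age_sd = 12,
                       age_missing_prob = 0.43,
                       countries = demo_country_distribution(),
                       indications = demo_indication_distribution(),
                       outcome_probs = c(death = 0.13, disability = 0.015,
                                         hospitalisation = 0.28,
                                         life_threatening = 0.03,
                                         required_intervention = 0.002,
                                         other = 0.36, none = 0.183),
                       dose_levels = c(1000, 1250, 1500, NA),
                       dose_probs = c(0.15, 0.5, 0.1, 0.25),
                       duplicate_fraction = 0,
                       year_range = c(2007, 2024),
                       seed = 1) {
  cfg <- list(n_cases = n_cases, drugs = as_tibble(drugs), pts = as_tibble(pts),
              planted = as_tibble(planted), events_per_report = events_per_report,
              concomitant_prob = concomitant_prob, sex_probs = sex_probs,
              age_mean = age_mean, age_sd = age_sd,
              age_missing_prob = age_missing_prob,
              countries = as_tibble(countries), indications = as_tibble(indications),
              outcome_probs = outcome_probs,
              dose_levels = dose_levels, dose_probs = dose_probs,
              duplicate_fraction = duplicate_fraction,
              year_range = as.integer(year_range), seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("probabilities for ", what, " must be nonnegative and sum to 1",
           call. = FALSE)
    }
  }
  if (!is.numeric(cfg$n_cases) || cfg$n_cases < 1) {
    stop("`n_cases` must be a positive integer", call. = FALSE)
  }
  check_probs(cfg$drugs$prob, "drugs")
  check_probs(cfg$pts$prob, "pts")
  check_probs(cfg$sex_probs, "sex")
  check_probs(cfg$countries$prob, "countries")
  check_probs(cfg$indications$prob, "indications")
  check_probs(cfg$outcome_probs, "outcomes")
  check_probs(cfg$dose_probs, "dose")
  if (cfg$duplicate_fraction < 0 || cfg$duplicate_fraction > 1) {
    stop("`duplicate_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (nrow(cfg$planted) > 0) {
    if (any(cfg$planted$lambda < 0)) {
      stop("planted `lambda` must be >= 0", call. = FALSE)
    }
    bad_drug <- setdiff(cfg$planted$drug, cfg$drugs$name)
    bad_pt <- setdiff(cfg$planted$pt, cfg$pts$pt)
    if (length(bad_drug) || length(bad_pt)) {
      stop("planted pair refers to unknown vocabulary entries: ",
           paste(c(bad_drug, bad_pt), collapse = ", "), call. = FALSE)
    }
  }
  p_base <- cfg$pts$prob * cfg$events_per_report
  if (any(p_base >= 1)) {
    stop("`events_per_report` times a PT probability reaches 1; ",
         "lower `events_per_report` or flatten the PT distribution",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Demonstration drug, country, and indication distributions
#'
#' Synthetic marginals used by the default [sim_config()]: one drug of
#' interest with a large share of primary-suspect reports plus nine
#' comparators, a US-dominated reporter-country mix, and a
#' dominant-indication oncology population with an explicit
#' unknown-indication level.
#'
#' @return Tibbles with a `prob` column summing to 1.
#' @export
demo_drug_vocabulary <- function() {
  # the drug of interest holds a small share of the database: EBGM is a
  # relative reporting ratio and is attenuated towards 1 when one drug
  # dominates the report set, so a small share is the regime in which all
  # four algorithms agree on true signals (as in a full-scale database)
  tibble(name = c("TYVERINE", sprintf("COMPARATOR_%02d", 1:9)),
         prob = c(0.05, rep(0.95 / 9, 9)))
}

#' @rdname demo_drug_vocabulary
#' @export
demo_country_distribution <- function() {
  tibble(country = c("US", "JP", "DE", "GB", "FR", "CN", "BR", "AU", "ZA",
                     "not_specified"),
         prob = c(0.45, 0.07, 0.06, 0.05, 0.04, 0.06, 0.05, 0.03, 0.01, 0.18))
}

#' @rdname demo_drug_vocabulary
#' @export
demo_indication_distribution <- function() {
  tibble(indication = c("Breast cancer", "Breast cancer metastatic",
                        "Gastric cancer", "Product used for unknown indication"),
         prob = c(0.45, 0.17, 0.15, 0.23))
}

#' Simulate a seeded spontaneous-report set with known ground truth
#'
#' Generates `n_cases` unique reports under the configured marginals,
#' plants the configured drug-event disproportionality on the odds scale,
#' optionally injects superseded duplicate case versions, and returns the
#' exact realized 2x2 counts for every planted pair so downstream
#' estimates can be checked against truth.
#'
#' @param config A [sim_config()].
#' @return A list with elements:
#'   * `reports`: report tibble (one row per report, including any injected
#'     duplicate versions), as produced by [read_reports()];
#'   * `ground_truth`: list with `planted` (the configured lambda table)
#'     and `realized_tables` (tibble of drug, pt, a, b, c, d recounted from
#'     the unique pre-duplication cases).
#' @export
simulate_reports <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_cases)
  pts <- config$pts
  J <- nrow(pts)

  primary <- sample(config$drugs$name, n, replace = TRUE, prob = config$drugs$prob)

  # independent per-PT inclusion; planted pairs multiply the odds
  p_base <- pts$prob * config$events_per_report
  P <- matrix(p_base, nrow = n, ncol = J, byrow = TRUE)
  if (nrow(config$planted) > 0) {
    for (k in seq_len(nrow(config$planted))) {
      j <- match(config$planted$pt[k], pts$pt)
      odds <- config$planted$lambda[k] * p_base[j] / (1 - p_base[j])
      P[primary == config$planted$drug[k], j] <- min(odds / (1 + odds), 1 - 1e-12)
    }
  }
  inc <- matrix(runif(n * J), nrow = n, ncol = J) < P
  empty <- which(rowSums(inc) == 0L)
  if (length(empty) > 0) {
    # a report must carry at least one event; the fallback draw follows the
    # report's own inclusion-probability row so planted odds stay calibrated
    j0 <- vapply(empty, function(i) sample.int(J, 1L, prob = P[i, ]), integer(1))
    inc[cbind(empty, j0)] <- TRUE
  }
  idx <- which(inc, arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])
  pts_list <- unname(split(pts$pt[idx[ord, 2L]],
                           factor(idx[ord, 1L], levels = seq_len(n))))

  # drug records: one primary suspect, optional concomitant
  has_con <- runif(n) < config$concomitant_prob
  con <- sample(config$drugs$name, n, replace = TRUE)
  drugs_list <- lapply(seq_len(n), function(i) {
    d <- c(primary_suspect = primary[i])
    if (has_con[i] && con[i] != primary[i]) d <- c(d, concomitant = con[i])
    d
  })

  sex <- sample(names(config$sex_probs), n, replace = TRUE, prob = config$sex_probs)
  age <- pmax(0, round(rnorm(n, config$age_mean, config$age_sd), 1))
  age[runif(n) < config$age_missing_prob] <- NA_real_
  country <- sample(config$countries$country, n, replace = TRUE,
                    prob = config$countries$prob)
  country[country == "not_specified"] <- NA_character_
  indication <- sample(config$indications$indication, n, replace = TRUE,
                       prob = config$indications$prob)
  outcome_draw <- sample(names(config$outcome_probs), n, replace = TRUE,
                         prob = config$outcome_probs)
  outcomes_list <- lapply(outcome_draw, function(o) {
    if (o == "none") character(0) else o
  })
  dose <- sample(seq_along(config$dose_levels), n, replace = TRUE,
                 prob = config$dose_probs)
  dose <- config$dose_levels[dose]

  year <- sample(seq(config$year_range[1], config$year_range[2]), n, replace = TRUE)
  day_of_year <- sample.int(365, n, replace = TRUE)
  receipt <- as.Date(sprintf("%d-01-01", year)) + (day_of_year - 1L)

  reports <- tibble(
    report_id = sprintf("R%07d", seq_len(n)),
    case_id = sprintf("C%07d", seq_len(n)),
    receipt_date = receipt,
    drugs = drugs_list,
    pts = pts_list,
    sex = sex,
    age_years = age,
    country = country,
    indication = indication,
    outcomes = outcomes_list,
    dose_mg_per_day = dose,
    year = year
  )
  class(reports) <- c("pv_reports", class(reports))

  realized <- if (nrow(config$planted) > 0) {
    dplyr::bind_rows(lapply(seq_len(nrow(config$planted)), function(k) {
      build_table(reports, config$planted$drug[k], config$planted$pt[k])
    }))
  } else {
    tibble(drug = character(), pt = character(),
           a = integer(), b = integer(), c = integer(), d = integer())
  }

  if (config$duplicate_fraction > 0) {
    reports <- inject_duplicates(reports, config$duplicate_fraction,
                                 seed = config$seed + 1L)
  }

  list(reports = reports,
       ground_truth = list(planted = config$planted, realized_tables = realized))
}

#' Inject superseded duplicate case versions
#'
#' Emulates case versioning in spontaneous reporting systems: a sampled
#' subset of cases emits one extra report sharing the `case_id` but with a
#' distinct `report_id` and an earlier receipt date, so that
#' latest-version deduplication recovers the original set exactly.
#'
#' @param reports Report tibble with unique `report_id`s.
#' @param duplicate_fraction Probability in `[0, 1]` that a case gains a
#'   superseded version.
#' @param seed Integer seed.
#' @return Report tibble with the duplicate versions appended.
#' @export
inject_duplicates <- function(reports, duplicate_fraction, seed = 1) {
  if (duplicate_fraction < 0 || duplicate_fraction > 1) {
    stop("`duplicate_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(reports$report_id)) {
    stop("input reports must have unique report ids", call. = FALSE)
  }
  if (duplicate_fraction == 0 || nrow(reports) == 0) return(reports)
  set.seed(seed)
  pick <- runif(nrow(reports)) < duplicate_fraction
  if (!any(pick)) return(reports)
  dup <- reports[pick, ]
  dup$report_id <- paste0(dup$report_id, "-0")
  lag_days <- sample(30:400, nrow(dup), replace = TRUE)
  dup$receipt_date <- dup$receipt_date - lag_days
  dup$year <- as.integer(format(dup$receipt_date, "%Y"))
  out <- dplyr::bind_rows(reports, dup)
  class(out) <- c("pv_reports", setdiff(class(out), "pv_reports"))
  out
}

#' Write a report set as a CSV fixture
#'
#' Serializes a report set in the wide interchange dialect so that
#' `read_reports(write_fixture(x), dialect = "wide")` round-trips every
#' field losslessly.
#'
#' @param reports Report tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(reports, path) {
  write_reports(reports, path, dialect = "wide")
}
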