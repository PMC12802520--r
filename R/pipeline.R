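#' Exclusion configuration for invalid signals
#'
#' Statistically significant drug-event pairs are not automatically
#' clinically meaningful: terms describing the treated disease, its
#' outcomes, non-reference investigation terms, or unspecified events are
#' conventionally excluded. Lists are user configuration; the shipped
#' defaults cover the four canonical categories with a few exemplar terms
#' each and must normally be extended per study.
#'
#' @param primary_disease,disease_outcome,non_reference,unspecified
#'   Character vectors of PT names (case-insensitive); the four lists must
#'   be disjoint after normalization.
#' @return A named list of class `exclusion_config`.
#' @export
exclusion_config <- function(primary_disease = character(),
                             disease_outcome = character(),
                             non_reference = character(),
                             unspecified = character()) {
  cfg <- list(primary_disease = primary_disease,
              disease_outcome = disease_outcome,
              non_reference = non_reference,
              unspecified = unspecified)
  norm <- lapply(cfg, normalize_term)
  all_terms <- unlist(norm)
  if (anyDuplicated(all_terms)) {
    stop("exclusion lists overlap after normalization: ",
         paste(unique(all_terms[duplicated(all_terms)]), collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "exclusion_config")
}

#' @rdname exclusion_config
#' @param path Optional JSON file with the four list fields; defaults to
#'   the configuration shipped with the package.
#' @export
load_exclusion_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "exclusion_defaults.json",
                                package = "pvsignal")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  exclusion_config(primary_disease = raw$primary_disease %||% character(),
                   disease_outcome = raw$disease_outcome %||% character(),
                   non_reference = raw$non_reference %||% character(),
                   unspecified = raw$unspecified %||% character())
}

#' Exclude invalid signals from the positive set
#'
#' Each combined-significant signal whose PT matches one of the four
#' exclusion lists is tagged with its category and removed from the
#' positive set. Accounting is conservative in report units (`sum of n`)
#' as well as PT units: `retained = detected - excluded` in both.
#'
#' @param signals Signal tibble with at least `pt`, `n` and `sig_all`.
#' @param exclusions An [exclusion_config()].
#' @return List with `signals` (input plus an `excluded` category column,
#'   `NA` for valid rows, and a logical `positive` column), and
#'   `accounting` (detected / excluded-per-category / retained counts in
#'   both PT and report units).
#' @export
exclude_invalid <- function(signals, exclusions = exclusion_config()) {
  stopifnot(inherits(exclusions, "exclusion_config"))
  norm <- normalize_term(signals$pt)
  category <- rep(NA_character_, nrow(signals))
  for (cat in names(exclusions)) {
    category[norm %in% normalize_term(exclusions[[cat]])] <- cat
  }
  sig <- signals$sig_all
  signals$excluded <- ifelse(sig, category, NA_character_)
  signals$positive <- sig & is.na(category)

  det <- sig
  exc <- sig & !is.na(category)
  per_cat <- vapply(names(exclusions), function(cat) {
    sum(signals$n[sig & !is.na(category) & category == cat])
  }, numeric(1))
  accounting <- list(
    detected_pts = sum(det),
    detected_reports = sum(signals$n[det]),
    excluded_pts = sum(exc),
    excluded_reports = sum(signals$n[exc]),
    excluded_reports_by_category = as.list(per_cat),
    retained_pts = sum(signals$positive),
    retained_reports = sum(signals$n[signals$positive])
  )
  list(signals = signals, accounting = accounting)
}

#' Aggregate positive signals by system organ class
#'
#' Sums report counts (`n`) of positive PT signals within each SOC and
#' expresses them as percentages of the positive-signal report total,
#' sorted descending.
#'
#' @param signals Signal tibble with `pt` and `n`; if a `positive` column
#'   is present only positive rows are aggregated.
#' @param map A [meddra_map()].
#' @return Tibble with `soc`, `soc_code`, `n`, `percent`.
#' @export
aggregate_soc <- function(signals, map) {
  if ("positive" %in% names(signals)) signals <- signals[signals$positive, ]
  if (nrow(signals) == 0) {
    return(tibble(soc = character(), soc_code = character(),
                  n = integer(), percent = numeric()))
  }
  lk <- soc_of(signals$pt, map)
  if (anyNA(lk$soc)) {
    stop("PT(s) not present in the MedDRA map: ",
         paste(unique(lk$pt[is.na(lk$soc)]), collapse = ", "), call. = FALSE)
  }
  agg <- dplyr::summarise(
    dplyr::group_by(tibble(soc = lk$soc, soc_code = lk$soc_code, n = signals$n),
                    soc, soc_code),
    n = sum(n), .groups = "drop"
  )
  agg$percent <- percent_of(agg$n, sum(agg$n))
  dplyr::arrange(agg, desc(n), soc)
}

#' Rank signals by frequency or strength
#'
#' Frequency ranking sorts by report count `n` descending (ties broken by
#' ROR descending, then PT name); strength ranking sorts by ROR descending
#' (ties by `n` descending, then PT name).
#'
#' @param signals Signal tibble with `pt`, `n`, `ror`.
#' @param by `"frequency"` or `"strength"`.
#' @param top_k Number of rows to keep (default all).
#' @return Reordered, truncated tibble.
#' @export
rank_signals <- function(signals, by = c("frequency", "strength"), top_k = Inf) {
  by <- match.arg(by)
  ord <- if (by == "frequency") {
    order(-signals$n, -ifelse(is.na(signals$ror), -Inf, signals$ror), signals$pt)
  } else {
    order(-ifelse(is.na(signals$ror), -Inf, signals$ror), -signals$n, signals$pt)
  }
  out <- signals[ord, ]
  head(out, n = min(top_k, nrow(out)))
}

#' Flag preferred terms absent from a product label
#'
#' A signal is novel when its PT does not appear in the supplied label PT
#' list (one term per line when read from file; matching is
#' case-insensitive).
#'
#' @param signals Signal tibble with a `pt` column.
#' @param label_pts Character vector of labelled PTs, or a path to a text
#'   file with one PT per line.
#' @return `signals` with a logical `novel` column.
#' @export
flag_novel <- function(signals, label_pts = character()) {
  if (length(label_pts) == 1 && file.exists(label_pts)) {
    label_pts <- readLines(label_pts, warn = FALSE)
  }
  label_pts <- label_pts[nzchar(trimws(label_pts))]
  signals$novel <- !(normalize_term(signals$pt) %in% normalize_term(label_pts))
  signals
}

#' Run the full signal-detection pipeline
#'
#' Orchestrates the complete flow over a spontaneous-report set:
#' read (if a path is given) -> deduplicate case versions -> validate PTs
#' against the MedDRA map -> select primary-suspect reports of the study
#' drug -> build all 2x2 tables (comparator: all other drugs in the set)
#' -> four disproportionality statistics -> significance and intensity ->
#' invalid-signal exclusion -> SOC aggregation -> ranking -> novelty
#' flagging -> descriptive summary of the drug's reports. Stage accounting
#' records counts entering and leaving every stage; the run is
#' deterministic for fixed inputs.
#'
#' @param reports Report tibble or path to a report CSV.
#' @param drug Study drug name.
#' @param map A [meddra_map()].
#' @param exclusions An [exclusion_config()].
#' @param label_pts Labelled PTs (vector or file path) for novelty
#'   flagging.
#' @param synonyms Drug-name synonyms.
#' @param region_map Country-to-region assignment for the descriptive
#'   summary (see [describe_reports()]).
#' @param dialect Interchange dialect when `reports` is a path.
#' @param continuity Apply the +0.5 continuity correction to all
#'   statistics.
#' @param top_k Rows kept in the ranked views.
#' @return List with elements `signals` (full statistics table),
#'   `positive` (retained positive signals), `by_frequency` and
#'   `by_strength` (ranked views), `soc` (SOC aggregation), `summary`
#'   (descriptive summary of the drug's reports), and `accounting`.
#' @export
run_pipeline <- function(reports, drug, map,
                         exclusions = load_exclusion_config(),
                         label_pts = character(),
                         synonyms = character(),
                         region_map = default_region_map(),
                         dialect = "wide",
                         continuity = FALSE,
                         top_k = 50) {
  if (is.character(reports) && length(reports) == 1) {
    reports <- read_reports(reports, dialect = dialect)
  }
  acc <- list(reports_read = nrow(reports),
              rows_rejected = nrow(reject_report(reports)))

  dedup <- deduplicate(reports)
  acc$duplicates_removed <- attr(dedup, "accounting")$removed
  acc$unique_reports <- nrow(dedup)

  val <- validate_pts(dedup, map)
  acc$terms_rejected <- sum(val$rejected_terms$n)
  acc$reports_dropped_no_valid_pt <- val$dropped_reports
  acc$validated_reports <- nrow(val$reports)

  drug_set <- filter_primary_suspect(val$reports, drug, synonyms)
  acc$drug_primary_reports <- nrow(drug_set)
  acc$drug_pt_incidences <- sum(lengths(drug_set$pts))

  tables <- build_all_tables(val$reports, drug, synonyms)
  acc$pts_tested <- nrow(tables)

  stats <- grade_intensity(evaluate_significance(
    signal_statistics(tables, continuity = continuity)))

  excl <- exclude_invalid(stats, exclusions)
  signals <- flag_novel(excl$signals, label_pts)
  # novelty is only defined for signals retained in the positive set
  signals$novel[!signals$positive] <- NA
  acc <- c(acc, excl$accounting)

  positive <- signals[signals$positive, ]
  soc <- aggregate_soc(positive, map)
  summary <- describe_reports(drug_set, region_map)

  list(signals = signals,
       positive = positive,
       by_frequency = rank_signals(positive, "frequency", top_k),
       by_strength = rank_signals(positive, "strength", top_k),
       soc = soc,
       summary = summary,
       accounting = acc)
}

#' Export a signal table in the published layout
#'
#' Formats a signal tibble with the conventional presentation columns:
#' `PT`, `N`, `ROR (95% CI)`, `PRR (chi2)`, `IC (IC025)`,
#' `EBGM (EBGM05)`, intensity markers (`+`, `++`, `+++` from the BCPNN
#' grade) and a novelty marker. Values are rounded half-up to two
#' decimals at this presentation step only.
#'
#' @param signals Signal tibble from [run_pipeline()] /
#'   [grade_intensity()].
#' @param path Optional TSV output path.
#' @return The formatted tibble (invisibly if `path` is given).
#' @export
format_signal_table <- function(signals, path = NULL) {
  r2 <- function(x) sprintf("%.2f", round_half_up(x, 2))
  marker <- c(none = "", weak = "+", medium = "++", strong = "+++")
  out <- tibble(
    pt = paste0(signals$pt,
                ifelse(!is.na(signals$novel) & signals$novel, " §", "")),
    n = signals$n,
    ror_ci = sprintf("%s (%s-%s)", r2(signals$ror), r2(signals$ror_low),
                     r2(signals$ror_high)),
    prr_chi2 = sprintf("%s (%s)", r2(signals$prr), r2(signals$chi2)),
    ic_ic025 = sprintf("%s (%s)", r2(signals$ic), r2(signals$ic025)),
    ebgm_ebgm05 = sprintf("%s (%s)", r2(signals$ebgm), r2(signals$ebgm05)),
    intensity = unname(marker[as.character(signals$int_bcpnn)])
  )
  if (!is.null(path)) {
    readr::write_tsv(out, path, progress = FALSE)
    return(invisible(out))
  }
  out
}
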