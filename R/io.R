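#' Read spontaneous reports from the interchange CSV format
#'
#' Two dialects are supported, mirroring the layouts of common
#' pharmacovigilance extracts:
#'
#' * `"wide"`: one row per report; multi-valued cells use `|` as the
#'   record separator, with drug records encoded as `NAME:ROLE` where
#'   `ROLE` is one of `PS`, `SS`, `C`, `I` (primary suspect, secondary
#'   suspect, concomitant, interacting).
#' * `"long"`: one row per report-drug-PT record with columns `drug`,
#'   `role`, `pt`; rows sharing a `report_id` are assembled into one
#'   report, demographic fields taken from the first row.
#'
#' Malformed rows (missing `report_id`, unknown role code) are not fatal:
#' they are dropped and collected into a reject table with reasons,
#' retrievable with [reject_report()]. Missing optional fields become
#' explicit `NA` / `not_specified` values.
#'
#' @param path Path to a CSV file.
#' @param dialect `"wide"` or `"long"`.
#' @return A `pv_reports` tibble (one row per report; `drugs` is a list of
#'   role-named character vectors, `pts` and `outcomes` are list columns)
#'   with the reject table stored in the `"rejects"` attribute.
#' @seealso [write_reports()], [deduplicate()], [filter_primary_suspect()]
#' @export
read_reports <- function(path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (dialect == "wide") parse_wide(raw) else parse_long(raw)
}

#' Retrieve the reject table of a report set
#'
#' @param reports A `pv_reports` tibble returned by [read_reports()].
#' @return Tibble with columns `row` (1-based data-row index in the source
#'   file) and `reason`.
#' @export
reject_report <- function(reports) {
  attr(reports, "rejects") %||% tibble(row = integer(), reason = character())
}

role_from_code <- function(code) {
  names(.role_codes)[match(code, .role_codes)]
}

parse_common <- function(raw) {
  raw$sex <- ifelse(is.na(raw$sex) | !(raw$sex %in% .sex_levels),
                    "not_specified", raw$sex)
  raw$age_years <- suppressWarnings(as.numeric(raw$age_years))
  raw$dose_mg_per_day <- suppressWarnings(as.numeric(raw$dose_mg_per_day))
  raw$receipt_date <- as.Date(raw$receipt_date)
  raw$year <- suppressWarnings(as.integer(raw$year))
  raw$year[is.na(raw$year)] <- as.integer(format(raw$receipt_date[is.na(raw$year)], "%Y"))
  raw
}

split_multi <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), "|", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

new_pv_reports <- function(df, rejects) {
  df <- as_tibble(df)
  class(df) <- c("pv_reports", class(df))
  attr(df, "rejects") <- rejects
  df
}

parse_wide <- function(raw) {
  required <- c("report_id", "case_id", "receipt_date", "drugs", "pts")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("wide dialect is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  optional <- c("sex", "age_years", "country", "indication", "outcomes",
                "dose_mg_per_day", "year")
  for (col in optional) if (!col %in% names(raw)) raw[[col]] <- NA_character_

  rejects <- tibble(row = integer(), reason = character())
  if (nrow(raw) == 0) {
    empty <- empty_reports()
    return(new_pv_reports(empty, rejects))
  }

  bad_id <- is.na(raw$report_id) | raw$report_id == ""
  drug_tokens <- split_multi(raw$drugs)
  parsed_drugs <- lapply(drug_tokens, function(tok) {
    if (length(tok) == 0) return(character(0))
    parts <- strsplit(tok, ":", fixed = TRUE)
    nm <- vapply(parts, `[`, "", 1L)
    code <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, "")
    role <- role_from_code(code)
    if (anyNA(role)) return(NULL) # unknown role code -> reject row
    setNames(nm, role)
  })
  bad_role <- vapply(parsed_drugs, is.null, logical(1))
  keep <- !bad_id & !bad_role
  rejects <- bind_rows(
    tibble(row = which(bad_id), reason = "missing report_id"),
    tibble(row = which(bad_role & !bad_id), reason = "unknown role code")
  )
  raw <- parse_common(raw)
  out <- tibble(
    report_id = raw$report_id[keep],
    case_id = raw$case_id[keep],
    receipt_date = raw$receipt_date[keep],
    drugs = parsed_drugs[keep],
    pts = lapply(split_multi(raw$pts[keep]), unique),
    sex = raw$sex[keep],
    age_years = raw$age_years[keep],
    country = raw$country[keep],
    indication = raw$indication[keep],
    outcomes = lapply(split_multi(raw$outcomes[keep]),
                      function(o) intersect(o, .outcome_levels)),
    dose_mg_per_day = raw$dose_mg_per_day[keep],
    year = raw$year[keep]
  )
  new_pv_reports(out, dplyr::arrange(rejects, row))
}

parse_long <- function(raw) {
  required <- c("report_id", "case_id", "receipt_date", "drug", "role", "pt")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("long dialect is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  optional <- c("sex", "age_years", "country", "indication", "outcomes",
                "dose_mg_per_day", "year")
  for (col in optional) if (!col %in% names(raw)) raw[[col]] <- NA_character_
  rejects <- tibble(row = integer(), reason = character())
  if (nrow(raw) == 0) return(new_pv_reports(empty_reports(), rejects))

  bad_id <- is.na(raw$report_id) | raw$report_id == ""
  role <- role_from_code(raw$role)
  bad_role <- is.na(role)
  keep <- !bad_id & !bad_role
  rejects <- bind_rows(
    tibble(row = which(bad_id), reason = "missing report_id"),
    tibble(row = which(bad_role & !bad_id), reason = "unknown role code")
  )
  raw <- parse_common(raw)
  raw$.role <- role
  kept <- raw[keep, ]
  groups <- split(kept, factor(kept$report_id, levels = unique(kept$report_id)))
  rows <- lapply(groups, function(g) {
    drug_rec <- unique(data.frame(name = g$drug, role = g$.role,
                                  stringsAsFactors = FALSE))
    drug_rec <- drug_rec[!is.na(drug_rec$name) & drug_rec$name != "", , drop = FALSE]
    tibble(
      report_id = g$report_id[1],
      case_id = g$case_id[1],
      receipt_date = g$receipt_date[1],
      drugs = list(setNames(drug_rec$name, drug_rec$role)),
      pts = list(unique(g$pt[!is.na(g$pt) & g$pt != ""])),
      sex = g$sex[1],
      age_years = g$age_years[1],
      country = g$country[1],
      indication = g$indication[1],
      outcomes = list(intersect(split_multi(g$outcomes[1])[[1]], .outcome_levels)),
      dose_mg_per_day = g$dose_mg_per_day[1],
      year = g$year[1]
    )
  })
  new_pv_reports(bind_rows(rows), dplyr::arrange(rejects, row))
}

empty_reports <- function() {
  tibble(
    report_id = character(), case_id = character(),
    receipt_date = as.Date(character()),
    drugs = list(), pts = list(),
    sex = character(), age_years = numeric(), country = character(),
    indication = character(), outcomes = list(),
    dose_mg_per_day = numeric(), year = integer()
  )
}

#' Write reports in an interchange dialect
#'
#' Inverse of [read_reports()]; fields are serialized so the round trip
#' is lossless. Drug names must not contain the `:` or `|` separator
#' characters.
#'
#' @param reports Report tibble.
#' @param path Output CSV path.
#' @param dialect `"wide"` (one row per report) or `"long"` (one row per
#'   report-drug-PT record).
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  all_names <- unlist(reports$drugs)
  if (any(grepl("[:|]", all_names))) {
    stop("drug names must not contain ':' or '|'", call. = FALSE)
  }
  if (dialect == "wide") {
    flat <- tibble(
      report_id = reports$report_id,
      case_id = reports$case_id,
      receipt_date = format(reports$receipt_date, "%Y-%m-%d"),
      drugs = vapply(reports$drugs, function(d) {
        paste(sprintf("%s:%s", unname(d), .role_codes[names(d)]), collapse = "|")
      }, ""),
      pts = vapply(reports$pts, paste, "", collapse = "|"),
      sex = reports$sex,
      age_years = reports$age_years,
      country = reports$country,
      indication = reports$indication,
      outcomes = vapply(reports$outcomes, paste, "", collapse = "|"),
      dose_mg_per_day = reports$dose_mg_per_day,
      year = reports$year
    )
    readr::write_csv(flat, path, na = "", progress = FALSE)
  } else {
    rows <- lapply(seq_len(nrow(reports)), function(i) {
      d <- reports$drugs[[i]]
      grid <- expand.grid(k = seq_along(d), pt = reports$pts[[i]],
                          stringsAsFactors = FALSE)
      tibble(
        report_id = reports$report_id[i], case_id = reports$case_id[i],
        receipt_date = format(reports$receipt_date[i], "%Y-%m-%d"),
        drug = unname(d)[grid$k], role = .role_codes[names(d)][grid$k],
        pt = grid$pt,
        sex = reports$sex[i], age_years = reports$age_years[i],
        country = reports$country[i], indication = reports$indication[i],
        outcomes = paste(reports$outcomes[[i]], collapse = "|"),
        dose_mg_per_day = reports$dose_mg_per_day[i], year = reports$year[i]
      )
    })
    readr::write_csv(bind_rows(rows), path, na = "", progress = FALSE)
  }
  invisible(path)
}

#' Deduplicate case versions
#'
#' Spontaneous reporting systems receive updated versions of the same case
#' under a shared case identifier. Following the conventional
#' latest-version rule, exactly one report per `case_id` is retained: the
#' one with the most recent `receipt_date`, ties broken by the
#' lexicographically greatest `report_id`. Output order is deterministic
#' (sorted by `case_id`).
#'
#' @param reports Report tibble.
#' @return Deduplicated report tibble; the `"accounting"` attribute holds
#'   `input`, `removed` and `output` counts.
#' @export
deduplicate <- function(reports) {
  n_in <- nrow(reports)
  if (n_in == 0) {
    attr(reports, "accounting") <- list(input = 0L, removed = 0L, output = 0L)
    return(reports)
  }
  ord <- order(reports$case_id,
               as.integer(reports$receipt_date),
               reports$report_id,
               method = "radix", decreasing = c(FALSE, TRUE, TRUE))
  out <- reports[ord, ]
  out <- out[!duplicated(out$case_id), ]
  attr(out, "rejects") <- attr(reports, "rejects")
  attr(out, "accounting") <- list(input = n_in, removed = n_in - nrow(out),
                                  output = nrow(out))
  out
}

# fast vectorized lookup: which reports list `drug` with role primary_suspect
has_primary_suspect <- function(reports, drug, synonyms = character()) {
  n <- nrow(reports)
  if (n == 0) return(logical(0))
  targets <- tolower(c(drug, synonyms))
  all_names <- unlist(reports$drugs, use.names = TRUE)
  roles <- names(all_names)
  ri <- rep.int(seq_len(n), lengths(reports$drugs))
  hit <- roles == "primary_suspect" & tolower(all_names) %in% targets
  out <- logical(n)
  out[ri[hit]] <- TRUE
  out
}

#' Filter reports where a drug is the primary suspect
#'
#' Retains exactly the reports in which the named drug appears with the
#' primary-suspect role code. Matching is case-insensitive and may include
#' a synonym list (e.g. brand and generic names), reflecting free-text
#' drug naming in spontaneous reports.
#'
#' @param reports Report tibble.
#' @param drug Drug name.
#' @param synonyms Optional character vector of alternative names.
#' @return Subset of `reports`.
#' @export
filter_primary_suspect <- function(reports, drug, synonyms = character()) {
  reports[has_primary_suspect(reports, drug, synonyms), ]
}

#' Validate event terms against a MedDRA map
#'
#' Event terms not present in the supplied PT-to-SOC map are removed from
#' each report and tallied; reports left with no valid PT are dropped.
#' This mirrors the standard cleaning step in which reported terms that
#' are not MedDRA preferred terms are excluded from analysis.
#'
#' @param reports Report tibble.
#' @param map A [meddra_map()].
#' @return List with elements `reports` (validated set), `rejected_terms`
#'   (tibble of `term`, `n` occurrences removed) and `dropped_reports`
#'   (count of reports removed entirely).
#' @export
validate_pts <- function(reports, map) {
  stopifnot(inherits(map, "meddra_map"))
  if (nrow(reports) == 0) {
    return(list(reports = reports,
                rejected_terms = tibble(term = character(), n = integer()),
                dropped_reports = 0L))
  }
  known <- lapply(reports$pts, function(p) p[normalize_term(p) %in% map$pt_norm])
  removed <- unlist(lapply(reports$pts, function(p) {
    p[!normalize_term(p) %in% map$pt_norm]
  }))
  rejected <- if (length(removed) == 0) {
    tibble(term = character(), n = integer())
  } else {
    tab <- sort(table(removed), decreasing = TRUE)
    tibble(term = names(tab), n = as.integer(tab))
  }
  keep <- lengths(known) > 0
  out <- reports[keep, ]
  out$pts <- known[keep]
  list(reports = out, rejected_terms = rejected,
       dropped_reports = sum(!keep))
}
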