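#' Build the 2x2 contingency table for one drug-event pair
#'
#' Report-level counting over a deduplicated report set: a report "has the
#' drug" iff the drug appears with the primary-suspect role, and "has the
#' PT" iff the term appears in its validated PT list (multiplicity within a
#' report is ignored). Each report contributes to exactly one of the four
#' cells, so `a + b + c + d` equals the total report count for every pair
#' from the same set:
#'
#' |                | event of interest | other events |
#' |----------------|-------------------|--------------|
#' | drug (primary suspect) | a         | b            |
#' | all other drugs        | c         | d            |
#'
#' The comparator population is all other drugs within the supplied set.
#'
#' @param reports Deduplicated report tibble.
#' @param drug Drug name (case-insensitive; see `synonyms`).
#' @param pt Preferred term (case-insensitive).
#' @param synonyms Optional drug-name synonyms.
#' @return One-row tibble with columns `drug`, `pt`, `a`, `b`, `c`, `d`.
#' @export
#' @examples
#' sim <- simulate_reports(sim_config(n_cases = 200, seed = 1))
#' build_table(sim$reports, "TYVERINE", "Diarrhoea")
build_table <- function(reports, drug, pt, synonyms = character()) {
  n <- nrow(reports)
  hasd <- has_primary_suspect(reports, drug, synonyms)
  target <- normalize_term(pt)
  hasp <- vapply(reports$pts, function(p) any(normalize_term(p) == target),
                 logical(1))
  a <- sum(hasd & hasp)
  b <- sum(hasd & !hasp)
  c_ <- sum(!hasd & hasp)
  tibble(drug = drug, pt = pt,
         a = a, b = b, c = c_, d = n - a - b - c_)
}

#' Build 2x2 tables for every event reported with a drug
#'
#' Vectorized form of [build_table()]: one table per distinct PT occurring
#' in any report where the drug is the primary suspect. PTs never
#' co-reported with the drug have `a = 0` and are not enumerated.
#'
#' @inheritParams build_table
#' @return Tibble with one row per PT and columns `drug`, `pt`, `a`, `b`,
#'   `c`, `d`; rows sorted by PT name for determinism.
#' @export
build_all_tables <- function(reports, drug, synonyms = character()) {
  n <- nrow(reports)
  hasd <- has_primary_suspect(reports, drug, synonyms)
  n_drug <- sum(hasd)
  if (n_drug == 0) {
    return(tibble(drug = character(), pt = character(),
                  a = integer(), b = integer(), c = integer(), d = integer()))
  }
  pt_all <- unlist(reports$pts)
  ri <- rep.int(seq_len(n), lengths(reports$pts))
  key <- normalize_term(pt_all)

  tab_drug <- table(key[hasd[ri]])
  tab_all <- table(key)
  pts_norm <- names(tab_drug)
  # display name: first spelling observed for each normalized term
  first <- !duplicated(key)
  display <- setNames(pt_all[first], key[first])

  a <- as.integer(tab_drug)
  c_ <- as.integer(tab_all[pts_norm]) - a
  out <- tibble(drug = drug, pt = unname(display[pts_norm]),
                a = a, b = n_drug - a, c = c_, d = n - n_drug - c_)
  dplyr::arrange(out, pt)
}
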