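#' Load a preferred-term to system-organ-class map
#'
#' Reads a tab-separated file mapping MedDRA preferred terms (PTs) to
#' system organ classes (SOCs). The licensed MedDRA dictionary itself is
#' not shipped; users supply their own extract (or use the small synthetic
#' demonstration map in `inst/extdata`). Required columns are `pt`,
#' `soc`, and `soc_code`; an optional `pt_code` column is carried through.
#'
#' Every PT must map to exactly one SOC: duplicated PT rows are allowed
#' only when they agree on the SOC, otherwise loading fails.
#'
#' @param path Path to a TSV file with columns `pt`, `soc`, `soc_code`
#'   and optionally `pt_code`.
#' @return A tibble of class `meddra_map` with one row per PT.
#' @export
load_meddra_map <- function(path) {
  map <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("pt", "soc", "soc_code")
  missing <- setdiff(required, names(map))
  if (length(missing) > 0) {
    stop("MedDRA map is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"pt_code" %in% names(map)) map$pt_code <- NA_character_
  meddra_map(map)
}

#' Construct a PT to SOC map from a data frame
#'
#' @param map Data frame with columns `pt`, `soc`, `soc_code` and
#'   optionally `pt_code`.
#' @return A tibble of class `meddra_map`, one row per distinct PT.
#' @export
meddra_map <- function(map) {
  map <- as_tibble(map)
  if (!"pt_code" %in% names(map)) map$pt_code <- NA_character_
  map$pt_norm <- normalize_term(map$pt)
  map <- distinct(map, pt_norm, soc, soc_code, .keep_all = TRUE)
  dup <- map$pt_norm[duplicated(map$pt_norm)]
  if (length(dup) > 0) {
    stop("PT(s) mapped to more than one SOC: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  class(map) <- c("meddra_map", class(map))
  map
}

#' Look up the SOC of preferred terms
#'
#' @param pts Character vector of PT names (matching is case-insensitive).
#' @param map A `meddra_map`.
#' @return Tibble with columns `pt`, `soc`, `soc_code` (`NA` when unmapped).
#' @export
soc_of <- function(pts, map) {
  stopifnot(inherits(map, "meddra_map"))
  i <- match(normalize_term(pts), map$pt_norm)
  tibble(pt = pts, soc = map$soc[i], soc_code = map$soc_code[i])
}

#' Built-in synthetic demonstration vocabulary
#'
#' A small PT vocabulary with a SOC assignment, used by the default
#' simulation configuration, the shipped fixtures, and the examples. SOC
#' names and numeric codes follow the published MedDRA SOC registry; the
#' PT subset and its background reporting probabilities are synthetic.
#'
#' @return A tibble with columns `pt`, `soc`, `soc_code`, `prob`
#'   (background per-report marginal probabilities summing to 1).
#' @export
demo_pt_vocabulary <- function() {
  v <- tibble::tribble(
    ~pt,                                   ~soc,                                                    ~soc_code,
    "Diarrhoea",                           "Gastrointestinal disorders",                            "10017947",
    "Nausea",                              "Gastrointestinal disorders",                            "10017947",
    "Vomiting",                            "Gastrointestinal disorders",                            "10017947",
    "Abdominal pain",                      "Gastrointestinal disorders",                            "10017947",
    "Stomatitis",                          "Gastrointestinal disorders",                            "10017947",
    "Dyspepsia",                           "Gastrointestinal disorders",                            "10017947",
    "Rash",                                "Skin and subcutaneous tissue disorders",                "10040785",
    "Palmar-plantar erythrodysaesthesia syndrome", "Skin and subcutaneous tissue disorders",        "10040785",
    "Dry skin",                            "Skin and subcutaneous tissue disorders",                "10040785",
    "Paronychia",                          "Skin and subcutaneous tissue disorders",                "10040785",
    "Erythema",                            "Skin and subcutaneous tissue disorders",                "10040785",
    "Dermatitis acneiform",                "Skin and subcutaneous tissue disorders",                "10040785",
    "Fatigue",                             "General disorders and administration site conditions",  "10018065",
    "Pyrexia",                             "General disorders and administration site conditions",  "10018065",
    "Oedema peripheral",                   "General disorders and administration site conditions",  "10018065",
    "Disease progression",                 "General disorders and administration site conditions",  "10018065",
    "Death",                               "General disorders and administration site conditions",  "10018065",
    "Oncologic complication",              "General disorders and administration site conditions",  "10018065",
    "Decreased appetite",                  "Metabolism and nutrition disorders",                    "10027433",
    "Dehydration",                         "Metabolism and nutrition disorders",                    "10027433",
    "Hypokalaemia",                        "Metabolism and nutrition disorders",                    "10027433",
    "Weight decreased",                    "Investigations",                                        "10022891",
    "Alanine aminotransferase increased",  "Investigations",                                        "10022891",
    "Investigation",                       "Investigations",                                        "10022891",
    "Neutropenia",                         "Blood and lymphatic system disorders",                  "10005329",
    "Anaemia",                             "Blood and lymphatic system disorders",                  "10005329",
    "Hepatotoxicity",                      "Hepatobiliary disorders",                               "10019805",
    "Jaundice",                            "Hepatobiliary disorders",                               "10019805",
    "Cellulitis",                          "Infections and infestations",                           "10021881",
    "Pneumonia",                           "Infections and infestations",                           "10021881",
    "Dyspnoea",                            "Respiratory, thoracic and mediastinal disorders",       "10038738",
    "Cough",                               "Respiratory, thoracic and mediastinal disorders",       "10038738",
    "Cardiotoxicity",                      "Cardiac disorders",                                     "10007541",
    "Palpitations",                        "Cardiac disorders",                                     "10007541",
    "Headache",                            "Nervous system disorders",                              "10029205",
    "Dizziness",                           "Nervous system disorders",                              "10029205",
    "Insomnia",                            "Psychiatric disorders",                                 "10037175",
    "Milia",                               "Skin and subcutaneous tissue disorders",                "10040785",
    "Nail disorder",                       "Skin and subcutaneous tissue disorders",                "10040785",
    "Hypocapnia",                          "Investigations",                                        "10022891"
  )
  # Zipf-like background frequencies: a few common terms, a long tail
  w <- 1 / seq_len(nrow(v))^0.8
  v$prob <- w / sum(w)
  v
}

#' @rdname demo_pt_vocabulary
#' @return `demo_meddra_map()` returns the same vocabulary as a
#'   [meddra_map()] object.
#' @export
demo_meddra_map <- function() {
  meddra_map(demo_pt_vocabulary()[, c("pt", "soc", "soc_code")])
}
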