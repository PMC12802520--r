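#' Naranjo adverse drug reaction probability scale
#'
#' The Naranjo scale scores a structured case report with ten weighted
#' yes/no/unknown questions (previous conclusive reports; event after the
#' drug; improvement on withdrawal; reappearance on rechallenge;
#' alternative causes; placebo reaction; toxic drug concentration;
#' dose-response; past similar reaction; objective confirmation) and maps
#' the total score to a causality category. The canonical published
#' weights are shipped as an editable TSV configuration
#' (`inst/extdata/naranjo_weights.tsv`); the category cut-offs are fixed:
#' score >= 9 definite, 5-8 probable, 1-4 possible, <= 0 doubtful.
#'
#' @param path Optional TSV with columns `question`, `yes`, `no`,
#'   `unknown` (10 rows); defaults to the canonical weights.
#' @return Tibble of class `naranjo_weights`.
#' @export
naranjo_weights <- function(path = NULL) {
  path <- path %||% system.file("extdata", "naranjo_weights.tsv",
                                package = "pvsignal")
  w <- readr::read_tsv(path, col_types = "cddd", progress = FALSE)
  required <- c("question", "yes", "no", "unknown")
  if (!all(required %in% names(w)) || nrow(w) != 10) {
    stop("weight table must have 10 rows and columns question/yes/no/unknown",
         call. = FALSE)
  }
  class(w) <- c("naranjo_weights", class(w))
  w
}

#' Score one case on the Naranjo scale
#'
#' @param answers Character vector of 10 responses, each `"yes"`, `"no"`
#'   or `"unknown"`, ordered as the canonical questions.
#' @param weights A [naranjo_weights()] table.
#' @return Integer score (sum of the response-selected weights).
#' @export
#' @examples
#' score_case(c("yes", "yes", "yes", rep("unknown", 7)))
score_case <- function(answers, weights = naranjo_weights()) {
  if (length(answers) != nrow(weights)) {
    stop("expected ", nrow(weights), " answers, got ", length(answers),
         call. = FALSE)
  }
  if (!all(answers %in% c("yes", "no", "unknown"))) {
    stop("answers must be 'yes', 'no' or 'unknown'", call. = FALSE)
  }
  w <- as.matrix(weights[, c("yes", "no", "unknown")])
  sum(w[cbind(seq_along(answers), match(answers, c("yes", "no", "unknown")))])
}

#' Map a Naranjo score to a causality category
#'
#' @param score Integer vector of scores.
#' @return Factor with levels `doubtful`, `possible`, `probable`,
#'   `definite` (score <= 0, 1-4, 5-8, >= 9 respectively).
#' @export
naranjo_category <- function(score) {
  cut(score, breaks = c(-Inf, 0, 4, 8, Inf),
      labels = c("doubtful", "possible", "probable", "definite"))
}

#' Score a table of cases and tally causality categories
#'
#' @param cases Data frame (or CSV path) with a `case_id` column and ten
#'   response columns `q1`..`q10`; extra columns are carried through.
#' @param weights A [naranjo_weights()] table.
#' @return List with `results` (per-case `score` and `category` appended)
#'   and `histogram` (named category counts).
#' @export
assess_cases <- function(cases, weights = naranjo_weights()) {
  if (is.character(cases) && length(cases) == 1) {
    cases <- readr::read_csv(cases, col_types = readr::cols(.default = readr::col_character()),
                             progress = FALSE)
  }
  cases <- as_tibble(cases)
  qcols <- paste0("q", 1:10)
  missing <- setdiff(qcols, names(cases))
  if (length(missing) > 0) {
    stop("missing response column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(cases) == 0) {
    res <- cases
    res$score <- integer(0)
    res$category <- naranjo_category(integer(0))
    return(list(results = res,
                histogram = setNames(rep(0L, 4),
                                     c("doubtful", "possible", "probable",
                                       "definite"))))
  }
  ans <- as.matrix(cases[, qcols])
  score <- apply(ans, 1, score_case, weights = weights)
  cases$score <- as.integer(score)
  cases$category <- naranjo_category(score)
  hist <- table(cases$category)
  list(results = cases, histogram = setNames(as.integer(hist), names(hist)))
}

#' Report scoring disagreements between two raters
#'
#' Dual-rater adjudication itself is a human process; this helper only
#' surfaces the cases on which two independently scored answer sets
#' disagree in category.
#'
#' @param rater1,rater2 `results` tibbles from [assess_cases()] sharing
#'   `case_id`s.
#' @return Tibble of disagreeing cases with both scores and categories.
#' @export
rater_disagreements <- function(rater1, rater2) {
  m <- match(rater1$case_id, rater2$case_id)
  keep <- !is.na(m) & rater1$category != rater2$category[m]
  tibble(case_id = rater1$case_id[keep],
         score_1 = rater1$score[keep],
         category_1 = rater1$category[keep],
         score_2 = rater2$score[m[keep]],
         category_2 = rater2$category[m[keep]])
}
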