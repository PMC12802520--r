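#' Round half away from zero
#'
#' Presentation-grade rounding used throughout the package for percentages
#' and published-style tables. Base [round()] rounds half to even
#' (banker's rounding); spontaneous-report summaries conventionally round
#' half up, so 0.125 -> 0.13 at two decimals.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(2.675, 2) # 2.68, where round() gives 2.67
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a total, rounded to two decimals
#'
#' Computes `100 * count / total` rounded half-up to two decimal places,
#' the arithmetic used in every descriptive and aggregation table the
#' package emits. With `total = 0` the percentage is reported as 0.
#'
#' @param count Numeric vector of counts.
#' @param total Scalar denominator.
#' @return Numeric vector of percentages with two-decimal precision.
#' @export
#' @examples
#' percent_of(29650, 38061) # 77.90
percent_of <- function(count, total) {
  if (length(total) != 1L) stop("`total` must be a single number", call. = FALSE)
  if (total == 0) return(rep(0, length(count)))
  round_half_up(100 * count / total, 2)
}

# canonical form used whenever preferred terms are compared:
# case-insensitive, trimmed, internal whitespace collapsed
normalize_term <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

# role vocabulary: full names used in memory, two-letter codes on disk
.role_levels <- c("primary_suspect", "secondary_suspect", "concomitant", "interacting")
.role_codes <- c(primary_suspect = "PS", secondary_suspect = "SS",
                 concomitant = "C", interacting = "I")

.outcome_levels <- c("death", "disability", "hospitalisation",
                     "life_threatening", "required_intervention", "other")

.sex_levels <- c("female", "male", "not_specified")

`%||%` <- function(a, b) if (is.null(a)) b else a
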