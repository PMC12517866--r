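#' @import data.table
#' @importFrom stats median plogis qlogis quantile rbinom rgeom rlnorm rnorm
#'   runif setNames
#' @importFrom utils head
#' @keywords internal
"_PACKAGE"

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Classic "half-up" rounding as used in report tables (base [round()] uses
#' round-half-to-even). Only defined here for non-negative inputs, which is
#' all the report surfaces need.
#'
#' @param x numeric vector, non-negative.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, ties going up.
#' @examples
#' round_half_up(2.655, 2) # 2.66 (printf-style rounding would give 2.65)
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Format a percentage the way report tables print it
#'
#' `100 * num / den`, rounded half-up to two decimals and fixed to two
#' printed decimals ("52.38"). Comparisons in signal decisions never use
#' these rounded values; they exist only for presentation.
#'
#' @param num numerator count(s).
#' @param den denominator count(s).
#' @return character vector like "21.20".
#' @export
fmt_pct <- function(num, den) {
  sprintf("%.2f", round_half_up(100 * num / den, 2))
}

## sex strings other than F/M (any case, padded, empty, NA) collapse to UNKNOWN
map_sex <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- rep("UNKNOWN", length(x))
  out[x %in% "F"] <- "F"
  out[x %in% "M"] <- "M"
  out
}

.outcome_map <- c(
  DE = "DEATH", LT = "LIFE_THREATENING", HO = "HOSPITALIZATION",
  DS = "DISABILITY", CA = "CONGENITAL_ANOMALY", OT = "OTHER_SERIOUS"
)

#' Map FAERS outcome codes to labels
#'
#' DE, LT, HO, DS, CA, OT become DEATH, LIFE_THREATENING, HOSPITALIZATION,
#' DISABILITY, CONGENITAL_ANOMALY, OTHER_SERIOUS; anything else is NA.
#'
#' @param code character vector of OUTC_COD values.
#' @return character vector of labels.
#' @export
outcome_label <- function(code) {
  unname(.outcome_map[toupper(trimws(as.character(code)))])
}

#' Type-7 quantiles
#'
#' Linear interpolation between closest order statistics — the convention
#' that produces fractional medians and quartiles (7, 14.5, 3.25, ...) from
#' integer day counts.
#'
#' @param x numeric vector.
#' @param probs probabilities.
#' @return numeric vector of quantiles.
#' @export
quantile_type7 <- function(x, probs = c(0.25, 0.5, 0.75)) {
  unname(quantile(x, probs = probs, type = 7, names = FALSE))
}
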