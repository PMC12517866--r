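#' Define a demographic stratum
#'
#' Sex is "F", "M" or "ANY"; the age window is half-open `[age_low,
#' age_high)` in years (so the conventional bins are `[18, 75)` and
#' `[75, Inf)`). Reports with UNKNOWN sex are excluded from any stratum
#' with sex != "ANY"; reports with missing age are excluded from any
#' stratum with a finite age restriction.
#'
#' @param label stratum label.
#' @param sex "F", "M" or "ANY".
#' @param age_low inclusive lower bound in years.
#' @param age_high exclusive upper bound in years (Inf for open-ended).
#' @return a `stratum_spec` object.
#' @export
stratum <- function(label, sex = "ANY", age_low = 0, age_high = Inf) {
  sex <- match.arg(sex, c("F", "M", "ANY"))
  stopifnot(age_low < age_high)
  structure(list(label = label, sex = sex, age_low = age_low,
                 age_high = age_high),
            class = "stratum_spec")
}

#' @export
print.stratum_spec <- function(x, ...) {
  cat(sprintf("<stratum> %s: sex=%s, age [%g, %g)\n",
              x$label, x$sex, x$age_low, x$age_high))
  invisible(x)
}

## logical membership vector; NA sex/age excluded where the stratum
## conditions on that field
stratum_members <- function(cohort, spec) {
  keep <- rep(TRUE, nrow(cohort))
  if (spec$sex != "ANY") keep <- keep & cohort$sex == spec$sex
  restricts_age <- spec$age_low > 0 || is.finite(spec$age_high)
  if (restricts_age) {
    keep <- keep & !is.na(cohort$age_years) &
      cohort$age_years >= spec$age_low & cohort$age_years < spec$age_high
  }
  keep
}

strata_overlap <- function(a, b) {
  sex_overlap <- a$sex == "ANY" || b$sex == "ANY" || a$sex == b$sex
  age_overlap <- a$age_low < b$age_high && b$age_low < a$age_high
  sex_overlap && age_overlap
}

#' Subgroup disproportionality (exposure contrast within a stratum)
#'
#' The report universe is restricted to the stratum and the usual
#' drug-vs-rest 2x2 is built inside it (stratum-matched comparator). With
#' `stratum("all")` this reduces to the unstratified analysis.
#'
#' @param cohort [build_cohort()] result.
#' @param drug label of a target drug.
#' @param spec a [stratum()].
#' @param ic_variance passed to [signal_estimate()].
#' @return list with `stratum`, `table` and the [signal_estimate()].
#' @export
subgroup_signal <- function(cohort, drug, spec, ic_variance = "bate1998") {
  stopifnot(inherits(spec, "stratum_spec"))
  keep <- stratum_members(cohort, spec)
  sub <- cohort[keep, , drop = FALSE]
  exposed <- sub[[drug]]
  tab <- contingency_table(sum(exposed & sub$case), sum(exposed & !sub$case),
                           sum(!exposed & sub$case),
                           sum(!exposed & !sub$case))
  list(stratum = spec, table = tab,
       estimate = signal_estimate(tab, ic_variance = ic_variance))
}

#' Cross-stratified ROR (demographic contrast within a drug)
#'
#' Restricted to reports exposed to the drug as primary suspect, the 2x2
#' has rows stratum-vs-reference and columns target-event-vs-other-events:
#' a = stratum cases, b = stratum non-cases, c = reference cases,
#' d = reference non-cases; ROR and the Woolf CI as usual. Strata must be
#' disjoint. Swapping stratum and reference inverts the ROR exactly.
#'
#' @param cohort [build_cohort()] result.
#' @param drug label of a target drug.
#' @param spec,reference two disjoint [stratum()] definitions.
#' @return list `drug`, `stratum`, `reference`, `table`, `ror`, `ci_low`,
#'   `ci_high`, `undefined`.
#' @export
cross_stratified_ror <- function(cohort, drug, spec, reference) {
  stopifnot(inherits(spec, "stratum_spec"),
            inherits(reference, "stratum_spec"))
  if (strata_overlap(spec, reference)) {
    stop("stratum and reference overlap; cross-stratification requires ",
         "disjoint strata")
  }
  exp_rows <- cohort[cohort[[drug]], , drop = FALSE]
  in_a <- stratum_members(exp_rows, spec)
  in_b <- stratum_members(exp_rows, reference)
  tab <- contingency_table(
    sum(in_a & exp_rows$case), sum(in_a & !exp_rows$case),
    sum(in_b & exp_rows$case), sum(in_b & !exp_rows$case)
  )
  r <- ror(tab)
  list(drug = drug, stratum = spec, reference = reference, table = tab,
       ror = r$ror, ci_low = r$ci_low, ci_high = r$ci_high,
       undefined = r$undefined)
}

#' Standard sex and age strata
#'
#' The four subgroup strata (female, male, 18-74, 75+) and the four
#' sex-by-age cells used in cross-stratification.
#'
#' @return named list of [stratum()] objects.
#' @export
default_strata <- function() {
  list(
    female = stratum("Female", sex = "F"),
    male = stratum("Male", sex = "M"),
    age_18_74 = stratum("18-74", age_low = 18, age_high = 75),
    age_75_plus = stratum("75+", age_low = 75),
    female_18_74 = stratum("Middle-aged and elderly female", "F", 18, 75),
    female_75_plus = stratum("Elderly female", "F", 75),
    male_18_74 = stratum("Middle-aged and elderly male", "M", 18, 75),
    male_75_plus = stratum("Elderly male", "M", 75)
  )
}
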