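#' Convert ages to years
#'
#' FAERS records age as a value plus a unit code. Units accepted (FAERS
#' code or spelled out): DEC/DECADE x10, YR/YEAR x1, MON/MONTH /12, WK/WEEK
#' /52.1775, DY/DAY /365.25. Results outside the plausibility bound
#' \[0, 130\] years become NA, as do unknown units (with one warning).
#'
#' @param age_value numeric vector, non-negative or NA.
#' @param age_unit character vector of unit codes.
#' @return numeric vector of ages in years (NA where absent/implausible).
#' @examples
#' normalize_age(6.5, "DEC")  # 65
#' normalize_age(18, "MON")   # 1.5
#' normalize_age(200, "YR")   # NA
#' @export
normalize_age <- function(age_value, age_unit) {
  factors <- c(
    DEC = 10, DECADE = 10, YR = 1, YEAR = 1, MON = 1 / 12, MONTH = 1 / 12,
    WK = 1 / 52.1775, WEEK = 1 / 52.1775, DY = 1 / 365.25, DAY = 1 / 365.25
  )
  unit <- toupper(trimws(as.character(age_unit)))
  f <- factors[unit]
  unknown <- is.na(f) & !is.na(age_value) & !(is.na(unit) | unit == "")
  if (any(unknown)) {
    warning("unknown age unit(s): ",
            paste(unique(unit[unknown]), collapse = ", "),
            "; treating age as absent")
  }
  years <- as.numeric(age_value) * unname(f)
  years[!is.na(years) & (years < 0 | years > 130)] <- NA_real_
  years
}

#' Build typed safety reports from a DEMO table
#'
#' One row per report version: keys, receipt and event dates, sex collapsed
#' to F/M/UNKNOWN, age normalized to years, country, and (if an OUTC table
#' is given) a per-report outcome label set.
#'
#' @param demo data.frame from [read_faers_table()] (kind "DEMO").
#' @param outc optional OUTC data.frame; adds an `outcomes` list-column.
#' @return data.frame of safety reports (class `safety_reports`), one row
#'   per report version, ordered by `primary_id`.
#' @export
safety_reports <- function(demo, outc = NULL) {
  dt <- data.table::as.data.table(demo)
  out <- data.table::data.table(
    primary_id = as.integer(dt$primaryid),
    case_id = as.integer(dt$caseid),
    fda_dt = as.character(dt$fda_dt),
    event_dt = if ("event_dt" %in% names(dt)) as.character(dt$event_dt)
               else NA_character_,
    sex = map_sex(if ("sex" %in% names(dt)) dt$sex else NA),
    age_value = suppressWarnings(as.numeric(dt$age)),
    age_unit = toupper(trimws(as.character(dt$age_cod))),
    country = if ("occr_country" %in% names(dt))
      toupper(trimws(as.character(dt$occr_country))) else NA_character_
  )
  out[, age_years := normalize_age(age_value, age_unit)]
  out[country == "", country := NA_character_]
  if (!is.null(outc) && nrow(outc)) {
    oc <- data.table::as.data.table(outc)
    oc <- oc[, .(primary_id = primaryid, outcome = outcome_label(outc_cod))]
    oc <- unique(oc[!is.na(outcome)])
    agg <- oc[, .(outcomes = list(sort(outcome))), by = primary_id]
    out <- merge(out, agg, by = "primary_id", all.x = TRUE)
  }
  data.table::setorder(out, primary_id)
  out <- as.data.frame(out)
  class(out) <- c("safety_reports", class(out))
  out
}

#' Deduplicate case versions by the FDA-recommended rule
#'
#' A FAERS case can appear as several report versions. Within each
#' `case_id`, the version with the most recent receipt date (`fda_dt`)
#' survives; on ties the highest `primary_id` survives. Partial receipt
#' dates are ordered by padding absent month/day with 01 (receipt dates are
#' 8-digit in practice; the padding only buys robustness). Output is
#' ordered by ascending `primary_id`, so the result is independent of the
#' input row order, and the operation is idempotent.
#'
#' @param reports data.frame from [safety_reports()].
#' @return data.frame of the same shape with exactly one row per `case_id`.
#' @export
deduplicate_reports <- function(reports) {
  stopifnot(all(c("primary_id", "case_id", "fda_dt") %in% names(reports)))
  key <- date_sort_key(reports$fda_dt)
  o <- order(reports$case_id, key, reports$primary_id)
  last_in_group <- o[!duplicated(reports$case_id[o], fromLast = TRUE)]
  sel <- last_in_group[order(reports$primary_id[last_in_group])]
  out <- reports[sel, , drop = FALSE]
  rownames(out) <- NULL
  if (!inherits(out, "safety_reports")) {
    class(out) <- c("safety_reports", class(out))
  }
  out
}

#' Drop child rows of removed report versions
#'
#' After deduplication, DRUG/REAC/THER/OUTC rows whose `primaryid` is not
#' in the survivor set are dropped.
#'
#' @param children data.frame with a `primaryid` column.
#' @param keep_ids integer vector of surviving primary ids (or a
#'   deduplicated [safety_reports()] frame).
#' @return filtered data.frame.
#' @export
filter_children <- function(children, keep_ids) {
  if (is.data.frame(keep_ids)) keep_ids <- keep_ids$primary_id
  children[children$primaryid %in% keep_ids, , drop = FALSE]
}

#' @export
print.safety_reports <- function(x, ...) {
  cat(sprintf("<safety_reports> %d report(s), %d distinct case(s)\n",
              nrow(x), length(unique(x$case_id))))
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}
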