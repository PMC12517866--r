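#' Time to onset for a drug's target-SOC cases
#'
#' For each report that is a case and exposed to the drug as primary
#' suspect, time to onset is the event date minus the earliest complete
#' therapy start date for that drug, in whole days. Only day-resolution
#' dates enter; records with a partial or missing event/start date are
#' excluded and tallied (`n_excluded_partial`), as are negative intervals
#' (`n_excluded_negative`) — no imputation.
#'
#' @param reports deduplicated [safety_reports()] frame (supplies
#'   `event_dt`).
#' @param ther_df THER table (start dates, keyed to drug rows via
#'   `dsg_drug_seq`).
#' @param drug_df DRUG table (to identify which therapy rows belong to the
#'   drug).
#' @param cohort [build_cohort()] result.
#' @param drug label of a target drug.
#' @param dictionary [read_drug_dictionary()] object.
#' @return data.frame `primary_id`, `tto_days` (class `onset_records`) with
#'   QC attributes `n_excluded_negative`, `n_excluded_partial`.
#' @export
compute_onset <- function(reports, ther_df, drug_df, cohort, drug,
                          dictionary) {
  targets <- attr(cohort, "targets")
  stopifnot(drug %in% names(targets))
  atc <- targets[[drug]]
  ids <- cohort$primary_id[cohort[[drug]] & cohort$case]

  dr <- data.table::as.data.table(drug_df)
  dr <- dr[primaryid %in% ids & toupper(trimws(role_cod)) == "PS"]
  dr[, atc_res := resolve_drug(drugname, dictionary)]
  dr <- dr[atc_res == atc, .(primaryid, drug_seq)]

  th <- data.table::as.data.table(ther_df)[primaryid %in% ids]
  th <- merge(th, dr, by.x = c("primaryid", "dsg_drug_seq"),
              by.y = c("primaryid", "drug_seq"))
  th[, start := faers_date_as_date(start_dt)]
  th <- th[!is.na(start)]
  starts <- if (nrow(th)) th[, .(start = min(start)), by = primaryid]
            else data.table::data.table(primaryid = integer(),
                                        start = as.Date(character()))

  ev <- data.table::data.table(
    primaryid = reports$primary_id,
    event = faers_date_as_date(reports$event_dt)
  )[primaryid %in% ids]

  m <- merge(ev, starts, by = "primaryid", all.x = TRUE)
  complete <- !is.na(m$event) & !is.na(m$start)
  n_partial <- sum(!complete)
  m <- m[complete]
  m[, tto_days := as.numeric(event - start)]
  n_negative <- sum(m$tto_days < 0)
  m <- m[tto_days >= 0]

  out <- as.data.frame(m[, .(primary_id = primaryid, tto_days)])
  out <- out[order(out$primary_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drug") <- drug
  attr(out, "n_excluded_negative") <- n_negative
  attr(out, "n_excluded_partial") <- n_partial
  class(out) <- c("onset_records", class(out))
  out
}

#' Summarize time to onset as median and IQR
#'
#' Quartiles use linear interpolation between closest order statistics
#' (type 7) — the convention under which integer day counts yield
#' fractional summaries such as a median of 14.5 or a first quartile of
#' 3.25 days.
#'
#' @param records an [compute_onset()] frame, or a bare numeric vector of
#'   day counts.
#' @param type quantile type (default 7).
#' @return list `n`, `median_days`, `iqr_low`, `iqr_high` (NULL for empty
#'   input), carrying over the QC tallies when present.
#' @examples
#' summarize_onset(c(1, 5, 9, 200))$median_days # 7
#' summarize_onset(c(0, 1))$median_days         # 0.5
#' @export
summarize_onset <- function(records, type = 7) {
  x <- if (is.data.frame(records)) records$tto_days else as.numeric(records)
  if (length(x) == 0L) return(NULL)
  q <- unname(quantile(x, probs = c(0.25, 0.5, 0.75), type = type,
                       names = FALSE))
  out <- list(n = length(x), median_days = q[2], iqr_low = q[1],
              iqr_high = q[3])
  for (at in c("drug", "n_excluded_negative", "n_excluded_partial")) {
    if (!is.null(attr(records, at))) out[[at]] <- attr(records, at)
  }
  class(out) <- "onset_summary"
  out
}

#' @export
print.onset_summary <- function(x, ...) {
  cat(sprintf("<onset> %sn=%d, median %g days (IQR %g-%g)\n",
              if (!is.null(x$drug)) paste0(x$drug, ": ") else "",
              x$n, x$median_days, x$iqr_low, x$iqr_high))
  invisible(x)
}
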