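#' Label primary-suspect exposure to target drugs
#'
#' A report is exposed to a target drug iff it carries at least one DRUG
#' row for that drug with role code PS. Secondary-suspect, concomitant and
#' interacting records (SS/C/I) never create exposure — restricting to the
#' primary suspect is how confounding by co-medication is minimized in the
#' case/non-case design.
#'
#' @param drug_df DRUG table (post [filter_children()]).
#' @param targets named character vector of target ATC codes, names are the
#'   drug labels, e.g. `c(atorvastatin = "C10AA05")`.
#' @param dictionary [read_drug_dictionary()] object.
#' @return data.frame with `primary_id` and one logical column per target
#'   drug (named by label), covering only reports with at least one
#'   resolved PS target row; join against the report universe to get
#'   FALSE elsewhere.
#' @export
label_exposure <- function(drug_df, targets, dictionary) {
  stopifnot(length(targets) > 0, !is.null(names(targets)))
  dt <- data.table::as.data.table(drug_df)
  dt <- dt[toupper(trimws(role_cod)) == "PS"]
  if (nrow(dt) == 0L) {
    out <- data.frame(primary_id = integer())
    for (lab in names(targets)) out[[lab]] <- logical()
    return(out)
  }
  dt[, atc := resolve_drug(drugname, dictionary)]
  dt <- dt[atc %in% targets]
  out <- data.table::data.table(primary_id = sort(unique(dt$primaryid)))
  for (lab in names(targets)) {
    ids <- unique(dt[atc == targets[[lab]], primaryid])
    out[, (lab) := primary_id %in% ids]
  }
  as.data.frame(out)
}

#' Label case reports by target system organ class
#'
#' A report is a case iff at least one of its PTs maps to the target SOC —
#' once per report, no matter how many target-SOC PTs it carries. PTs
#' absent from the map never make a case; their count is attached as the
#' `n_unmapped` attribute for QC.
#'
#' @param reac_df REAC table (columns `primaryid` and `pt` and/or `pt_cod`).
#' @param map [read_meddra_map()] object.
#' @param target_soc integer SOC code (e.g. 10038738 for respiratory,
#'   thoracic and mediastinal disorders).
#' @return data.frame `primary_id`, `case` (all TRUE), one row per case
#'   report; `n_unmapped` attribute counts reaction rows with unmapped PTs.
#' @export
label_cases <- function(reac_df, map, target_soc) {
  dt <- data.table::as.data.table(reac_df)
  if (!"pt_cod" %in% names(dt)) dt[, pt_cod := NA_integer_]
  miss <- is.na(dt$pt_cod)
  if (any(miss) && "pt" %in% names(dt)) {
    data.table::set(dt, which(miss), "pt_cod",
                    pt_code_from_name(dt$pt[miss], map))
  }
  soc <- map$soc_code[match(dt$pt_cod, map$pt_code)]
  n_unmapped <- sum(is.na(soc))
  ids <- sort(unique(dt$primaryid[!is.na(soc) & soc == target_soc]))
  out <- data.frame(primary_id = ids, case = rep(TRUE, length(ids)))
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Build the case/non-case cohort labeling
#'
#' Joins exposure and case labels onto the deduplicated report universe.
#' The result carries, per report: the exposure flag for each target drug,
#' the case flag, and the demographics needed downstream (sex, age in
#' years, receipt date). Labels are independent of input row order.
#'
#' @param reports deduplicated [safety_reports()] frame (the analysis
#'   universe).
#' @param drug_df,reac_df child tables restricted to the survivors.
#' @param targets named character vector of target ATC codes.
#' @param dictionary [read_drug_dictionary()] object.
#' @param map [read_meddra_map()] object.
#' @param target_soc integer SOC code.
#' @return a `cohort_labeling` data.frame, one row per report in the
#'   universe.
#' @export
build_cohort <- function(reports, drug_df, reac_df, targets, dictionary,
                         map, target_soc) {
  uni <- data.table::data.table(
    primary_id = reports$primary_id,
    sex = reports$sex,
    age_years = reports$age_years,
    fda_dt = reports$fda_dt
  )
  exp <- data.table::as.data.table(
    label_exposure(drug_df, targets, dictionary))
  cas <- label_cases(reac_df, map, target_soc)
  out <- merge(uni, exp, by = "primary_id", all.x = TRUE)
  for (lab in names(targets)) {
    data.table::set(out, which(is.na(out[[lab]])), lab, FALSE)
  }
  out[, case := primary_id %in% cas$primary_id]
  data.table::setorder(out, primary_id)
  out <- as.data.frame(out)
  attr(out, "targets") <- targets
  attr(out, "target_soc") <- target_soc
  attr(out, "n_unmapped") <- attr(cas, "n_unmapped")
  class(out) <- c("cohort_labeling", class(out))
  out
}

#' Per-PT case counts for one drug
#'
#' For each PT in the target SOC, the number of exposed case reports
#' mentioning that PT. Duplicate (report, PT) rows count once, so each PT
#' count is bounded by the drug's SOC-level case count.
#'
#' @param reac_df REAC table.
#' @param cohort [build_cohort()] result.
#' @param drug label of the target drug (a name of the cohort's `targets`).
#' @param map [read_meddra_map()] object.
#' @return data.frame `pt_code`, `pt_name`, `n` sorted by descending `n`
#'   then PT name.
#' @export
pt_event_counts <- function(reac_df, cohort, drug, map) {
  stopifnot(drug %in% names(attr(cohort, "targets")))
  target_soc <- attr(cohort, "target_soc")
  exposed_cases <- cohort$primary_id[cohort[[drug]] & cohort$case]
  dt <- data.table::as.data.table(reac_df)
  if (!"pt_cod" %in% names(dt)) dt[, pt_cod := NA_integer_]
  miss <- is.na(dt$pt_cod)
  if (any(miss) && "pt" %in% names(dt)) {
    data.table::set(dt, which(miss), "pt_cod",
                    pt_code_from_name(dt$pt[miss], map))
  }
  dt <- dt[primaryid %in% exposed_cases]
  dt[, soc := map$soc_code[match(pt_cod, map$pt_code)]]
  dt <- dt[!is.na(soc) & soc == target_soc]
  dt <- unique(dt[, .(primaryid, pt_cod)])
  cnt <- dt[, .(n = .N), by = pt_cod]
  cnt[, pt_name := map$pt_name[match(pt_cod, map$pt_code)]]
  data.table::setorder(cnt, -n, pt_name)
  as.data.frame(cnt[, .(pt_code = pt_cod, pt_name, n)])
}

#' @export
print.cohort_labeling <- function(x, ...) {
  targets <- attr(x, "targets")
  cat(sprintf("<cohort_labeling> %d reports, %d cases (SOC %d)\n",
              nrow(x), sum(x$case), attr(x, "target_soc")))
  for (lab in names(targets)) {
    cat(sprintf("  %s (%s): %d exposed, %d exposed cases\n", lab,
                targets[[lab]], sum(x[[lab]]), sum(x[[lab]] & x$case)))
  }
  invisible(x)
}
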