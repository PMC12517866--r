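## Quarter strings "2014Q1" -> first/last day keys used by the window filter.
quarter_bounds <- function(q) {
  m <- regmatches(q, regexec("^([0-9]{4})Q([1-4])$", q))[[1]]
  if (length(m) != 3) stop("bad quarter string: ", q, " (want e.g. '2014Q1')")
  y <- as.integer(m[2]); k <- as.integer(m[3])
  first <- y * 10000L + (3L * (k - 1L) + 1L) * 100L + 1L
  last_month <- 3L * k
  last_day <- c(31L, 30L, 30L, 31L)[k]
  last <- y * 10000L + last_month * 100L + last_day
  c(first, last)
}

#' Pipeline configuration
#'
#' Inputs may be file paths (FAERS ASCII dialect) or an in-memory
#' [generate_faers()] dataset. The date window is a quarter range applied
#' to the receipt date (`fda_dt`) after deduplication — quarterly FAERS
#' files are organized by receipt, so the window is a receipt window.
#'
#' @param data optional `faers_dataset`.
#' @param paths optional named list of file paths (demo, drug, reac, ther,
#'   outc).
#' @param dictionary_path drug dictionary TSV.
#' @param meddra_path PT->SOC map TSV.
#' @param targets named character vector of target ATC codes.
#' @param target_soc integer SOC code.
#' @param window character c(from, to) quarter strings, e.g.
#'   c("2014Q1", "2023Q1").
#' @param strata named list of [stratum()] objects for subgroup analysis.
#' @param cross_strata list of `list(stratum =, reference =)` label pairs
#'   referring to `strata` names.
#' @param ic_variance "bate1998" or "delta".
#' @param top_k how many PTs in the ranked table.
#' @param out_dir optional output directory for TSVs + metadata JSON.
#' @param seed recorded in run metadata (the pipeline itself is
#'   deterministic).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(data = NULL, paths = NULL,
                            dictionary_path = default_dictionary_path(),
                            meddra_path = default_meddra_path(),
                            targets = c(atorvastatin = "C10AA05",
                                        rosuvastatin = "C10AA07"),
                            target_soc = 10038738L,
                            window = c("2014Q1", "2023Q1"),
                            strata = default_strata(),
                            cross_strata = default_cross_strata(),
                            ic_variance = c("bate1998", "delta"),
                            top_k = 5L,
                            out_dir = NULL,
                            seed = NULL) {
  ic_variance <- match.arg(ic_variance)
  if (is.null(data) && is.null(paths)) {
    stop("pipeline_config: one of 'data' or 'paths' is required")
  }
  if (length(targets) == 0 || is.null(names(targets))) {
    stop("pipeline_config: 'targets' must be a named, non-empty ATC vector")
  }
  w <- c(quarter_bounds(window[1])[1], quarter_bounds(window[2])[2])
  if (w[1] > w[2]) stop("pipeline_config: window start after window end")
  structure(list(data = data, paths = paths,
                 dictionary_path = dictionary_path,
                 meddra_path = meddra_path, targets = targets,
                 target_soc = as.integer(target_soc), window = window,
                 window_keys = w, strata = strata,
                 cross_strata = cross_strata, ic_variance = ic_variance,
                 top_k = as.integer(top_k), out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
default_cross_strata <- function() {
  list(list(stratum = "female_18_74", reference = "male_18_74"),
       list(stratum = "female_75_plus", reference = "male_18_74"),
       list(stratum = "female_18_74", reference = "male_75_plus"),
       list(stratum = "female_75_plus", reference = "male_75_plus"))
}

#' Run the full case/non-case pipeline
#'
#' read -> deduplicate -> receipt-window filter -> exposure/case labeling
#' -> SOC- and PT-level disproportionality -> subgroup and
#' cross-stratified ROR -> time to onset -> report tables. Each stage logs
#' its input/output row counts (collected in `$counts` and emitted as
#' messages); outputs are deterministic given the config. Any stage
#' failure aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage messages.
#' @return a `pipeline_result` list: `counts`, `cohort`, `signals`,
#'   `demographics`, `top_pt` (per drug), `subgroups`, `cross_strata`,
#'   `onset` (per drug), `qc`, `meta`.
#' @export
run_faers_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  counts <- list()

  tabs <- stage("read", {
    if (!is.null(config$data)) {
      d <- config$data
      list(demo = d$demo, drug = d$drug, reac = d$reac, ther = d$ther,
           outc = d$outc)
    } else {
      p <- config$paths
      list(demo = read_faers_table(p$demo, "DEMO"),
           drug = read_faers_table(p$drug, "DRUG"),
           reac = read_faers_table(p$reac, "REAC"),
           ther = if (!is.null(p$ther)) read_faers_table(p$ther, "THER")
                  else NULL,
           outc = if (!is.null(p$outc)) read_faers_table(p$outc, "OUTC")
                  else NULL)
    }
  })
  counts$raw_reports <- nrow(tabs$demo)
  say("read: %d report versions", counts$raw_reports)

  dictionary <- stage("dictionaries", read_drug_dictionary(config$dictionary_path))
  map <- stage("dictionaries", read_meddra_map(config$meddra_path))

  reports <- stage("deduplicate", {
    deduplicate_reports(safety_reports(tabs$demo, tabs$outc))
  })
  counts$deduplicated <- nrow(reports)
  say("deduplicate: %d -> %d reports", counts$raw_reports,
      counts$deduplicated)

  reports <- stage("window", {
    key <- date_sort_key(reports$fda_dt)
    reports[!is.na(key) & key >= config$window_keys[1] &
              key <= config$window_keys[2], , drop = FALSE]
  })
  counts$in_window <- nrow(reports)
  say("window %s..%s: %d reports", config$window[1], config$window[2],
      counts$in_window)

  keep <- reports$primary_id
  drug_df <- filter_children(tabs$drug, keep)
  reac_df <- filter_children(tabs$reac, keep)
  ther_df <- if (!is.null(tabs$ther)) filter_children(tabs$ther, keep)
             else NULL

  cohort <- stage("label", {
    build_cohort(reports, drug_df, reac_df, config$targets, dictionary,
                 map, config$target_soc)
  })
  counts$cases <- sum(cohort$case)
  for (lab in names(config$targets)) {
    counts[[paste0("exposed_", lab)]] <- sum(cohort[[lab]])
    counts[[paste0("exposed_cases_", lab)]] <- sum(cohort[[lab]] & cohort$case)
  }
  say("label: %d cases among %d reports", counts$cases, nrow(cohort))

  signals <- stage("disproportionality", {
    signal_table(cohort, reac_df, map, pt_level = TRUE,
                 ic_variance = config$ic_variance)
  })
  say("disproportionality: %d tests", attr(signals, "n_tests"))

  demographics <- stage("demographics", {
    demographics_table(reports, cohort)
  })
  top_pt <- stage("top_pt", {
    out <- list()
    for (lab in names(config$targets)) {
      out[[lab]] <- top_pt_table(pt_event_counts(reac_df, cohort, lab, map),
                                 k = config$top_k,
                                 soc_cases = sum(cohort[[lab]] & cohort$case))
    }
    out
  })

  subgroups <- stage("subgroups", {
    rows <- list()
    for (lab in names(config$targets)) {
      for (sn in names(config$strata)) {
        sg <- subgroup_signal(cohort, lab, config$strata[[sn]],
                              ic_variance = config$ic_variance)
        rows[[length(rows) + 1L]] <- data.frame(
          drug = lab, stratum = config$strata[[sn]]$label,
          a = sg$table$a, b = sg$table$b, c = sg$table$c, d = sg$table$d,
          ror = sg$estimate$ror, ci_low = sg$estimate$ror_ci_low,
          ci_high = sg$estimate$ror_ci_high, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  cross <- stage("cross_stratification", {
    rows <- list()
    for (lab in names(config$targets)) {
      for (pair in config$cross_strata) {
        cs <- cross_stratified_ror(cohort, lab,
                                   config$strata[[pair$stratum]],
                                   config$strata[[pair$reference]])
        rows[[length(rows) + 1L]] <- data.frame(
          drug = lab, stratum = cs$stratum$label,
          reference = cs$reference$label,
          a = cs$table$a, b = cs$table$b, c = cs$table$c, d = cs$table$d,
          ror = cs$ror, ci_low = cs$ci_low, ci_high = cs$ci_high,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  onset <- stage("onset", {
    out <- list()
    if (!is.null(ther_df)) {
      for (lab in names(config$targets)) {
        rec <- compute_onset(reports, ther_df, drug_df, cohort, lab,
                             dictionary)
        out[[lab]] <- list(records = rec, summary = summarize_onset(rec))
      }
    }
    out
  })

  meta <- list(package = "faersignal",
               version = as.character(utils::packageVersion("faersignal")),
               ic_variance = config$ic_variance,
               n_tests = attr(signals, "n_tests"),
               n_unmapped_pts = attr(cohort, "n_unmapped"),
               window = config$window,
               seed = config$seed)

  result <- structure(list(counts = counts, cohort = cohort,
                           signals = signals, demographics = demographics,
                           top_pt = top_pt, subgroups = subgroups,
                           cross_strata = cross, onset = onset,
                           qc = list(n_unmapped_pts = attr(cohort, "n_unmapped")),
                           meta = meta),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

write_tsv_norm <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA",
                     eol = "\n")
}

#' Write pipeline result tables as TSV plus run metadata JSON
#'
#' @param result a [run_faers_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sig <- result$signals
  num <- vapply(sig, is.numeric, logical(1))
  sig[num] <- lapply(sig[num], function(z) signif(z, 10))
  write_tsv_norm(sig, file.path(dir, "signals.tsv"))
  write_tsv_norm(result$demographics, file.path(dir, "demographics.tsv"))
  for (lab in names(result$top_pt)) {
    write_tsv_norm(result$top_pt[[lab]],
                   file.path(dir, paste0("top_pt_", lab, ".tsv")))
  }
  write_tsv_norm(result$subgroups, file.path(dir, "subgroups.tsv"))
  write_tsv_norm(result$cross_strata, file.path(dir, "cross_strata.tsv"))
  onset_rows <- lapply(names(result$onset), function(lab) {
    s <- result$onset[[lab]]$summary
    if (is.null(s)) {
      data.frame(drug = lab, n = 0L, median_days = NA_real_,
                 q1 = NA_real_, q3 = NA_real_, excluded_negative = NA_integer_,
                 excluded_partial = NA_integer_)
    } else {
      data.frame(drug = lab, n = s$n, median_days = s$median_days,
                 q1 = s$iqr_low, q3 = s$iqr_high,
                 excluded_negative = s$n_excluded_negative,
                 excluded_partial = s$n_excluded_partial)
    }
  })
  write_tsv_norm(do.call(rbind, onset_rows), file.path(dir, "onset.tsv"))
  jsonlite::write_json(c(result$meta, list(counts = result$counts)),
                       file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  reports: %d raw -> %d deduplicated -> %d in window\n",
              x$counts$raw_reports, x$counts$deduplicated,
              x$counts$in_window))
  cat(sprintf("  cases: %d; disproportionality tests: %d\n",
              x$counts$cases, x$meta$n_tests))
  soc <- x$signals[x$signals$event == "soc", ]
  for (k in seq_len(nrow(soc))) {
    cat(sprintf("  %s (SOC): ROR %.2f (%.2f-%.2f), IC %.2f, IC025 %.2f%s\n",
                soc$drug[k], soc$ror[k], soc$ror_ci_low[k],
                soc$ror_ci_high[k], soc$ic[k], soc$ic025[k],
                if (isTRUE(soc$signal[k])) " *signal*" else ""))
  }
  invisible(x)
}

#' Demographic summary of exposed case reports
#'
#' One block per characteristic (totals, sex, age bins, median age with
#' IQR, top reporting countries, outcomes, receipt year) with counts and
#' percentages per drug. Percentages use the per-drug case total as
#' denominator; the combined column uses the combined total. Rounding is
#' two decimals, half-up, at presentation only.
#'
#' @param reports deduplicated, window-filtered [safety_reports()] frame
#'   (supplies country, outcomes, receipt year).
#' @param cohort [build_cohort()] result on the same universe.
#' @param top_countries how many countries to list.
#' @return data.frame with columns `section`, `category`, then per drug
#'   `<label>_n`, `<label>_pct`, and `total_n`, `total_pct`.
#' @export
demographics_table <- function(reports, cohort, top_countries = 3L) {
  targets <- attr(cohort, "targets")
  labs <- names(targets)
  rep_dt <- data.table::as.data.table(reports)[, .(
    primary_id, sex, age_years, country, fda_dt,
    outcomes = if ("outcomes" %in% names(reports)) outcomes
               else vector("list", .N))]
  sets <- lapply(labs, function(lab) {
    ids <- cohort$primary_id[cohort[[lab]] & cohort$case]
    rep_dt[primary_id %in% ids]
  })
  names(sets) <- labs
  all_ids <- unique(unlist(lapply(sets, function(s) s$primary_id)))
  total_set <- rep_dt[primary_id %in% all_ids]
  denom <- vapply(sets, nrow, integer(1))
  denom_total <- nrow(total_set)

  row_of <- function(section, category, count_fun) {
    ns <- vapply(sets, count_fun, numeric(1))
    nt <- count_fun(total_set)
    out <- data.frame(section = section, category = category,
                      stringsAsFactors = FALSE)
    for (lab in labs) {
      out[[paste0(lab, "_n")]] <- ns[[lab]]
      out[[paste0(lab, "_pct")]] <- fmt_pct(ns[[lab]], denom[[lab]])
    }
    out$total_n <- nt
    out$total_pct <- fmt_pct(nt, denom_total)
    out
  }
  rows <- list()
  ## per-drug totals as share of the combined total
  tot <- data.frame(section = "total", category = "Total cases",
                    stringsAsFactors = FALSE)
  for (lab in labs) {
    tot[[paste0(lab, "_n")]] <- denom[[lab]]
    tot[[paste0(lab, "_pct")]] <- fmt_pct(denom[[lab]], denom_total)
  }
  tot$total_n <- denom_total
  tot$total_pct <- fmt_pct(denom_total, denom_total)
  rows[[1]] <- tot

  for (s in c("F", "M", "UNKNOWN")) {
    lab_s <- c(F = "Female", M = "Male", UNKNOWN = "Unknown")[[s]]
    rows[[length(rows) + 1L]] <-
      row_of("sex", lab_s, function(x) sum(x$sex == s))
  }
  age_bins <- list(c("<18", 0, 18), c("18-74", 18, 75), c("75+", 75, Inf),
                   c("Unknown", NA, NA))
  for (bin in age_bins) {
    if (is.na(bin[2])) {
      f <- function(x) sum(is.na(x$age_years))
    } else {
      lo <- as.numeric(bin[2]); hi <- as.numeric(bin[3])
      f <- function(x) sum(!is.na(x$age_years) & x$age_years >= lo &
                             x$age_years < hi)
    }
    rows[[length(rows) + 1L]] <- row_of("age", bin[1], f)
  }
  ## median (IQR) age, type-7, known ages only
  med <- data.frame(section = "age", category = "Median (IQR)",
                    stringsAsFactors = FALSE)
  med_fmt <- function(x) {
    v <- x$age_years[!is.na(x$age_years)]
    if (!length(v)) return("NA")
    q <- quantile_type7(v)
    sprintf("%g (%g-%g)", round(q[2], 1), round(q[1], 1), round(q[3], 1))
  }
  for (lab in labs) {
    med[[paste0(lab, "_n")]] <- NA_integer_
    med[[paste0(lab, "_pct")]] <- med_fmt(sets[[lab]])
  }
  med$total_n <- NA_integer_
  med$total_pct <- med_fmt(total_set)
  rows[[length(rows) + 1L]] <- med

  ctab <- sort(table(total_set$country[!is.na(total_set$country)]),
               decreasing = TRUE)
  for (cty in head(names(ctab), top_countries)) {
    rows[[length(rows) + 1L]] <-
      row_of("country", cty, function(x) sum(!is.na(x$country) &
                                               x$country == cty))
  }
  out_labels <- c("Hospitalization" = "HOSPITALIZATION",
                  "Other serious/important medical event" = "OTHER_SERIOUS",
                  "Death" = "DEATH", "Life-threatening" = "LIFE_THREATENING",
                  "Disability" = "DISABILITY",
                  "Congenital anomaly" = "CONGENITAL_ANOMALY")
  has_outcome <- function(x, code) {
    if (!"outcomes" %in% names(x)) return(0)
    sum(vapply(x$outcomes, function(o) !is.null(o) && code %in% o,
               logical(1)))
  }
  for (k in seq_along(out_labels)) {
    code <- out_labels[[k]]
    rows[[length(rows) + 1L]] <-
      row_of("outcome", names(out_labels)[k],
             function(x) has_outcome(x, code))
  }
  yrs <- sort(unique(substr(total_set$fda_dt, 1, 4)))
  for (y in yrs) {
    rows[[length(rows) + 1L]] <-
      row_of("year", y, function(x) sum(substr(x$fda_dt, 1, 4) == y))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ranked PT table (top-k most reported PTs)
#'
#' Ties in count break alphabetically by PT name; percentages use the
#' drug's SOC-level case total as denominator.
#'
#' @param pt_counts [pt_event_counts()] output.
#' @param k number of rows (all PTs if fewer).
#' @param soc_cases denominator; defaults to the sum of the PT counts'
#'   parent SOC case count being unknown, so pass it explicitly from the
#'   cohort.
#' @return data.frame `pt_name`, `n`, `pct`.
#' @export
top_pt_table <- function(pt_counts, k = 5L, soc_cases) {
  ord <- order(-pt_counts$n, pt_counts$pt_name)
  out <- pt_counts[ord, , drop = FALSE][seq_len(min(k, nrow(pt_counts))), ,
                                        drop = FALSE]
  out$pct <- fmt_pct(out$n, soc_cases)
  rownames(out) <- NULL
  out[, c("pt_name", "n", "pct")]
}
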