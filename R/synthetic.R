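#' Configuration for the synthetic FAERS generator
#'
#' Defaults are the study conditions the pipeline is validated under:
#' two planted statins whose reporting-odds multipliers equal the
#' SOC-level point estimates reported for them (2.05 and 1.90), a
#' demographic mix with ~52/40/9 female/male/unknown sex, ~19% missing
#' age and median age in the mid-60s, a 20% duplicate-version rate, and
#' log-normal onset times with medians 7 and 14.5 days whose spread is
#' back-solved from the printed interquartile ranges. `theta` acts on the
#' reporting *odds*, so the planted value is exactly the estimand of the
#' reporting odds ratio.
#'
#' @param n_reports number of base reports (before duplicate versions).
#' @param drugs data.frame with columns `label`, `name` (verbatim
#'   drugname stem), `atc`, `p_exposed`, `theta`, `tto_meanlog`,
#'   `tto_sdlog`.
#' @param target_soc integer SOC code events are planted in.
#' @param baseline_case_prob probability an unexposed report is a case.
#' @param strata_effects optional data.frame (`sex`, `age_low`,
#'   `age_high`, `multiplier`) of per-stratum multipliers on theta.
#' @param sex_probs named probabilities for observed sex (`F`, `M`).
#' @param p_missing_sex,p_missing_age,p_partial_date,p_missing_country
#'   missingness rates.
#' @param age_mixture list with component `weights` (child/adult/elderly).
#' @param p_duplicate_version probability a case has extra versions;
#'   `dup_geom_p` sets the geometric count of extras.
#' @param dup_geom_p geometric parameter for extra version counts.
#' @param p_nonps_target probability a report carries a target drug in a
#'   non-PS role (never exposure).
#' @param p_negative_tto probability a planted onset interval is negative
#'   (data-entry noise the pipeline must exclude).
#' @param n_pt_geom_p geometric parameter for the 1-3 PTs per report.
#' @param p_event_date probability a non-planted report has an event date.
#' @param country_probs named country probabilities.
#' @param outcome_probs named outcome-code probabilities (HO/OT/DE/LT/DS/CA);
#'   `p_any_outcome`/`p_second_outcome` set how many codes a report gets.
#' @param p_any_outcome,p_second_outcome outcome-count probabilities.
#' @param window character c(start, end) 8-digit receipt-date window.
#' @param meddra_path PT->SOC map used to pick PT vocabularies.
#' @param seed integer RNG seed.
#' @return a `synthetic_config` object.
#' @export
synthetic_config <- function(
    n_reports = 10000,
    drugs = default_synthetic_drugs(),
    target_soc = 10038738L,
    baseline_case_prob = 0.05,
    strata_effects = NULL,
    sex_probs = c(F = 0.565, M = 0.435),
    p_missing_sex = 0.086,
    p_missing_age = 0.19,
    age_mixture = list(weights = c(child = 0.011, adult = 0.730,
                                   elderly = 0.259)),
    p_duplicate_version = 0.2,
    dup_geom_p = 0.5,
    p_partial_date = 0.1,
    p_missing_country = 0.05,
    p_nonps_target = 0.01,
    p_negative_tto = 0.02,
    n_pt_geom_p = 0.6,
    p_event_date = 0.6,
    country_probs = c(CA = 0.45, US = 0.25, GB = 0.10, DE = 0.10,
                      FR = 0.05, JP = 0.05),
    outcome_probs = c(HO = 0.36, OT = 0.42, DE = 0.07, LT = 0.05,
                      DS = 0.08, CA = 0.02),
    p_any_outcome = 0.75,
    p_second_outcome = 0.15,
    window = c("20140101", "20230331"),
    meddra_path = default_meddra_path(),
    seed = 1L) {
  cfg <- as.list(environment())
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_synthetic_drugs <- function() {
  data.frame(
    label = c("atorvastatin", "rosuvastatin"),
    name = c("ATORVASTATIN", "ROSUVASTATIN"),
    atc = c("C10AA05", "C10AA07"),
    p_exposed = c(0.02, 0.02),
    theta = c(2.05, 1.90),
    tto_meanlog = log(c(7, 14.5)),
    tto_sdlog = c(3.4, 4.0),
    stringsAsFactors = FALSE
  )
}

validate_synthetic_config <- function(cfg) {
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (any(is.na(v)) || any(v < 0) || any(v > 1)) {
      stop("synthetic_config: field '", field, "' must be in [0, 1]")
    }
  }
  for (f in c("baseline_case_prob", "p_missing_sex", "p_missing_age",
              "p_duplicate_version", "dup_geom_p", "p_partial_date",
              "p_missing_country", "p_nonps_target", "p_negative_tto",
              "n_pt_geom_p", "p_event_date", "p_any_outcome",
              "p_second_outcome")) chk_prob(f)
  if (cfg$n_reports < 1) stop("synthetic_config: field 'n_reports' must be >= 1")
  d <- cfg$drugs
  need <- c("label", "name", "atc", "p_exposed", "theta", "tto_meanlog",
            "tto_sdlog")
  if (!all(need %in% names(d))) {
    stop("synthetic_config: field 'drugs' must have columns ",
         paste(need, collapse = ", "))
  }
  if (any(d$theta <= 0)) stop("synthetic_config: field 'drugs$theta' must be > 0")
  if (any(d$p_exposed < 0 | d$p_exposed > 1)) {
    stop("synthetic_config: field 'drugs$p_exposed' must be in [0, 1]")
  }
  for (f in c("sex_probs", "country_probs", "outcome_probs")) {
    v <- cfg[[f]]
    if (any(v < 0)) stop("synthetic_config: field '", f, "' must be >= 0")
  }
  w <- cfg$age_mixture$weights
  if (is.null(w) || abs(sum(w) - 1) > 1e-8) {
    stop("synthetic_config: field 'age_mixture$weights' must sum to 1")
  }
  if (!is.null(cfg$strata_effects)) {
    se <- cfg$strata_effects
    if (!all(c("sex", "age_low", "age_high", "multiplier") %in% names(se))) {
      stop("synthetic_config: field 'strata_effects' must have columns ",
           "sex, age_low, age_high, multiplier")
    }
    if (any(se$multiplier <= 0)) {
      stop("synthetic_config: field 'strata_effects$multiplier' must be > 0")
    }
  }
  invisible(TRUE)
}

## uniform draw of 8-digit dates in [from, to]
random_faers_dates <- function(n, from, to) {
  d0 <- as.Date(from, format = "%Y%m%d")
  d1 <- as.Date(to, format = "%Y%m%d")
  format(d0 + floor(runif(n, 0, as.numeric(d1 - d0) + 1)), "%Y%m%d")
}

## date lookup table: integer day-of-epoch -> "YYYYMMDD"; formatting a few
## thousand calendar days once is far cheaper than formatting per report
make_date_lut <- function(from, to, pad_before = 400, pad_after = 6500) {
  d0 <- as.integer(as.Date(from, format = "%Y%m%d"))
  d1 <- as.integer(as.Date(to, format = "%Y%m%d"))
  origin <- d0 - pad_before
  days <- seq.int(origin, d1 + pad_after)
  list(origin = origin, last = d1 + pad_after,
       keys = format(as.Date(days, origin = "1970-01-01"), "%Y%m%d"),
       win0 = d0, win1 = d1)
}

lut_random_days <- function(lut, n) {
  lut$win0 + floor(runif(n, 0, lut$win1 - lut$win0 + 1))
}

lut_key <- function(lut, day) {
  day <- pmin(pmax(day, lut$origin), lut$last)
  lut$keys[day - lut$origin + 1L]
}

truncate_dates <- function(x, p_partial) {
  hit <- runif(length(x)) < p_partial & !is.na(x) & x != ""
  if (any(hit)) {
    to_month <- hit & runif(length(x)) < 0.7
    x[to_month] <- substr(x[to_month], 1, 6)
    x[hit & !to_month] <- substr(x[hit & !to_month], 1, 4)
  }
  x
}

#' Generate a synthetic FAERS dataset with known ground truth
#'
#' Emulates the FAERS relational schema: a DEMO table with duplicate case
#' versions, partial dates and missing demographics; role-coded DRUG rows
#' (PS creates exposure, SS/C/I never does); PT-coded REAC rows (1-3 per
#' report so the once-per-report case rule is exercised); THER start dates
#' and DEMO event dates consistent with the per-drug log-normal onset
#' model for planted exposed cases; and OUTC rows. Case status follows a
#' per-report logistic model: odds(case) = baseline odds x theta^exposed
#' x stratum multiplier. Fully reproducible given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return a `faers_dataset`: list with elements `demo`, `drug`, `reac`,
#'   `ther`, `outc` (data.frames in the FAERS dialect), `truth` (planted
#'   theta table, survivor map `case_id` -> `primary_id`, and per-case base
#'   flags) and `config`.
#' @export
generate_faers <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- as.integer(config$n_reports)
  drugs <- config$drugs
  nd <- nrow(drugs)
  map <- read_meddra_map(config$meddra_path)
  resp_pts <- map[map$soc_code == config$target_soc, ]
  bg_pts <- map[map$soc_code != config$target_soc, ]
  if (nrow(resp_pts) == 0L || nrow(bg_pts) == 0L) {
    stop("synthetic_config: field 'meddra_path' must provide PTs inside ",
         "and outside target_soc")
  }
  resp_w <- 1 / seq_len(nrow(resp_pts))
  bg_w <- 1 / seq_len(nrow(bg_pts))

  ## --- demographics -------------------------------------------------------
  sexp <- config$sex_probs / sum(config$sex_probs)
  sex <- sample(names(sexp), n, replace = TRUE, prob = sexp)
  sex[runif(n) < config$p_missing_sex] <- ""

  comp <- sample(names(config$age_mixture$weights), n, replace = TRUE,
                 prob = config$age_mixture$weights)
  age_years <- numeric(n)
  i <- comp == "child"
  age_years[i] <- runif(sum(i), 0.1, 17.9)
  i <- comp == "adult"
  age_years[i] <- pmin(pmax(rnorm(sum(i), 62, 12), 18), 74.9)
  i <- comp == "elderly"
  age_years[i] <- pmin(75 + stats::rexp(sum(i), 1 / 6), 105)
  age_years[runif(n) < config$p_missing_age] <- NA_real_

  age_cod <- rep("YR", n)
  age_val <- round(age_years)
  young <- !is.na(age_years) & age_years < 2
  age_cod[young] <- "MON"
  age_val[young] <- round(age_years[young] * 12)
  dec <- !is.na(age_years) & runif(n) < 0.005 & !young
  age_cod[dec] <- "DEC"
  age_val[dec] <- round(age_years[dec] / 10, 1)
  age_cod[is.na(age_years)] <- ""

  cp <- config$country_probs / sum(config$country_probs)
  country <- sample(names(cp), n, replace = TRUE, prob = cp)
  country[runif(n) < config$p_missing_country] <- ""

  lut <- make_date_lut(config$window[1], config$window[2])
  fda_day <- lut_random_days(lut, n)
  fda_dt <- lut_key(lut, fda_day)

  ## --- exposure and case status -------------------------------------------
  expo <- matrix(runif(n * nd) < rep(drugs$p_exposed, each = n), n, nd)
  colnames(expo) <- drugs$label

  mult <- rep(1, n)
  if (!is.null(config$strata_effects)) {
    se <- config$strata_effects
    for (k in seq_len(nrow(se))) {
      hit <- (se$sex[k] == "ANY" | sex == se$sex[k]) &
        !is.na(age_years) & age_years >= se$age_low[k] &
        age_years < se$age_high[k]
      mult[hit] <- mult[hit] * se$multiplier[k]
    }
  }
  log_odds <- qlogis(config$baseline_case_prob) +
    (expo %*% log(drugs$theta))[, 1] +
    log(mult) * (rowSums(expo) > 0)
  case <- runif(n) < plogis(log_odds)

  ## --- reactions ----------------------------------------------------------
  n_pt <- 1L + pmin(rgeom(n, config$n_pt_geom_p), 2L)
  rid_first <- which(case)
  first_pt <- sample.int(nrow(resp_pts), length(rid_first), replace = TRUE,
                         prob = resp_w)
  n_extra <- n_pt - ifelse(case, 1L, 0L)
  rid_extra <- rep(seq_len(n), n_extra)
  extra_case <- case[rid_extra]
  extra_pt_code <- integer(length(rid_extra))
  extra_pt_name <- character(length(rid_extra))
  ## case reports may carry any additional PT; non-case extras must stay
  ## outside the target SOC or they would silently become cases
  if (any(extra_case)) {
    pool <- rbind(resp_pts[, c("pt_code", "pt_name")],
                  bg_pts[, c("pt_code", "pt_name")])
    pool_w <- c(resp_w * 0.3, bg_w)
    j <- sample.int(nrow(pool), sum(extra_case), replace = TRUE, prob = pool_w)
    extra_pt_code[extra_case] <- pool$pt_code[j]
    extra_pt_name[extra_case] <- pool$pt_name[j]
  }
  if (any(!extra_case)) {
    j <- sample.int(nrow(bg_pts), sum(!extra_case), replace = TRUE,
                    prob = bg_w)
    extra_pt_code[!extra_case] <- bg_pts$pt_code[j]
    extra_pt_name[!extra_case] <- bg_pts$pt_name[j]
  }
  reac_rid <- c(rid_first, rid_extra)
  reac_code <- c(resp_pts$pt_code[first_pt], extra_pt_code)
  reac_name <- c(resp_pts$pt_name[first_pt], extra_pt_name)

  ## --- drug rows ----------------------------------------------------------
  drug_rows <- list()
  for (d in seq_len(nd)) {
    rid <- which(expo[, d])
    if (!length(rid)) next
    nm <- rep(drugs$name[d], length(rid))
    v <- runif(length(rid))
    nm[v < 0.25] <- paste(nm[v < 0.25], "CALCIUM")
    dose <- runif(length(rid)) < 0.2
    nm[dose] <- paste(nm[dose], sample(c("10MG", "20MG", "40 MG"),
                                       sum(dose), replace = TRUE))
    drug_rows[[length(drug_rows) + 1L]] <- data.table::data.table(
      rid = rid, role_cod = "PS", drugname = nm, d_index = d)
    ## target drug in a non-exposure role on other reports
    rid2 <- which(!expo[, d] & runif(n) < config$p_nonps_target)
    if (length(rid2)) {
      drug_rows[[length(drug_rows) + 1L]] <- data.table::data.table(
        rid = rid2,
        role_cod = sample(c("SS", "C", "I"), length(rid2), replace = TRUE),
        drugname = drugs$name[d], d_index = 0L)
    }
  }
  bg_names <- c("IBUPROFEN", "METFORMIN", "ASPIRIN", "LISINOPRIL",
                "AMLODIPINE", "OMEPRAZOLE", "LEVOTHYROXINE", "GABAPENTIN",
                "SERTRALINE", "PREDNISONE", "WARFARIN", "FUROSEMIDE",
                "METOPROLOL", "LOSARTAN", "PANTOPRAZOLE")
  unexposed <- which(rowSums(expo) == 0)
  drug_rows[[length(drug_rows) + 1L]] <- data.table::data.table(
    rid = unexposed, role_cod = "PS",
    drugname = sample(bg_names, length(unexposed), replace = TRUE),
    d_index = 0L)
  n_conco <- pmin(rgeom(n, 0.6), 2L)
  rid_c <- rep(seq_len(n), n_conco)
  if (length(rid_c)) {
    drug_rows[[length(drug_rows) + 1L]] <- data.table::data.table(
      rid = rid_c,
      role_cod = sample(c("SS", "C"), length(rid_c), replace = TRUE),
      drugname = sample(bg_names, length(rid_c), replace = TRUE),
      d_index = 0L)
  }
  drug_dt <- data.table::rbindlist(drug_rows)
  data.table::setorder(drug_dt, rid, -role_cod) # PS rows first within report
  drug_dt[, drug_seq := seq_len(.N), by = rid]

  ## --- therapy + event dates ----------------------------------------------
  ## the first exposed target drug of a case report drives the event date
  first_exp <- rep(0L, n)
  for (d in rev(seq_len(nd))) first_exp[expo[, d]] <- d
  event_dt <- rep("", n)
  planted <- which(case & first_exp > 0)
  ther_rid <- integer(); ther_d <- integer()
  ther_start_day <- integer()
  if (length(planted)) {
    d_of <- first_exp[planted]
    ## onset intervals capped at 6000 days: far beyond the study window,
    ## but keeps the lognormal tail from generating absurd calendar dates
    tto <- pmin(round(rlnorm(length(planted), drugs$tto_meanlog[d_of],
                             drugs$tto_sdlog[d_of])), 6000)
    neg <- runif(length(planted)) < config$p_negative_tto
    tto[neg] <- -sample(1:30, sum(neg), replace = TRUE)
    start <- lut_random_days(lut, length(planted))
    event_dt[planted] <- lut_key(lut, start + tto)
    ther_rid <- planted; ther_d <- d_of
    ther_start_day <- start
  }
  ## therapy rows for the remaining exposed (report, drug) pairs
  for (d in seq_len(nd)) {
    rid <- which(expo[, d])
    rid <- rid[!(rid %in% planted & first_exp[rid] == d)]
    rid <- rid[runif(length(rid)) < 0.8]
    if (!length(rid)) next
    ther_rid <- c(ther_rid, rid)
    ther_d <- c(ther_d, rep(d, length(rid)))
    ther_start_day <- c(ther_start_day, lut_random_days(lut, length(rid)))
  }
  ## occasional second, later therapy course (earliest-start rule)
  if (length(ther_rid)) {
    extra <- which(runif(length(ther_rid)) < 0.1)
    if (length(extra)) {
      ther_rid <- c(ther_rid, ther_rid[extra])
      ther_d <- c(ther_d, ther_d[extra])
      ther_start_day <- c(ther_start_day,
                          ther_start_day[extra] +
                            sample(30:400, length(extra), replace = TRUE))
    }
  }
  ther_start <- lut_key(lut, ther_start_day)
  end_dt <- rep("", length(ther_rid))
  has_end <- runif(length(ther_rid)) < 0.4
  if (any(has_end)) {
    end_dt[has_end] <- lut_key(lut, ther_start_day[has_end] +
                                 sample(1:365, sum(has_end), replace = TRUE))
  }
  ## non-planted reports sometimes carry an (uninformative) event date
  others <- which(event_dt == "" & runif(n) < config$p_event_date)
  event_dt[others] <- lut_key(lut, lut_random_days(lut, length(others)))
  event_dt <- truncate_dates(event_dt, config$p_partial_date)
  ther_start <- truncate_dates(ther_start, config$p_partial_date)
  end_dt <- truncate_dates(end_dt, config$p_partial_date * 3)

  ## --- outcomes ------------------------------------------------------------
  op <- config$outcome_probs / sum(config$outcome_probs)
  o1_rid <- which(runif(n) < config$p_any_outcome)
  o1 <- sample(names(op), length(o1_rid), replace = TRUE, prob = op)
  o2_rid <- o1_rid[runif(length(o1_rid)) < config$p_second_outcome]
  o2 <- sample(names(op), length(o2_rid), replace = TRUE, prob = op)
  outc_rid <- c(o1_rid, o2_rid)
  outc_cod <- c(o1, o2)

  ## --- duplicate case versions and primary ids ----------------------------
  is_dup <- runif(n) < config$p_duplicate_version
  k_extra <- ifelse(is_dup, pmin(rgeom(n, config$dup_geom_p) + 1L, 3L), 0L)
  version_rid <- c(seq_len(n), rep(seq_len(n), k_extra))
  n_total <- length(version_rid)
  delta <- integer(n_total)
  extra_idx <- seq.int(n + 1L, length.out = n_total - n)
  if (length(extra_idx)) {
    tie <- runif(length(extra_idx)) < 0.3
    delta[extra_idx] <- ifelse(tie, 0L,
                               sample(c(-200:-1, 1:200), length(extra_idx),
                                      replace = TRUE))
  }
  v_fda_day <- fda_day[version_rid] + delta
  v_fda <- lut_key(lut, v_fda_day)
  pid <- sample.int(n_total) # random ids: ties break on pid both ways

  demo <- data.frame(
    primaryid = pid,
    caseid = version_rid,
    fda_dt = v_fda,
    event_dt = event_dt[version_rid],
    sex = sex[version_rid],
    age = as.numeric(age_val)[version_rid],
    age_cod = age_cod[version_rid],
    occr_country = country[version_rid],
    stringsAsFactors = FALSE
  )

  ## children are copied into every version of their case
  vmap <- data.table::data.table(rid = version_rid, primaryid = pid)
  expand <- function(rid, ...) {
    dt <- data.table::data.table(rid = rid, ...)
    if (n_total == n) { # no duplicate versions: direct id mapping
      out <- dt
      out[, primaryid := pid[rid]]
      out[, rid := NULL]
    } else {
      out <- merge(vmap, dt, by = "rid", allow.cartesian = TRUE)
      out[, rid := NULL]
    }
    data.table::setorder(out, primaryid)
    out
  }
  drug_tab <- expand(drug_dt$rid, drug_seq = drug_dt$drug_seq,
                     role_cod = drug_dt$role_cod,
                     drugname = drug_dt$drugname)
  reac_tab <- expand(reac_rid, pt = reac_name, pt_cod = reac_code)
  ther_tab <- if (length(ther_rid)) {
    seq_of <- drug_dt[d_index > 0 & role_cod == "PS",
                      .(rid, d_index, drug_seq)]
    th <- data.table::data.table(rid = ther_rid, d_index = ther_d,
                                 start_dt = ther_start, end_dt = end_dt)
    th <- merge(th, seq_of, by = c("rid", "d_index"))
    expand(th$rid, dsg_drug_seq = th$drug_seq, start_dt = th$start_dt,
           end_dt = th$end_dt)
  } else {
    data.table::data.table(primaryid = integer(), dsg_drug_seq = integer(),
                           start_dt = character(), end_dt = character())
  }
  outc_tab <- expand(outc_rid, outc_cod = outc_cod)

  ## ground truth: survivor per case by the max-(fda, pid) rule
  if (n_total == n) {
    surv <- data.table::data.table(case_id = seq_len(n), primary_id = pid)
  } else {
    vt <- data.table::data.table(rid = version_rid, pid = pid,
                                 key_dt = v_fda_day)
    data.table::setorder(vt, rid, key_dt, pid)
    surv <- vt[vt[, .I[.N], by = rid]$V1, .(case_id = rid, primary_id = pid)]
  }

  base <- data.frame(case_id = seq_len(n), case = case, sex = sex,
                     age_years = age_years, stringsAsFactors = FALSE)
  for (d in seq_len(nd)) base[[drugs$label[d]]] <- expo[, d]

  structure(list(
    demo = demo,
    drug = as.data.frame(drug_tab[, .(primaryid, drug_seq, role_cod,
                                      drugname)]),
    reac = as.data.frame(reac_tab[, .(primaryid, pt, pt_cod)]),
    ther = as.data.frame(ther_tab[, .(primaryid, dsg_drug_seq, start_dt,
                                      end_dt)]),
    outc = as.data.frame(outc_tab[, .(primaryid, outc_cod)]),
    truth = list(
      theta = drugs[, c("label", "atc", "theta")],
      survivors = as.data.frame(surv[order(case_id)]),
      base = base
    ),
    config = config
  ), class = "faers_dataset")
}

#' @export
print.faers_dataset <- function(x, ...) {
  cat(sprintf(
    "<faers_dataset> %d report versions (%d cases); DRUG %d, REAC %d, THER %d, OUTC %d rows\n",
    nrow(x$demo), length(unique(x$demo$caseid)), nrow(x$drug), nrow(x$reac),
    nrow(x$ther), nrow(x$outc)))
  invisible(x)
}

#' Write a synthetic dataset as FAERS ASCII tables
#'
#' Writes DEMO/DRUG/REAC/THER/OUTC in the "$" dialect plus the ground
#' truth as JSON.
#'
#' @param ds a [generate_faers()] dataset.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_faers_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "faers_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (kind in c("DEMO", "DRUG", "REAC", "THER", "OUTC")) {
    write_faers_table(ds[[tolower(kind)]],
                      file.path(dir, paste0(tolower(kind), ".txt")), kind)
  }
  jsonlite::write_json(
    list(theta = ds$truth$theta, survivors = ds$truth$survivors),
    file.path(dir, "ground_truth.json"), dataframe = "columns",
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' A small deterministic dataset with hand-checkable structure
#'
#' 200 generated base reports (fixed seed, elevated exposure so the 2x2
#' cells are populated) plus four crafted reports that guarantee coverage
#' of every exclusion rule: a target drug in concomitant role only with
#' unknown sex, an exposed case with a month-resolution event date, an
#' exposed case with a negative onset interval, and a clean exposed case
#' with a duplicated reaction row (7-day onset).
#'
#' @return a `faers_dataset`.
#' @export
fixture_small <- function() {
  cfg <- synthetic_config(
    n_reports = 200, seed = 101L,
    drugs = within(default_synthetic_drugs(), p_exposed <- c(0.15, 0.15)),
    p_nonps_target = 0.05, p_negative_tto = 0.05, p_partial_date = 0.15
  )
  ds <- generate_faers(cfg)
  add <- function(df, ...) rbind(df, data.frame(..., stringsAsFactors = FALSE))
  ## crafted reports (primaryid 990001.., caseid 9001..)
  ds$demo <- add(ds$demo,
    primaryid = 990001:990004, caseid = 9001:9004,
    fda_dt = c("20220315", "20220401", "20220501", "20220410"),
    event_dt = c("", "202203", "20220401", "20220310"),
    sex = c("", "F", "M", "F"),
    age = c(60, 70, 55, 66), age_cod = c("YR", "YR", "YR", "YR"),
    occr_country = c("US", "CA", "CA", "US"))
  ds$drug <- add(ds$drug,
    primaryid = c(990001L, 990002L, 990003L, 990004L),
    drug_seq = 1L, role_cod = c("C", "PS", "PS", "PS"),
    drugname = c("ATORVASTATIN", "ATORVASTATIN", "ROSUVASTATIN",
                 "ATORVASTATIN CALCIUM 20MG"))
  ds$reac <- add(ds$reac,
    primaryid = c(990001L, 990002L, 990003L, 990004L, 990004L),
    pt = c("Dyspnoea", "Cough", "Dyspnoea", "Dyspnoea", "Dyspnoea"),
    pt_cod = c(10013968L, 10011224L, 10013968L, 10013968L, 10013968L))
  ds$ther <- add(ds$ther,
    primaryid = c(990002L, 990003L, 990004L), dsg_drug_seq = 1L,
    start_dt = c("20220301", "20220501", "20220303"), end_dt = "")
  ds$truth$survivors <- rbind(
    ds$truth$survivors,
    data.frame(case_id = 9001:9004, primary_id = 990001:990004))
  crafted <- data.frame(case_id = 9001:9004,
                        case = TRUE,
                        sex = c("", "F", "M", "F"),
                        age_years = c(60, 70, 55, 66),
                        atorvastatin = c(FALSE, TRUE, FALSE, TRUE),
                        rosuvastatin = c(FALSE, FALSE, TRUE, FALSE),
                        stringsAsFactors = FALSE)
  ds$truth$base <- rbind(ds$truth$base, crafted)
  ds
}
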