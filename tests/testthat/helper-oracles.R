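# Independent brute-force oracles, deliberately written with plain loops /
# split-apply so they share no code path with the package internals.

# survivor per case: max fda (padded), tie -> max primary_id
oracle_dedup <- function(demo_like) {
  pad <- function(s) {
    s <- as.character(s)
    n <- nchar(s)
    s[n == 4] <- paste0(s[n == 4], "0101")
    s[n == 6] <- paste0(s[n == 6], "01")
    out <- suppressWarnings(as.numeric(s))
    out[is.na(out)] <- -1
    out
  }
  groups <- split(seq_len(nrow(demo_like)), demo_like$case_id)
  keep <- vapply(groups, function(ix) {
    f <- pad(demo_like$fda_dt[ix])
    best <- ix[f == max(f)]
    best[which.max(demo_like$primary_id[best])]
  }, integer(1))
  sort(demo_like$primary_id[keep])
}

# PS-exposure report ids for one ATC code by linear scan
oracle_exposure <- function(drug_df, atc, dict) {
  hits <- integer(0)
  for (i in seq_len(nrow(drug_df))) {
    if (toupper(trimws(drug_df$role_cod[i])) != "PS") next
    code <- resolve_drug(drug_df$drugname[i], dict)
    if (!is.na(code) && code == atc) hits <- c(hits, drug_df$primaryid[i])
  }
  sort(unique(hits))
}

# case report ids: any PT mapping to the target SOC
oracle_cases <- function(reac_df, map, soc) {
  pts <- map$pt_code[map$soc_code == soc]
  code <- reac_df$pt_cod
  if (is.null(code)) code <- map$pt_code[match(toupper(reac_df$pt),
                                               toupper(map$pt_name))]
  sort(unique(reac_df$primaryid[!is.na(code) & code %in% pts]))
}

# a/b/c/d by double scan over the report universe
oracle_contingency <- function(universe_ids, exposed_ids, case_ids) {
  a <- b <- cc <- d <- 0L
  exposed_ids <- unique(exposed_ids); case_ids <- unique(case_ids)
  for (id in universe_ids) {
    e <- id %in% exposed_ids
    k <- id %in% case_ids
    if (e && k) a <- a + 1L else if (e) b <- b + 1L
    else if (k) cc <- cc + 1L else d <- d + 1L
  }
  c(a = a, b = b, c = cc, d = d)
}

# per-PT exposed-case counts by nested loops, once per (report, PT)
oracle_pt_counts <- function(reac_df, exposed_case_ids, map, soc) {
  tally <- list()
  for (id in exposed_case_ids) {
    rows <- reac_df[reac_df$primaryid == id, , drop = FALSE]
    seen <- character(0)
    for (j in seq_len(nrow(rows))) {
      code <- rows$pt_cod[j]
      if (is.na(code)) next
      k <- match(code, map$pt_code)
      if (is.na(k) || map$soc_code[k] != soc) next
      key <- as.character(code)
      if (key %in% seen) next
      seen <- c(seen, key)
      tally[[key]] <- (tally[[key]] %||% 0L) + 1L
    }
  }
  tally
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small single-drug generator config used across simulation tests
sim_config <- function(n, theta, seed, p_exposed = 0.02, baseline = 0.05,
                       sdlog = 1.5, ...) {
  synthetic_config(
    n_reports = n,
    drugs = data.frame(label = "druga", name = "ATORVASTATIN",
                       atc = "C10AA05", p_exposed = p_exposed,
                       theta = theta, tto_meanlog = log(7),
                       tto_sdlog = sdlog, stringsAsFactors = FALSE),
    baseline_case_prob = baseline,
    p_duplicate_version = 0, p_partial_date = 0,
    seed = seed, ...
  )
}

sim_targets <- c(druga = "C10AA05")

# dedup -> label -> SOC 2x2, the estimator path used by the simulations
sim_soc_table <- function(ds, dict, map) {
  rep <- deduplicate_reports(safety_reports(ds$demo))
  coh <- build_cohort(rep, filter_children(ds$drug, rep),
                      filter_children(ds$reac, rep),
                      sim_targets, dict, map, 10038738L)
  build_contingency(coh, "druga")
}

shared_dict <- read_drug_dictionary()
shared_map <- read_meddra_map()
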