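test_that("generation is deterministic given the seed", {
  cfg <- synthetic_config(n_reports = 300, seed = 71)
  d1 <- generate_faers(cfg)
  d2 <- generate_faers(cfg)
  for (tab in c("demo", "drug", "reac", "ther", "outc")) {
    expect_identical(d1[[tab]], d2[[tab]], label = tab)
  }
  expect_identical(d1$truth$survivors, d2$truth$survivors)
  d3 <- generate_faers(synthetic_config(n_reports = 300, seed = 72))
  expect_false(identical(d1$demo, d3$demo))
})

test_that("config validation names the offending field", {
  expect_error(synthetic_config(n_reports = 0), "n_reports")
  expect_error(synthetic_config(p_duplicate_version = 1.2),
               "p_duplicate_version")
  expect_error(synthetic_config(
    drugs = within(default_synthetic_drugs(), theta <- c(-1, 2))), "theta")
  expect_error(synthetic_config(
    age_mixture = list(weights = c(child = 0.5, adult = 0.2,
                                   elderly = 0.2))), "age_mixture")
  expect_error(synthetic_config(
    strata_effects = data.frame(sex = "F", age_low = 0, age_high = Inf)),
    "strata_effects")
})

test_that("generated tables pass schema validation and join integrity", {
  ds <- generate_faers(synthetic_config(n_reports = 400, seed = 73))
  dir <- withr::local_tempdir()
  write_faers_dataset(ds, dir)
  demo <- read_faers_table(file.path(dir, "demo.txt"), "DEMO")
  expect_equal(nrow(demo), nrow(ds$demo))
  pids <- demo$primaryid
  expect_false(anyDuplicated(pids) > 0)
  for (tab in c("drug", "reac", "ther", "outc")) {
    child <- read_faers_table(file.path(dir, paste0(tab, ".txt")),
                              toupper(tab))
    expect_true(all(child$primaryid %in% pids), label = tab)
  }
})

test_that("the survivor map is consistent with the dedup rule by construction", {
  ds <- generate_faers(synthetic_config(n_reports = 1500, seed = 74,
                                        p_duplicate_version = 0.2))
  reports <- safety_reports(ds$demo)
  expect_equal(deduplicate_reports(reports)$primary_id,
               sort(ds$truth$survivors$primary_id))
  expect_equal(sort(ds$truth$survivors$case_id),
               sort(unique(ds$demo$caseid)))
})

test_that("null data produce near-null tables; planted theta is recovered", {
  # theta = 1: the Woolf CI covers 1 in most replicates
  cover <- 0L
  for (s in 1:30) {
    ds <- generate_faers(sim_config(20000, theta = 1, seed = 700 + s))
    tab <- sim_soc_table(ds, shared_dict, shared_map)
    r <- ror(tab)
    if (!r$undefined && r$ci_low <= 1 && 1 <= r$ci_high) cover <- cover + 1L
  }
  expect_gte(cover, 26)   # ~95% coverage, small-sample slack

  # theta = 3 at larger n: estimate lands inside its own CI neighborhood
  ds <- generate_faers(sim_config(100000, theta = 3, seed = 75))
  r <- ror(sim_soc_table(ds, shared_dict, shared_map))
  expect_true(r$ci_low <= 3 && 3 <= r$ci_high)
  expect_lt(abs(log(r$ror) - log(3)), 0.25)
})

test_that("realized ROR concentrates on theta as the dataset grows", {
  sizes <- c(5000, 20000, 80000)
  mae <- vapply(sizes, function(n) {
    errs <- vapply(1:8, function(s) {
      ds <- generate_faers(sim_config(n, theta = 2, seed = 800 + s,
                                      p_exposed = 0.05))
      r <- ror(sim_soc_table(ds, shared_dict, shared_map))
      abs(log(r$ror) - log(2))
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(mae) < 0))
})

test_that("the small fixture covers every exclusion rule and is stable", {
  fx1 <- fixture_small()
  fx2 <- fixture_small()
  expect_identical(fx1$demo, fx2$demo)
  expect_identical(fx1$reac, fx2$reac)

  demo <- fx1$demo
  expect_true(any(demo$sex == ""))                     # unknown sex
  pd <- parse_faers_date(demo$event_dt[demo$event_dt != ""])
  expect_true(any(pd$resolution %in% c("YEAR", "MONTH"))) # partial date
  expect_true(any(fx1$drug$role_cod == "C" &
                    grepl("ATORVASTATIN", fx1$drug$drugname))) # role C target

  # crafted negative-onset report is excluded by the pipeline
  rep <- deduplicate_reports(safety_reports(demo))
  coh <- build_cohort(rep, filter_children(fx1$drug, rep),
                      filter_children(fx1$reac, rep),
                      c(atorvastatin = "C10AA05", rosuvastatin = "C10AA07"),
                      shared_dict, shared_map, 10038738L)
  rec <- compute_onset(rep, filter_children(fx1$ther, rep),
                       filter_children(fx1$drug, rep), coh, "rosuvastatin",
                       shared_dict)
  expect_gte(attr(rec, "n_excluded_negative"), 1L)
  # crafted 7-day atorvastatin onset present
  rec_a <- compute_onset(rep, filter_children(fx1$ther, rep),
                         filter_children(fx1$drug, rep), coh, "atorvastatin",
                         shared_dict)
  expect_true(7 %in% rec_a$tto_days)
  # concomitant-only report is not exposed
  expect_false(coh$atorvastatin[coh$primary_id == 990001])
  expect_true(coh$case[coh$primary_id == 990001])
})

test_that("fixture outputs match the committed brute-force expectations", {
  want <- jsonlite::fromJSON(test_path("fixture_small_expected.json"))
  fx <- fixture_small()
  rep <- deduplicate_reports(safety_reports(fx$demo))
  expect_equal(nrow(rep), want$n_survivors)
  targets <- c(atorvastatin = "C10AA05", rosuvastatin = "C10AA07")
  coh <- build_cohort(rep, filter_children(fx$drug, rep),
                      filter_children(fx$reac, rep), targets,
                      shared_dict, shared_map, 10038738L)
  for (lab in names(targets)) {
    tab <- build_contingency(coh, lab)
    w <- want[[paste0("table_", lab)]]
    expect_equal(c(tab$a, tab$b, tab$c, tab$d),
                 as.numeric(c(w$a, w$b, w$c, w$d)), label = lab)
    rec <- compute_onset(rep, filter_children(fx$ther, rep),
                         filter_children(fx$drug, rep), coh, lab,
                         shared_dict)
    expect_equal(sort(rec$tto_days), as.numeric(want[[paste0("tto_", lab)]]),
                 label = lab)
    d <- want[[paste0("demog_", lab)]]
    sub <- rep[rep$primary_id %in% coh$primary_id[coh[[lab]] & coh$case], ]
    expect_equal(nrow(sub), d$total, label = lab)
    expect_equal(sum(sub$sex == "F"), d$female, label = lab)
    expect_equal(sum(sub$sex == "M"), d$male, label = lab)
    expect_equal(sum(sub$sex == "UNKNOWN"), d$unknown_sex, label = lab)
  }
})
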