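test_that("drug resolution strips dose tokens and knows brand synonyms", {
  expect_equal(resolve_drug("ATORVASTATIN CALCIUM 20MG", shared_dict),
               "C10AA05")
  expect_equal(resolve_drug("  lipitor ", shared_dict), "C10AA05")
  expect_equal(resolve_drug("CRESTOR 10 MG", shared_dict), "C10AA07")
  expect_true(is.na(resolve_drug("ABC123XYZ", shared_dict)))
  expect_equal(resolve_drug("IBUPROFEN", shared_dict), "M01AE01")
  # exact-after-normalization only; no fuzzy matching
  expect_true(is.na(resolve_drug("ATORVASTATN", shared_dict)))
})

test_that("only primary-suspect records create exposure", {
  drug_df <- data.frame(
    primaryid = c(1L, 2L, 2L, 3L, 4L),
    drug_seq = 1:5,
    role_cod = c("C", "PS", "C", "SS", "PS"),
    drugname = c("ATORVASTATIN", "ROSUVASTATIN", "ATORVASTATIN",
                 "ATORVASTATIN", "LIPITOR 20MG"),
    stringsAsFactors = FALSE
  )
  targets <- c(atorvastatin = "C10AA05", rosuvastatin = "C10AA07")
  ex <- label_exposure(drug_df, targets, shared_dict)
  expect_false(1L %in% ex$primary_id)            # concomitant only
  expect_true(ex$rosuvastatin[ex$primary_id == 2L])
  expect_false(ex$atorvastatin[ex$primary_id == 2L]) # C role ignored
  expect_false(3L %in% ex$primary_id)            # secondary suspect
  expect_true(ex$atorvastatin[ex$primary_id == 4L])  # brand + dose
})

test_that("exposure labels equal the linear-scan oracle on synthetic data", {
  ds <- generate_faers(synthetic_config(
    n_reports = 1500, seed = 21, p_duplicate_version = 0,
    p_nonps_target = 0.05))
  targets <- c(atorvastatin = "C10AA05", rosuvastatin = "C10AA07")
  ex <- label_exposure(ds$drug, targets, shared_dict)
  for (lab in names(targets)) {
    got <- sort(ex$primary_id[ex[[lab]]])
    expect_equal(got, oracle_exposure(ds$drug, targets[[lab]], shared_dict),
                 label = lab)
  }
})

test_that("a report is a case once regardless of how many target PTs it has", {
  reac <- data.frame(
    primaryid = c(1L, 1L, 1L, 2L, 3L, 3L),
    pt = c("Dyspnoea", "Cough", "Wheezing", "Nausea", "Dyspnoea", "Nausea"),
    pt_cod = c(10013968L, 10011224L, 10047924L, 10028813L, 10013968L,
               10028813L),
    stringsAsFactors = FALSE
  )
  cas <- label_cases(reac, shared_map, 10038738L)
  expect_equal(cas$primary_id, c(1L, 3L))   # report 1 counted once
  expect_equal(attr(cas, "n_unmapped"), 0L)

  # unmapped PTs never make a case, but are tallied
  reac2 <- data.frame(primaryid = 9L, pt = "Mystery syndrome",
                      pt_cod = NA_integer_, stringsAsFactors = FALSE)
  cas2 <- label_cases(reac2, shared_map, 10038738L)
  expect_equal(nrow(cas2), 0)
  expect_equal(attr(cas2, "n_unmapped"), 1L)
})

test_that("PT names resolve when codes are absent", {
  reac <- data.frame(primaryid = 1:2, pt = c("dyspnoea", "NAUSEA"),
                     stringsAsFactors = FALSE)
  cas <- label_cases(reac, shared_map, 10038738L)
  expect_equal(cas$primary_id, 1L)
})

test_that("per-PT counts de-duplicate reaction rows and match nested loops", {
  ds <- generate_faers(synthetic_config(n_reports = 1000, seed = 22,
                                        p_duplicate_version = 0))
  targets <- c(atorvastatin = "C10AA05", rosuvastatin = "C10AA07")
  reports <- deduplicate_reports(safety_reports(ds$demo))
  cohort <- build_cohort(reports, ds$drug, ds$reac, targets, shared_dict,
                         shared_map, 10038738L)
  cnt <- pt_event_counts(ds$reac, cohort, "atorvastatin", shared_map)
  exposed_cases <- cohort$primary_id[cohort$atorvastatin & cohort$case]
  want <- oracle_pt_counts(ds$reac, exposed_cases, shared_map, 10038738L)
  expect_equal(nrow(cnt), length(want))
  for (k in seq_len(nrow(cnt))) {
    expect_equal(cnt$n[k], want[[as.character(cnt$pt_code[k])]],
                 label = cnt$pt_name[k])
  }
  # each PT count bounded by the SOC-level case count
  expect_true(all(cnt$n <= length(exposed_cases)))

  # duplicate REAC rows count once
  reac_dup <- data.frame(primaryid = c(1L, 1L), pt = "Dyspnoea",
                         pt_cod = 10013968L, stringsAsFactors = FALSE)
  coh1 <- data.frame(primary_id = 1L, atorvastatin = TRUE, case = TRUE)
  attr(coh1, "targets") <- targets["atorvastatin"]
  attr(coh1, "target_soc") <- 10038738L
  cnt1 <- pt_event_counts(reac_dup, coh1, "atorvastatin", shared_map)
  expect_equal(cnt1$n, 1L)
})

test_that("cohort labels are independent of child row order", {
  ds <- generate_faers(synthetic_config(n_reports = 400, seed = 23,
                                        p_duplicate_version = 0))
  targets <- c(atorvastatin = "C10AA05", rosuvastatin = "C10AA07")
  reports <- deduplicate_reports(safety_reports(ds$demo))
  c1 <- build_cohort(reports, ds$drug, ds$reac, targets, shared_dict,
                     shared_map, 10038738L)
  set.seed(99)
  drug_sh <- ds$drug[sample(nrow(ds$drug)), , drop = FALSE]
  reac_sh <- ds$reac[sample(nrow(ds$reac)), , drop = FALSE]
  c2 <- build_cohort(reports, drug_sh, reac_sh, targets, shared_dict,
                     shared_map, 10038738L)
  expect_equal(c1$case, c2$case)
  expect_equal(c1$atorvastatin, c2$atorvastatin)
  expect_equal(c1$rosuvastatin, c2$rosuvastatin)
})
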