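test_that("2x2 construction matches hand enumeration and the scan oracle", {
  # universe of 10 reports, 4 exposed, 3 cases, 2 overlapping
  coh <- data.frame(primary_id = 1:10,
                    druga = c(rep(TRUE, 4), rep(FALSE, 6)),
                    case = c(TRUE, TRUE, FALSE, FALSE, TRUE,
                             rep(FALSE, 5)))
  attr(coh, "targets") <- c(druga = "X")
  attr(coh, "target_soc") <- 1L
  tab <- build_contingency(coh, "druga")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(2, 2, 1, 5))

  # empty exposure is a degenerate but valid table
  coh$druga <- FALSE
  tab0 <- build_contingency(coh, "druga")
  expect_equal(c(tab0$a, tab0$b), c(0, 0))

  # synthetic dataset equals the brute-force double-count oracle
  ds <- generate_faers(sim_config(5000, theta = 3, seed = 31))
  tabs <- sim_soc_table(ds, shared_dict, shared_map)
  rep <- deduplicate_reports(safety_reports(ds$demo))
  want <- oracle_contingency(
    rep$primary_id,
    oracle_exposure(ds$drug, "C10AA05", shared_dict),
    oracle_cases(ds$reac, shared_map, 10038738L))
  expect_equal(c(tabs$a, tabs$b, tabs$c, tabs$d), unname(as.numeric(want)))
})

test_that("ROR point estimate and Woolf interval behave as published", {
  bal <- ror(contingency_table(5, 5, 5, 5))
  expect_equal(bal$ror, 1)
  # symmetric about 1 on the log scale
  expect_equal(log(bal$ci_high), -log(bal$ci_low))

  r <- ror(contingency_table(10, 90, 100, 9900))
  expect_equal(r$ror, 11)

  # swap symmetry: ROR(a,b,c,d) = 1/ROR(b,a,d,c); invariant under a<->d, b<->c
  set.seed(41)
  for (k in 1:50) {
    t1 <- as.list(setNames(sample(1:80, 4, replace = TRUE),
                           c("a", "b", "c", "d")))
    r1 <- ror(do.call(contingency_table, t1))$ror
    r2 <- ror(contingency_table(t1$b, t1$a, t1$d, t1$c))$ror
    r3 <- ror(contingency_table(t1$d, t1$c, t1$b, t1$a))$ror
    expect_equal(r1, 1 / r2)
    expect_equal(r1, r3)
  }

  # monotone: one extra co-report strictly increases the ROR
  base <- ror(contingency_table(12, 40, 33, 500))$ror
  expect_gt(ror(contingency_table(13, 40, 33, 500))$ror, base)

  # zero cells: undefined marker, not an exception; Haldane on request
  z <- ror(contingency_table(0, 10, 5, 100))
  expect_true(z$undefined)
  expect_true(is.na(z$ror))
  zh <- ror(contingency_table(0, 10, 5, 100), correction = "haldane")
  expect_false(zh$undefined)
  expect_equal(zh$ror, (0.5 * 100.5) / (10.5 * 5.5))
})

test_that("ROR agrees with an independent log-scale route to 1e-9", {
  set.seed(42)
  for (k in 1:200) {
    a <- sample(1:50, 1); b <- sample(1:500, 1)
    cc <- sample(1:500, 1); d <- sample(1:5000, 1)
    got <- ror(contingency_table(a, b, cc, d))$ror
    want <- exp(log(a) + log(d) - log(b) - log(cc))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("IC is zero at independence and follows the observed/expected form", {
  # a*n == (a+b)(a+c): observed equals expected
  ind <- information_component(contingency_table(1, 9, 99, 891))
  expect_equal(ind$ic, 0)

  i <- information_component(contingency_table(10, 90, 100, 9900))
  expect_equal(i$ic, log2(10 * 10100 / (100 * 110)))

  # interval brackets the point estimate whenever a >= 1
  set.seed(44)
  for (k in 1:100) {
    a <- sample(1:40, 1); b <- sample(0:400, 1)
    cc <- sample(0:400, 1); d <- sample(0:8000, 1)
    est <- information_component(contingency_table(a, b, cc, d))
    expect_lt(est$ic025, est$ic)
    expect_gt(est$ic975, est$ic)
  }

  # a = 0: shrinkage value with a flag, not an error
  z <- information_component(contingency_table(0, 50, 100, 1000))
  expect_true(z$shrunk)
  expect_true(is.finite(z$ic))

  # delta-method variance is selectable and uses the documented closed form
  dd <- information_component(contingency_table(20, 180, 200, 19600),
                              variance = "delta")
  v <- (1 / 20 - 1 / 200 - 1 / 220 + 1 / 20000) / log(2)^2
  expect_equal(dd$ic975 - dd$ic, 2 * sqrt(v))
})

test_that("IC is monotone in a and approaches log2(theta) at scale", {
  # monotone in a with margins adjusted consistently
  ics <- vapply(c(10, 20, 40, 80), function(a) {
    information_component(contingency_table(a, 1000 - a, 500, 50000))$ic
  }, numeric(1))
  expect_true(all(diff(ics) > 0))

  # fixed margins with co-reporting inflated theta-fold: IC = log2(theta)
  theta <- 4
  for (n in c(1e4, 1e6)) {
    ab <- 0.02 * n; ac <- 0.01 * n
    a <- theta * ab * ac / n              # theta x expected count
    tab <- contingency_table(a, ab - a, ac - a, n - ab - ac + a)
    expect_equal(information_component(tab)$ic, log2(theta))
  }
})

test_that("the dual criterion needs both arms and ten cases", {
  # the published SOC-level configuration is a signal
  est <- list(ror = 2.05, ror_ci_low = 2.02, ror_ci_high = 2.08,
              ror_undefined = FALSE, ic = 0.96, ic025 = 0.93, ic975 = 1.0,
              ic_shrunk = FALSE, n_cases = 8211)
  class(est) <- "signal_estimate"
  d <- decide_signal(est)
  expect_true(d$ror_positive && d$ic_positive && d$signal)

  est$n_cases <- 9; est$ror_ci_low <- 1.2
  expect_false(decide_signal(est)$signal)   # count rule

  est$n_cases <- 50; est$ror_ci_low <- 1.5; est$ic025 <- -0.1
  d2 <- decide_signal(est)
  expect_true(d2$ror_positive)
  expect_false(d2$ic_positive)
  expect_false(d2$signal)                   # conjunction

  est$ror_undefined <- TRUE
  d3 <- decide_signal(est)
  expect_false(d3$signal)
  expect_equal(d3$reason, "undefined_estimate")
})

test_that("signal_table sorts by descending ROR and reports test counts", {
  ds <- generate_faers(synthetic_config(n_reports = 3000, seed = 32,
                                        p_duplicate_version = 0))
  targets <- c(atorvastatin = "C10AA05", rosuvastatin = "C10AA07")
  rep <- deduplicate_reports(safety_reports(ds$demo))
  coh <- build_cohort(rep, ds$drug, ds$reac, targets, shared_dict,
                      shared_map, 10038738L)
  st <- signal_table(coh, ds$reac, shared_map)
  expect_true(all(c("drug", "event", "a", "ror", "ic025", "signal")
                  %in% names(st)))
  for (lab in names(targets)) {
    rors <- st$ror[st$drug == lab]
    rors <- rors[!is.na(rors)]
    expect_true(all(diff(rors) <= 0), label = lab)
  }
  expect_equal(attr(st, "n_tests"), nrow(st))
})
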