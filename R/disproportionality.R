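#' Build a 2x2 case/non-case contingency table
#'
#' With report counts: `a` = target drug and target event, `b` = target
#' drug, other events, `c` = other drugs, target event, `d` = neither.
#' The margins therefore satisfy a+b = reports exposed to the drug and
#' a+c = case reports; a+b+c+d is the whole deduplicated report universe
#' (the entire database is the comparator).
#'
#' @param a,b,c,d non-negative integer counts.
#' @return a `contingency_table` object.
#' @export
contingency_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(counts >= 0), all(counts == floor(counts)))
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 d = as.numeric(d), n = as.numeric(a + b + c + d)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<2x2> a=%g b=%g c=%g d=%g (n=%g)\n", x$a, x$b, x$c, x$d, x$n))
  invisible(x)
}

#' Build the 2x2 table for a drug-event pair from cohort labels
#'
#' The event may be the target SOC as a whole (`event = "soc"`) or a single
#' PT (`event = <pt_code>`), in which case the case column is recomputed as
#' "report mentions that PT" against the same full-universe denominator.
#'
#' @param cohort [build_cohort()] result.
#' @param drug label of a target drug.
#' @param event `"soc"` or an integer PT code.
#' @param reac_df REAC table (required for PT-level events).
#' @param map [read_meddra_map()] object (required for PT-level events).
#' @return a [contingency_table()].
#' @export
build_contingency <- function(cohort, drug, event = "soc", reac_df = NULL,
                              map = NULL) {
  stopifnot(drug %in% names(attr(cohort, "targets")))
  exposed <- cohort[[drug]]
  if (identical(event, "soc")) {
    is_case <- cohort$case
  } else {
    stopifnot(!is.null(reac_df))
    dt <- data.table::as.data.table(reac_df)
    if (!"pt_cod" %in% names(dt)) dt[, pt_cod := NA_integer_]
    miss <- is.na(dt$pt_cod)
    if (any(miss) && "pt" %in% names(dt) && !is.null(map)) {
      data.table::set(dt, which(miss), "pt_cod",
                      pt_code_from_name(dt$pt[miss], map))
    }
    ids <- unique(dt$primaryid[!is.na(dt$pt_cod) & dt$pt_cod == event])
    is_case <- cohort$primary_id %in% ids
  }
  a <- sum(exposed & is_case)
  b <- sum(exposed & !is_case)
  cc <- sum(!exposed & is_case)
  d <- sum(!exposed & !is_case)
  contingency_table(a, b, cc, d)
}

#' Reporting odds ratio with 95% confidence interval
#'
#' ROR = ad/(bc); 95% CI = exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))
#' (Woolf interval). With any zero cell the estimate is undefined and all
#' three values are NA with `undefined = TRUE` — no exception, and no
#' continuity correction unless `correction = "haldane"` adds 0.5 to every
#' cell (exploratory output only; the signal rule's a >= 10 floor makes the
#' correction irrelevant for decisions).
#'
#' @param table a [contingency_table()].
#' @param correction "none" (default) or "haldane".
#' @return list with `ror`, `ci_low`, `ci_high`, `undefined`.
#' @examples
#' ror(contingency_table(10, 90, 100, 9900))$ror # 11
#' @export
ror <- function(table, correction = c("none", "haldane")) {
  correction <- match.arg(correction)
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  if (correction == "haldane" && any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  if (any(c(a, b, c, d) == 0)) {
    return(list(ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                undefined = TRUE))
  }
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = est,
       ci_low = exp(log(est) - 1.96 * se),
       ci_high = exp(log(est) + 1.96 * se),
       undefined = FALSE)
}

## Bate-1998 closed-form posterior moments of the information component.
## Hyperparameters: alpha1 = beta1 = 1, alpha = beta = 2, gamma11 = 1 and
## gamma scaled to the margins so that the prior IC expectation is 0.
bcpnn_moments <- function(a, ab, ac, n) {
  a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
  g <- g11 * (n + al) * (n + be) / ((ab + a1) * (ac + b1))
  e_ic <- log2((a + g11) * (n + al) * (n + be) /
                 ((n + g) * (ab + a1) * (ac + b1)))
  v_ic <- ((n - a + g - g11) / ((a + g11) * (1 + n + g)) +
             (n - ab + al - a1) / ((ab + a1) * (1 + n + al)) +
             (n - ac + be - b1) / ((ac + b1) * (1 + n + be))) / log(2)^2
  list(e_ic = e_ic, v_ic = v_ic)
}

#' BCPNN information component with 95% credibility interval
#'
#' Point estimate is the observed/expected form
#' IC = log2( a (a+b+c+d) / ((a+c)(a+b)) ) — log2 of how many times more
#' often the drug and event are co-reported than expected under
#' independence. The interval is IC +/- 2 sqrt(V(IC)), centred on the
#' reported point estimate, with V(IC) taken by default from the standard
#' closed-form BCPNN posterior variance (Beta/Dirichlet hyperparameters at
#' their conventional values); a delta-method variance,
#' (1/ln 2)^2 (1/a - 1/(a+b) - 1/(a+c) + 1/n), is selectable. Centring on
#' the point estimate keeps ic025 <= ic <= ic975 by construction and
#' reproduces the IC/IC025 spacing seen in published screening tables;
#' the posterior-mean centring is conservative only for degenerate tables
#' that the a >= 10 decision floor excludes anyway.
#'
#' When a = 0 the plug-in IC is undefined; the shrinkage estimator's
#' posterior mean is returned as the point value with `shrunk = TRUE`.
#'
#' @param table a [contingency_table()].
#' @param variance "bate1998" (default) or "delta".
#' @return list with `ic`, `ic025`, `ic975`, `shrunk`, `variance`.
#' @examples
#' information_component(contingency_table(1, 9, 99, 891))$ic # 0 (independence)
#' @export
information_component <- function(table, variance = c("bate1998", "delta")) {
  variance <- match.arg(variance)
  a <- table$a; n <- table$n
  ab <- table$a + table$b; ac <- table$a + table$c
  mom <- bcpnn_moments(a, ab, ac, n)
  if (a > 0 && ab > 0 && ac > 0) {
    ic <- log2(a * n / (ab * ac))
    shrunk <- FALSE
  } else {
    ic <- mom$e_ic
    shrunk <- TRUE
  }
  if (variance == "bate1998") {
    v <- mom$v_ic
  } else {
    v <- (1 / a - 1 / ab - 1 / ac + 1 / n) / log(2)^2
    if (!is.finite(v) || v < 0) v <- NA_real_
  }
  list(ic = ic, ic025 = ic - 2 * sqrt(v), ic975 = ic + 2 * sqrt(v),
       shrunk = shrunk, variance = variance)
}

#' Full signal estimate for one 2x2 table
#'
#' @param table a [contingency_table()].
#' @param ic_variance passed to [information_component()].
#' @param correction passed to [ror()].
#' @return a `signal_estimate` list: ror, ror_ci_low, ror_ci_high, ic,
#'   ic025, ic975, n_cases (= a), plus flags.
#' @export
signal_estimate <- function(table, ic_variance = "bate1998",
                            correction = "none") {
  r <- ror(table, correction = correction)
  i <- information_component(table, variance = ic_variance)
  structure(list(ror = r$ror, ror_ci_low = r$ci_low, ror_ci_high = r$ci_high,
                 ror_undefined = r$undefined,
                 ic = i$ic, ic025 = i$ic025, ic975 = i$ic975,
                 ic_shrunk = i$shrunk, n_cases = table$a),
            class = "signal_estimate")
}

#' Apply the dual signal criterion
#'
#' ROR arm: lower 95% CI limit > 1 and at least 10 co-reported cases.
#' IC arm: IC025 > 0. A drug-event pair is a signal only when both arms
#' are positive. Undefined estimates never signal; the reason is recorded.
#' All comparisons use unrounded values.
#'
#' @param est a [signal_estimate()].
#' @return list `ror_positive`, `ic_positive`, `signal`, `reason`.
#' @export
decide_signal <- function(est) {
  if (isTRUE(est$ror_undefined) || is.na(est$ic025)) {
    return(list(ror_positive = FALSE, ic_positive = FALSE, signal = FALSE,
                reason = "undefined_estimate"))
  }
  ror_positive <- (est$ror_ci_low > 1) && (est$n_cases >= 10)
  ic_positive <- est$ic025 > 0
  list(ror_positive = ror_positive, ic_positive = ic_positive,
       signal = ror_positive && ic_positive,
       reason = if (ror_positive && ic_positive) "dual_criterion_met" else "")
}

#' Screen drug-event pairs and tabulate signals
#'
#' One row per (drug, event): the SOC-level event plus, optionally, every
#' PT of the target SOC observed among that drug's cases, all against the
#' full-universe comparator. No multiple-testing correction is applied
#' (matching field practice for hypothesis generation); the number of
#' tests performed is attached as the `n_tests` attribute so users can
#' post-correct.
#'
#' @param cohort [build_cohort()] result.
#' @param reac_df REAC table.
#' @param map [read_meddra_map()] object.
#' @param pt_level also screen each observed target-SOC PT (default TRUE).
#' @param ic_variance passed to [information_component()].
#' @return data.frame, one row per (drug, event), columns drug, event,
#'   pt_code, a, b, c, d, ror, ror_ci_low, ror_ci_high, ic, ic025, ic975,
#'   n_cases, signal; sorted by descending ror within drug.
#' @export
signal_table <- function(cohort, reac_df, map, pt_level = TRUE,
                         ic_variance = "bate1998") {
  targets <- attr(cohort, "targets")
  rows <- list()
  n_tests <- 0L
  for (drug in names(targets)) {
    events <- list(list(label = "soc", pt = NA_integer_))
    if (pt_level) {
      cnts <- pt_event_counts(reac_df, cohort, drug, map)
      for (k in seq_len(nrow(cnts))) {
        events[[length(events) + 1L]] <-
          list(label = cnts$pt_name[k], pt = cnts$pt_code[k])
      }
    }
    for (ev in events) {
      tab <- if (is.na(ev$pt)) build_contingency(cohort, drug, "soc")
             else build_contingency(cohort, drug, ev$pt, reac_df, map)
      est <- signal_estimate(tab, ic_variance = ic_variance)
      dec <- decide_signal(est)
      n_tests <- n_tests + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        drug = drug, event = ev$label, pt_code = ev$pt,
        a = tab$a, b = tab$b, c = tab$c, d = tab$d,
        ror = est$ror, ror_ci_low = est$ror_ci_low,
        ror_ci_high = est$ror_ci_high,
        ic = est$ic, ic025 = est$ic025, ic975 = est$ic975,
        n_cases = est$n_cases, signal = dec$signal,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$drug, -xtfrm(out$ror)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tests") <- n_tests
  attr(out, "ic_variance") <- ic_variance
  out
}
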