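#' 2x2 contingency table of exposure by event
#'
#' Cell layout follows the standard disproportionality cross-tabulation:
#' `a` exposed with the event, `b` exposed without, `c` unexposed with the
#' event, `d` unexposed without.
#'
#' @param a,b,c,d Non-negative integer counts; `a + b + c + d > 0`.
#' @return An object of class `contingency2x2`.
#' @export
#' @examples
#' contingency(6, 1641, 154, 970419)
contingency <- function(a, b, c, d) {
  cells <- c(a = unname(a), b = unname(b), c = unname(c), d = unname(d))
  if (!all(vapply(cells, is_count, logical(1)))) {
    abort("all four cells must be single non-negative integers.")
  }
  if (sum(cells) <= 0) abort("the table must contain at least one unit.")
  structure(as.list(cells), class = "contingency2x2")
}

#' @export
print.contingency2x2 <- function(x, ...) {
  m <- matrix(unlist(x), 2, 2, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"),
                              c("event", "no event")))
  cat("<contingency2x2>\n")
  print(m)
  invisible(x)
}

#' Cross-tabulate records into a contingency table
#'
#' Partitions the analysis units (records, or cases collapsed over their
#' records) by an exposure predicate and an event predicate. At `unit =
#' "case"` a case counts as exposed (or as an event case) when any of its
#' records satisfies the predicate.
#'
#' @param records Analysis records.
#' @param exposure,event Predicate functions of the records table (see
#'   [drug_is()], [event_is()]).
#' @param unit `"record"` (default) or `"case"`.
#' @return A [contingency()] whose cells sum to the number of units.
#' @export
build_contingency <- function(records, exposure, event,
                              unit = c("record", "case")) {
  assert_records(records)
  unit <- match.arg(unit)
  if (nrow(records) == 0) abort("`records` is empty.")
  ex <- eval_predicate(exposure, records, "exposure")
  ev <- eval_predicate(event, records, "event")
  if (unit == "case") {
    flags <- tibble::tibble(case_id = records$case_id, ex = ex, ev = ev) |>
      dplyr::summarise(ex = any(.data$ex), ev = any(.data$ev),
                       .by = "case_id")
    ex <- flags$ex
    ev <- flags$ev
  }
  contingency(
    a = sum(ex & ev), b = sum(ex & !ev),
    c = sum(!ex & ev), d = sum(!ex & !ev)
  )
}

cells_of <- function(t) {
  stopifnot(inherits(t, "contingency2x2"))
  unlist(t, use.names = TRUE)
}

#' Reporting odds ratio
#'
#' `ROR = a*d / (b*c)`: the odds of the target event among exposed reports
#' over the same odds among all other reports. Undefined (`NA`) when `b = 0`
#' or `c = 0`; with the Haldane-Anscombe continuity correction every cell is
#' incremented by 0.5 first, so the ratio is always defined.
#'
#' @param t A [contingency()].
#' @param correction Apply the +0.5 continuity correction (default `FALSE`).
#' @return A non-negative number, or `NA` when undefined.
#' @export
#' @examples
#' compute_ror(contingency(6, 1641, 154, 970419)) # 23.04
compute_ror <- function(t, correction = FALSE) {
  x <- cells_of(t) + if (correction) 0.5 else 0
  if (x["b"] == 0 || x["c"] == 0) return(NA_real_)
  unname(x["a"] * x["d"] / (x["b"] * x["c"]))
}

#' Woolf confidence interval for the reporting odds ratio
#'
#' Log-normal interval: `exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`,
#' `z` the standard-normal quantile for the level. Any zero cell makes the
#' interval undefined unless the continuity correction is enabled.
#'
#' @inheritParams compute_ror
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(ci_low, ci_high)` (possibly `NA`).
#' @export
ror_ci <- function(t, level = 0.95, correction = FALSE) {
  stopifnot(is_prob(level), level > 0, level < 1)
  x <- cells_of(t) + if (correction) 0.5 else 0
  if (any(x == 0)) return(c(ci_low = NA_real_, ci_high = NA_real_))
  lor <- log(x["a"]) + log(x["d"]) - log(x["b"]) - log(x["c"])
  se <- sqrt(sum(1 / x))
  z <- qnorm(1 - (1 - level) / 2)
  unname2 <- function(v) setNames(as.numeric(v), c("ci_low", "ci_high"))
  unname2(exp(lor + c(-1, 1) * z * se))
}

# Vectorized two-sided Fisher exact p over parallel cell vectors.
#
# Minimum-likelihood definition: sum the hypergeometric probabilities of all
# tables with the observed margins whose probability does not exceed the
# observed table's, within relative tolerance 1 + 1e-7 (guards against ties
# lost to floating point). A zero margin leaves a single admissible table, so
# p = 1 falls out of the same rule.
fisher_p_vec <- function(a, b, c, d) {
  n <- length(a)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m1 <- a[i] + b[i]            # exposed margin
    m2 <- c[i] + d[i]            # unexposed margin
    k <- a[i] + c[i]             # event margin
    support <- max(0, k - m2):min(k, m1)
    pr <- dhyper(support, m1, m2, k)
    p[i] <- min(1, sum(pr[pr <= pr[support == a[i]] * (1 + 1e-7)]))
  }
  p
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p by minimum-likelihood summation: the probabilities of all
#' tables sharing the observed margins that are no more likely than the
#' observed table (within relative tolerance `1 + 1e-7`). When a margin is
#' zero the observed table is the only one possible and p = 1.
#'
#' @param t A [contingency()].
#' @return A p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact_two_sided(contingency(2, 3379, 158, 968681)) # 0.108
fisher_exact_two_sided <- function(t) {
  x <- cells_of(t)
  fisher_p_vec(x["a"], x["b"], x["c"], x["d"])
}

#' Disproportionality signal criterion
#'
#' A drug-event pair is a signal when the lower limit of the ROR confidence
#' interval exceeds one (strictly). An undefined lower limit is never a
#' signal.
#'
#' @param ror Reporting odds ratio(s); accepted for interface symmetry, not
#'   used by the criterion.
#' @param ci_low Lower confidence limit(s), `NA` when undefined.
#' @return Logical vector.
#' @export
evaluate_signal <- function(ror, ci_low) {
  !is.na(ci_low) & ci_low > 1
}

#' Volcano-plot coordinates
#'
#' `x = ln(ROR)`, `y = -log10(p)`: effect size against significance.
#'
#' @param ror Positive reporting odds ratio(s).
#' @param p_value p-value(s) in (0, 1].
#' @return Tibble with columns `x`, `y`.
#' @export
volcano_coordinates <- function(ror, p_value) {
  if (any(!is.na(ror) & ror <= 0)) abort("`ror` must be positive.")
  if (any(!is.na(p_value) & (p_value <= 0 | p_value > 1))) {
    abort("`p_value` must lie in (0, 1].")
  }
  tibble::tibble(x = log(ror), y = -log10(p_value))
}

#' Screen every exposure (or event) for disproportionate reporting
#'
#' Generalized volcano screen. One axis varies over the distinct values of a
#' column, the other is fixed by a predicate:
#' * drug screen: `vary = "drug_name"`, `event = event_is("hiccups")` — one
#'   result per drug;
#' * gender screen: `vary = "event_term"`, `exposure = function(r) r$sex ==
#'   "male"` — one result per adverse-event term;
#' * route screen: `vary = "event_term"`, `exposure = function(r) r$route ==
#'   "intravenous"`.
#'
#' Each value yields a 2x2 against the rest of the table, the ROR with its
#' Woolf interval, the two-sided Fisher exact p, volcano coordinates and the
#' signal flag. Results are sorted by `(p_value, -ror, exposure)` so output is
#' deterministic under ties.
#'
#' @param records Analysis records.
#' @param vary Column name supplying the varying axis (`"drug_name"` or
#'   `"event_term"`; any record column works). Rows with a missing value in
#'   this column contribute to the unexposed/non-event margins only.
#' @param exposure,event Exactly one of these is a fixed predicate function;
#'   the other side is taken over by `vary`.
#' @param unit `"record"` (default) or `"case"`.
#' @param level Confidence level for the Woolf interval.
#' @param correction Continuity correction flag, passed to the ROR and CI.
#' @param adjust Add a Benjamini-Hochberg `p_adjusted` column (an extension:
#'   raw p-values stay the primary output).
#' @return Tibble with columns `exposure`, `a`, `b`, `c`, `d`,
#'   `n_event_reports`, `ror`, `ci_low`, `ci_high`, `p_value`, `ln_ror`,
#'   `neg_log10_p`, `is_signal` (and `p_adjusted` if requested).
#' @export
screen_exposures <- function(records, vary, exposure = NULL, event = NULL,
                             unit = c("record", "case"), level = 0.95,
                             correction = FALSE, adjust = FALSE) {
  assert_records(records)
  unit <- match.arg(unit)
  if (!vary %in% names(records)) {
    abort(sprintf("`vary` column `%s` not found in records.", vary))
  }
  if (is.null(exposure) == is.null(event)) {
    abort("supply exactly one fixed predicate (`exposure` or `event`); the other axis varies over `vary`.")
  }
  vary_is_exposure <- is.null(exposure)
  fixed <- eval_predicate(if (vary_is_exposure) event else exposure,
                          records, if (vary_is_exposure) "event" else "exposure")
  labels <- records[[vary]]

  if (unit == "case") {
    # a case's varying-axis membership: any record with that value; fixed
    # side: any record satisfying the predicate
    per_case <- tibble::tibble(case_id = records$case_id, fixed = fixed) |>
      dplyr::summarise(fixed = any(.data$fixed), .by = "case_id")
    membership <- tibble::tibble(case_id = records$case_id, label = labels) |>
      dplyr::filter(!is.na(.data$label)) |>
      dplyr::distinct()
    n_units <- nrow(per_case)
    n_fixed <- sum(per_case$fixed)
    counts <- membership |>
      dplyr::left_join(per_case, by = "case_id") |>
      dplyr::summarise(k = dplyr::n(), hits = sum(.data$fixed),
                       .by = "label")
  } else {
    n_units <- nrow(records)
    n_fixed <- sum(fixed)
    keep <- !is.na(labels)
    counts <- tibble::tibble(label = labels[keep], fixed = fixed[keep]) |>
      dplyr::summarise(k = dplyr::n(), hits = sum(.data$fixed),
                       .by = "label")
  }
  if (nrow(counts) == 0) return(empty_screen_result(adjust))

  # Orientation: `a` is always (exposure present, event present).
  a <- counts$hits
  if (vary_is_exposure) {
    b <- counts$k - a          # exposed, no event
    c <- n_fixed - a           # unexposed, event
  } else {
    b <- n_fixed - a           # exposed, other events
    c <- counts$k - a          # unexposed, this event
  }
  d <- n_units - a - b - c

  adj <- if (correction) 0.5 else 0
  aa <- a + adj; bb <- b + adj; cc <- c + adj; dd <- d + adj
  ror <- ifelse(bb == 0 | cc == 0, NA_real_, aa * dd / (bb * cc))
  ok <- aa > 0 & bb > 0 & cc > 0 & dd > 0
  se <- ifelse(ok, sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd), NA_real_)
  z <- qnorm(1 - (1 - level) / 2)
  ci_low <- ifelse(ok, exp(log(ror) - z * se), NA_real_)
  ci_high <- ifelse(ok, exp(log(ror) + z * se), NA_real_)
  p <- fisher_p_vec(a, b, c, d)

  out <- tibble::tibble(
    exposure = counts$label,
    a = as.integer(a), b = as.integer(b), c = as.integer(c), d = as.integer(d),
    n_event_reports = as.integer(a),
    ror = ror, ci_low = ci_low, ci_high = ci_high, p_value = p,
    ln_ror = log(ror), neg_log10_p = -log10(p),
    is_signal = evaluate_signal(ror, ci_low)
  )
  if (adjust) out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  dplyr::arrange(out, .data$p_value, dplyr::desc(.data$ror), .data$exposure)
}

empty_screen_result <- function(adjust = FALSE) {
  out <- tibble::tibble(
    exposure = character(), a = integer(), b = integer(), c = integer(),
    d = integer(), n_event_reports = integer(), ror = numeric(),
    ci_low = numeric(), ci_high = numeric(), p_value = numeric(),
    ln_ror = numeric(), neg_log10_p = numeric(), is_signal = logical()
  )
  if (adjust) out$p_adjusted <- numeric()
  out
}

#' Keep exposures reported with the event more than `min_count` times
#'
#' Strict filter on the number of event reports per exposure (`a` cell), used
#' before predictor selection so the regression is not driven by one-off
#' reports.
#'
#' @param results Screen results from [screen_exposures()].
#' @param min_count Threshold; results with `n_event_reports > min_count` are
#'   kept (default 3).
#' @return Filtered results.
#' @export
filter_min_reports <- function(results, min_count = 3) {
  stopifnot(is_count(min_count))
  dplyr::filter(results, .data$n_event_reports > min_count)
}
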