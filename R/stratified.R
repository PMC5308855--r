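#' Event risk by administration route of one drug
#'
#' For each administration route of the drug, forms the 2x2 of (drug given by
#' that route) vs (every other record in the table) against (event vs
#' non-event) and tests it with the two-sided Fisher exact test. The
#' comparison population is the remainder of the whole table, not the drug's
#' other routes. Records of the drug with a missing route are grouped as
#' `"unknown"` so the per-route counts always sum to the drug's totals.
#'
#' @param records Analysis records (typically the suspected-medicine table).
#' @param drug Canonical drug name.
#' @param event Event predicate.
#' @return Tibble: `route`, `n_event`, `n_nonevent`, `p_value`, `ror`,
#'   `ci_low`, `ci_high`; attribute `"totals"` holds the drug's overall
#'   event/non-event counts.
#' @export
route_screen <- function(records, drug, event) {
  assert_records(records)
  ev <- eval_predicate(event, records, "event")
  on_drug <- records$drug_name == drug
  if (!any(on_drug)) abort(sprintf("no records for drug \"%s\".", drug))
  if (all(on_drug)) {
    abort("the drug covers every record: no comparison population remains.")
  }
  route <- ifelse(is.na(records$route), "unknown", records$route)
  routes <- intersect(c(ROUTE_LEVELS, "unknown"), unique(route[on_drug]))

  n <- nrow(records)
  n_event <- sum(ev)
  rows <- lapply(routes, function(r) {
    in_stratum <- on_drug & route == r
    a <- sum(in_stratum & ev)
    b <- sum(in_stratum & !ev)
    t <- contingency(a, b, n_event - a, n - a - b - (n_event - a))
    ci <- ror_ci(t)
    tibble::tibble(
      route = r, n_event = a, n_nonevent = b,
      p_value = fisher_exact_two_sided(t),
      ror = compute_ror(t), ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]]
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "totals") <- c(n_event = sum(on_drug & ev),
                           n_nonevent = sum(on_drug & !ev))
  out
}

#' Cross-tabulate co-treatment among event cases
#'
#' Among unique event cases (each case counted once by `case_id`), classifies
#' every case by whether any of its records — any involvement category, so
#' this expects the all-data table, not the suspected-only subset — names the
#' index drug, and whether any names a drug of the co-treatment class (e.g.
#' anti-cancer agents).
#'
#' @param all_records Analysis records from the all-data table.
#' @param event Event predicate.
#' @param drug_a Index drug name.
#' @param drug_class_b Character vector of co-treatment class drug names.
#' @return Object of class `cotreatment_table`: counts `n_both`,
#'   `n_drug_a_only`, `n_class_b_only`, `n_neither` and `n_cases` (their sum).
#' @export
cotreatment_cross_tab <- function(all_records, event, drug_a, drug_class_b) {
  assert_records(all_records)
  ev <- eval_predicate(event, all_records, "event")
  event_cases <- unique(all_records$case_id[ev])
  if (!length(event_cases)) abort("no event cases in the record table.")
  sub <- all_records[all_records$case_id %in% event_cases, ]
  flags <- sub |>
    dplyr::summarise(
      on_a = any(.data$drug_name == drug_a),
      on_b = any(.data$drug_name %in% drug_class_b),
      .by = "case_id"
    )
  structure(
    list(
      n_both = sum(flags$on_a & flags$on_b),
      n_drug_a_only = sum(flags$on_a & !flags$on_b),
      n_class_b_only = sum(!flags$on_a & flags$on_b),
      n_neither = sum(!flags$on_a & !flags$on_b),
      n_cases = nrow(flags),
      drug_a = drug_a
    ),
    class = "cotreatment_table"
  )
}

#' @export
print.cotreatment_table <- function(x, ...) {
  m <- matrix(c(x$n_both, x$n_class_b_only, x$n_drug_a_only, x$n_neither),
              2, 2, byrow = TRUE,
              dimnames = list(c("co-treatment class", "no co-treatment"),
                              c(x$drug_a, paste("no", x$drug_a))))
  cat(sprintf("<cotreatment_table> %d unique event cases\n", x$n_cases))
  print(m)
  invisible(x)
}

#' Co-treatment summary percentages
#'
#' Integer percentages summarizing a co-treatment cross-tabulation: the share
#' of index-drug users also on the co-treatment class, the share of all event
#' cases not on the index drug, the co-treatment share among those non-users,
#' and the index-drug share among all event cases. A zero denominator yields
#' 0.
#'
#' @param tab A [cotreatment_cross_tab()] result.
#' @return Named numeric vector of four integer percentages.
#' @export
cotreatment_percentages <- function(tab) {
  stopifnot(inherits(tab, "cotreatment_table"))
  pct <- function(num, den) if (den == 0) 0 else round(100 * num / den)
  n_a <- tab$n_both + tab$n_drug_a_only
  n_non_a <- tab$n_class_b_only + tab$n_neither
  c(
    pct_drug_a_cotreated = pct(tab$n_both, n_a),
    pct_cases_not_on_drug_a = pct(n_non_a, tab$n_cases),
    pct_class_b_among_nonusers = pct(tab$n_class_b_only, n_non_a),
    pct_drug_a_among_cases = pct(n_a, tab$n_cases)
  )
}
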