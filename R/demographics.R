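#' Decode a coded demographic range to a number
#'
#' Reporting databases code age in decades ("50s") and height/weight in
#' 10-unit ranges ("160-169"). For analysis as continuous variables the code
#' is decoded to its leading integer (the range's lower bound) by default;
#' `method = "midpoint"` uses the range midpoint instead ("160-169" -> 164.5,
#' decade "50s" -> 54.5). Codes without a leading integer decode to missing;
#' their count is reported via a message.
#'
#' @param code Character vector of codes (may contain `NA`).
#' @param method `"lower"` (default) or `"midpoint"`.
#' @return Numeric vector, `NA` where the code is missing or unparseable.
#' @export
#' @examples
#' numeric_from_code(c("50s", "160-169", NA, "unknown"))
numeric_from_code <- function(code, method = c("lower", "midpoint")) {
  method <- match.arg(method)
  code <- as.character(code)
  m <- regmatches(code, regexpr("^[0-9]+", code))
  lower <- rep(NA_real_, length(code))
  has <- grepl("^[0-9]+", code)
  lower[has] <- as.numeric(m)
  n_bad <- sum(!is.na(code) & !has)
  if (n_bad > 0) {
    inform(sprintf("numeric_from_code: %d unparseable code(s) set to missing.",
                   n_bad))
  }
  if (method == "lower") return(lower)
  upper <- lower
  rng <- regmatches(code, regexpr("^[0-9]+\\s*-\\s*[0-9]+", code))
  is_rng <- grepl("^[0-9]+\\s*-\\s*[0-9]+", code)
  upper[is_rng] <- as.numeric(sub("^[0-9]+\\s*-\\s*", "", rng))
  dec <- grepl("^[0-9]+\\s*s$", code) & !is_rng
  upper[dec] <- lower[dec] + 9
  (lower + upper) / 2
}

#' Compare a binary characteristic between event and non-event groups
#'
#' Fisher exact test on the 2x2 of group by category (e.g. sex male/female in
#' hiccup vs non-hiccup cases). A zero margin gives p = 1.
#'
#' @param event_counts,nonevent_counts Length-2 numeric vectors of category
#'   counts (same category order in both), e.g. `c(male = 150, female = 6)`.
#' @param variable Label for the output row (default `"sex"`).
#' @return One-row tibble: `variable`, `n_event`, `n_nonevent`, `p_value`,
#'   `test`.
#' @export
compare_categorical <- function(event_counts, nonevent_counts,
                                variable = "sex") {
  if (length(event_counts) != 2 || length(nonevent_counts) != 2) {
    abort("both count vectors must have exactly two categories.")
  }
  t <- contingency(event_counts[1], event_counts[2],
                   nonevent_counts[1], nonevent_counts[2])
  tibble::tibble(
    variable = variable,
    n_event = as.integer(sum(event_counts)),
    n_nonevent = as.integer(sum(nonevent_counts)),
    mean_event = NA_real_, sd_event = NA_real_,
    mean_nonevent = NA_real_, sd_nonevent = NA_real_,
    p_value = fisher_exact_two_sided(t),
    test = "fisher"
  )
}

#' Compare a continuous characteristic between event and non-event groups
#'
#' Two-sided t-test on non-missing values; Welch (unequal variances) by
#' default, pooled-variance on request. Group means, SDs and the n actually
#' used are reported.
#'
#' @param values_event,values_nonevent Numeric vectors (`NA` dropped).
#' @param variant `"welch"` (default) or `"pooled"`.
#' @param variable Label for the output row.
#' @return One-row tibble: `variable`, group `n`/mean/sd, `p_value`, `test`.
#' @export
compare_continuous <- function(values_event, values_nonevent,
                               variant = c("welch", "pooled"),
                               variable = "value") {
  variant <- match.arg(variant)
  x <- values_event[!is.na(values_event)]
  y <- values_nonevent[!is.na(values_nonevent)]
  if (length(x) < 2 || length(y) < 2) {
    abort("each group needs at least two non-missing values.")
  }
  p <- if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
    1  # degenerate: identical constant groups, t = 0/0
  } else {
    t.test(x, y, var.equal = (variant == "pooled"))$p.value
  }
  tibble::tibble(
    variable = variable,
    n_event = length(x), n_nonevent = length(y),
    mean_event = mean(x), sd_event = stats::sd(x),
    mean_nonevent = mean(y), sd_nonevent = stats::sd(y),
    p_value = p,
    test = "t_test"
  )
}

#' Patient-background comparison table
#'
#' Compares sex (Fisher exact test) and decoded age, height and weight
#' (t-tests) between event and non-event cases, using only non-missing values
#' per variable and reporting the n actually used. Cases are the analysis
#' unit: demographics are constant within a case and a case is an event case
#' when any of its records reports the event.
#'
#' @param records Analysis records.
#' @param event Event predicate, e.g. `event_is("hiccups")`.
#' @param variant t-test variant, see [compare_continuous()].
#' @param code_method Range-code decoding, see [numeric_from_code()].
#' @return Tibble with one row per variable.
#' @export
patient_background <- function(records, event, variant = c("welch", "pooled"),
                               code_method = c("lower", "midpoint")) {
  assert_records(records)
  variant <- match.arg(variant)
  code_method <- match.arg(code_method)
  ev <- eval_predicate(event, records, "event")
  cases <- tibble::tibble(
    case_id = records$case_id, sex = records$sex,
    age_code = records$age_code, height_code = records$height_code,
    weight_code = records$weight_code, ev = ev
  ) |>
    dplyr::summarise(
      sex = dplyr::first(.data$sex), age_code = dplyr::first(.data$age_code),
      height_code = dplyr::first(.data$height_code),
      weight_code = dplyr::first(.data$weight_code),
      ev = any(.data$ev), .by = "case_id"
    )
  sex_counts <- function(x) c(sum(x == "male", na.rm = TRUE),
                              sum(x == "female", na.rm = TRUE))
  rows <- list(
    compare_categorical(sex_counts(cases$sex[cases$ev]),
                        sex_counts(cases$sex[!cases$ev]), variable = "sex")
  )
  for (v in c("age", "height", "weight")) {
    vals <- numeric_from_code(cases[[paste0(v, "_code")]], method = code_method)
    rows[[v]] <- compare_continuous(vals[cases$ev], vals[!cases$ev],
                                    variant = variant, variable = v)
  }
  dplyr::bind_rows(rows)
}

#' Reporting-year trend in the event fraction
#'
#' Computes the per-year fraction of records reporting the event (or the raw
#' count) and the Spearman rank correlation between year and that statistic,
#' with average ranks for ties and a two-sided p from the t approximation
#' (`method = "exact"` uses the exact permutation distribution, available for
#' small year counts without ties).
#'
#' @param records Analysis records with `report_year`.
#' @param event Event predicate.
#' @param statistic `"fraction"` (default) or `"count"`.
#' @param method `"approx"` (default, t approximation) or `"exact"`.
#' @return List of class `trend_result`: `years`, `per_year` (fraction or
#'   count), `rho`, `p_value`.
#' @export
yearly_trend <- function(records, event, statistic = c("fraction", "count"),
                         method = c("approx", "exact")) {
  assert_records(records)
  statistic <- match.arg(statistic)
  method <- match.arg(method)
  ev <- eval_predicate(event, records, "event")
  keep <- !is.na(records$report_year)
  yr <- records$report_year[keep]
  ev <- ev[keep]
  years <- sort(unique(yr))
  if (length(years) < 2) abort("need report years on at least 2 distinct years.")
  per_year <- vapply(years, function(y) {
    n <- sum(yr == y)
    k <- sum(ev & yr == y)
    if (statistic == "fraction") k / n else as.numeric(k)
  }, numeric(1))
  if (stats::sd(per_year) == 0) {
    rho <- 0        # all tied: no monotone association by convention
    p <- 1
  } else {
    ct <- suppressWarnings(
      cor.test(as.numeric(years), per_year, method = "spearman",
               exact = (method == "exact"))
    )
    rho <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(
    list(years = years, per_year = per_year, rho = rho, p_value = p,
         statistic = statistic),
    class = "trend_result"
  )
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result> %d years, Spearman rho = %.4f, p = %.4f\n",
              length(x$years), x$rho, x$p_value))
  invisible(x)
}
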