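test_that("contingency tables validate their cells", {
  expect_s3_class(contingency(0, 1, 2, 3), "contingency2x2")
  expect_error(contingency(-1, 1, 1, 1))
  expect_error(contingency(1.5, 1, 1, 1))
  expect_error(contingency(0, 0, 0, 0))
})

test_that("build_contingency partitions records and cases", {
  records <- tibble::tibble(
    case_id = c("c1", "c2", "c3", "c4"),
    sex = NA_character_, age_code = NA_character_, height_code = NA_character_,
    weight_code = NA_character_, report_year = NA_integer_,
    drug_name = c("drug_x", "drug_x", "drug_y", "drug_y"),
    involvement = "suspected", route = NA_character_,
    event_term = c("hiccups", "other", "hiccups", "other")
  )
  t <- build_contingency(records, drug_is("drug_x"), event_is("hiccups"))
  expect_identical(unlist(t), c(a = 1L, b = 1L, c = 1L, d = 1L))

  # exposure never true -> a = b = 0
  t0 <- build_contingency(records, drug_is("absent"), event_is("hiccups"))
  expect_identical(unlist(t0)[c("a", "b")], c(a = 0L, b = 0L))

  # case unit: a case is exposed/event if any record is
  rec2 <- dplyr::bind_rows(
    records,
    dplyr::mutate(records[1, ], drug_name = "drug_y", event_term = "other")
  )
  tc <- build_contingency(rec2, drug_is("drug_x"), event_is("hiccups"),
                          unit = "case")
  expect_identical(unlist(tc), c(a = 1L, b = 1L, c = 1L, d = 1L))
  expect_error(build_contingency(records[0, ], drug_is("x"), event_is("y")))
})

test_that("contingency cells sum to unit count on random fixtures", {
  set.seed(13)
  for (i in 1:5) {
    db <- deduplicate_reports(random_db())
    records <- suppressWarnings(build_all_data_table(db))
    t <- build_contingency(records, drug_is("drug01"), event_is("hiccups"))
    expect_identical(sum(unlist(t)), nrow(records))
    tc <- build_contingency(records, drug_is("drug01"), event_is("hiccups"),
                            unit = "case")
    expect_identical(sum(unlist(tc)), length(unique(records$case_id)))
  }
})

test_that("ROR arithmetic, undefined cases and continuity correction", {
  expect_equal(compute_ror(contingency(5, 5, 5, 5)), 1)
  expect_equal(compute_ror(contingency(6, 1641, 154, 970419)), 23.04,
               tolerance = 1e-3)
  expect_equal(compute_ror(contingency(0, 10, 10, 10)), 0)
  expect_true(is.na(compute_ror(contingency(1, 0, 1, 1))))
  expect_true(is.na(compute_ror(contingency(1, 1, 0, 1))))
  expect_equal(compute_ror(contingency(1, 0, 1, 1), correction = TRUE),
               1.5 * 1.5 / (0.5 * 1.5))
  # symmetry: swapping b and c leaves the ROR unchanged
  set.seed(5)
  for (i in 1:20) {
    x <- sample(1:50, 4, replace = TRUE)
    expect_equal(compute_ror(contingency(x[1], x[2], x[3], x[4])),
                 compute_ror(contingency(x[1], x[3], x[2], x[4])))
  }
})

test_that("Woolf interval matches the closed form and widens with the level", {
  ci <- ror_ci(contingency(5, 5, 5, 5))
  expect_equal(unname(ci), c(0.173, 5.772), tolerance = 1e-3)
  # log-symmetry: a = d, b = c  =>  ci_low * ci_high = ROR^2
  t <- contingency(8, 3, 3, 8)
  ci2 <- ror_ci(t)
  expect_equal(ci2[["ci_low"]] * ci2[["ci_high"]], compute_ror(t)^2)
  # nesting in the level
  lo <- ror_ci(contingency(12, 5, 7, 30), level = 0.95)
  hi <- ror_ci(contingency(12, 5, 7, 30), level = 0.99)
  expect_true(hi[["ci_low"]] < lo[["ci_low"]] && hi[["ci_high"]] > lo[["ci_high"]])
  # zero cell undefined without correction
  expect_true(all(is.na(ror_ci(contingency(0, 5, 5, 5)))))
  expect_false(anyNA(ror_ci(contingency(0, 5, 5, 5), correction = TRUE)))
})

test_that("two-sided Fisher p reproduces printed route tests", {
  expect_equal(round(fisher_exact_two_sided(contingency(2, 3379, 158, 968681)), 3),
               0.108)
  expect_lt(fisher_exact_two_sided(contingency(6, 1641, 154, 970419)), 1e-4)
  expect_equal(fisher_exact_two_sided(contingency(0, 950, 160, 971110)), 1)
})

test_that("Fisher p agrees with enumeration oracle and stats::fisher.test", {
  expect_equal(fisher_exact_two_sided(contingency(2, 3, 4, 5)),
               oracle_fisher_p(2, 3, 4, 5), tolerance = 1e-12)
  set.seed(99)
  for (i in 1:40) {
    x <- as.integer(sample(0:25, 4, replace = TRUE))
    if (sum(x) == 0) x[1] <- 1L
    p_pkg <- fisher_exact_two_sided(contingency(x[1], x[2], x[3], x[4]))
    expect_equal(p_pkg, oracle_fisher_p(x[1], x[2], x[3], x[4]),
                 tolerance = 1e-10)
    expect_equal(
      p_pkg,
      fisher.test(matrix(x, 2, byrow = TRUE))$p.value,
      tolerance = 1e-7
    )
  }
  # zero margin: the observed table is the only admissible one
  expect_equal(fisher_exact_two_sided(contingency(0, 0, 3, 7)), 1)
  expect_equal(fisher_exact_two_sided(contingency(0, 3, 0, 7)), 1)
})

test_that("signal criterion is strict in the lower limit", {
  expect_true(evaluate_signal(22.6, 9.97))
  expect_false(evaluate_signal(2, 1))
  expect_false(evaluate_signal(2, NA))
  expect_identical(evaluate_signal(c(2, 2, 2), c(1.01, 1, NA)),
                   c(TRUE, FALSE, FALSE))
})

test_that("volcano coordinates are the log transforms", {
  expect_equal(unlist(volcano_coordinates(1, 1)), c(x = 0, y = 0))
  expect_equal(unlist(volcano_coordinates(exp(1), 0.1)), c(x = 1, y = 1))
  xy <- volcano_coordinates(22.6, 1e-4)
  expect_equal(xy$x, 3.118, tolerance = 1e-3)
  expect_equal(xy$y, 4)
  expect_error(volcano_coordinates(-1, 0.5))
  expect_error(volcano_coordinates(2, 0))
})

test_that("drug screen ranks a planted signal first and is deterministic", {
  spec <- synthetic_spec(
    n_cases = 8000,
    drugs = c(list(drug_spec("planted_drug", 0.05, 5,
                             involvement_distribution = c(suspected = 1,
                                                          concomitant = 0,
                                                          interaction = 0))),
              lapply(1:9, function(i) {
                drug_spec(sprintf("null_drug_%d", i), 0.05, 1)
              })),
    background_event_rate = 0.02,
    duplicate_fraction = 0,
    seed = 42
  )
  sim <- generate_database(spec)
  records <- filter_suspected(build_all_data_table(sim$db))
  res <- screen_exposures(records, vary = "drug_name", event = event_is("hiccups"))
  expect_identical(res$exposure[1], "planted_drug")
  expect_true(res$is_signal[1])
  # identical input order gives identical output
  res2 <- screen_exposures(records, vary = "drug_name",
                           event = event_is("hiccups"))
  expect_identical(res, res2)
  # every screened 2x2 partitions the record count
  expect_true(all(res$a + res$b + res$c + res$d == nrow(records)))
})

test_that("screen handles a degenerate single-exposure axis", {
  records <- tibble::tibble(
    case_id = c("c1", "c2"), sex = NA_character_, age_code = NA_character_,
    height_code = NA_character_, weight_code = NA_character_,
    report_year = NA_integer_, drug_name = "only_drug",
    involvement = "suspected", route = NA_character_,
    event_term = c("hiccups", "other")
  )
  res <- screen_exposures(records, vary = "drug_name",
                          event = event_is("hiccups"))
  expect_identical(res$c, 0L)
  expect_true(is.na(res$ror))
  expect_false(res$is_signal)
  # empty axis -> empty result
  res0 <- screen_exposures(records[0, ], vary = "drug_name",
                           event = event_is("hiccups"))
  expect_identical(nrow(res0), 0L)
})

test_that("screens agree with direct per-exposure contingency computation", {
  set.seed(23)
  db <- deduplicate_reports(random_db(n_cases = 60))
  records <- suppressWarnings(build_all_data_table(db))
  res <- screen_exposures(records, vary = "drug_name",
                          event = event_is("hiccups"))
  for (i in seq_len(nrow(res))) {
    t <- build_contingency(records, drug_is(res$exposure[i]),
                           event_is("hiccups"))
    expect_identical(unlist(t),
                     c(a = res$a[i], b = res$b[i], c = res$c[i], d = res$d[i]))
    expect_equal(res$p_value[i], fisher_exact_two_sided(t))
  }
  # event-axis orientation: fixed male exposure over each event term
  res_ev <- screen_exposures(records, vary = "event_term",
                             exposure = function(r) r$sex %in% "male")
  for (i in seq_len(nrow(res_ev))) {
    t <- build_contingency(records, function(r) r$sex %in% "male",
                           event_is(res_ev$exposure[i]))
    expect_identical(unlist(t),
                     c(a = res_ev$a[i], b = res_ev$b[i], c = res_ev$c[i],
                       d = res_ev$d[i]))
  }
})

test_that("report-count filter is strict and Table 2's drugs all pass", {
  res <- tibble::tibble(
    exposure = c("A", "B", "C"), n_event_reports = c(4L, 3L, 12L),
    p_value = c(0.01, 0.01, 0.01)
  )
  expect_identical(filter_min_reports(res, 3)$exposure, c("A", "C"))
  tab2_counts <- c(6, 8, 12, 8, 5, 4, 5)
  expect_true(all(tab2_counts > 3))
  # min_count 0 keeps every exposure with at least one report
  expect_identical(nrow(filter_min_reports(res, 0)), 3L)
})

test_that("volcano plot draws the baseline and drops undefined RORs", {
  res <- tibble::tibble(
    exposure = c("A", "B"), a = c(5L, 0L), b = c(5L, 5L), c = c(5L, 5L),
    d = c(5L, 5L), n_event_reports = c(5L, 0L), ror = c(1, NA),
    ci_low = c(0.17, NA), ci_high = c(5.8, NA), p_value = c(1, 1),
    ln_ror = c(0, NA), neg_log10_p = c(0, 0), is_signal = c(FALSE, FALSE)
  )
  p <- volcano_plot(res)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_identical(nrow(built$data[[2]]), 1L)           # undefined ROR dropped
  expect_equal(built$data[[1]]$yintercept, -log10(0.05))
})
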