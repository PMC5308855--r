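test_that("spec validation rejects out-of-range parameters before generation", {
  good_drug <- drug_spec("drug_x", 0.05, 2)
  expect_s3_class(good_drug, "drug_spec")
  expect_error(drug_spec("x", 1.2, 1), class = "rorscreen_spec_error")
  expect_error(drug_spec("x", 0.1, -1), class = "rorscreen_spec_error")
  expect_error(drug_spec("x", 0.1, 1, route_distribution = c(intravenous = 1)),
               class = "rorscreen_spec_error")
  expect_error(synthetic_spec(0, list(good_drug), 0.01),
               class = "rorscreen_spec_error")
  expect_error(synthetic_spec(1000, list(), 0.01),
               class = "rorscreen_spec_error")
  # expected event count below one
  expect_error(synthetic_spec(10, list(good_drug), 0.01),
               class = "rorscreen_spec_error")
  expect_error(synthetic_spec(1000, list(good_drug), 0.01,
                              duplicate_fraction = 1),
               class = "rorscreen_spec_error")
  expect_error(synthetic_spec(1000, list(drug_spec("medicine_01", 0.1, 1)),
                              0.01),
               class = "rorscreen_spec_error")
})

base_spec <- function(n = 5000, dup = 0.1, seed = 5, ...) {
  synthetic_spec(
    n_cases = n,
    drugs = list(drug_spec("drug_a", 0.08, 3), drug_spec("drug_b", 0.05, 1)),
    background_event_rate = 0.02,
    duplicate_fraction = dup,
    seed = seed,
    ...
  )
}

test_that("identical spec and seed give identical databases", {
  s1 <- generate_database(base_spec())
  s2 <- generate_database(base_spec())
  expect_identical(s1$db$demo, s2$db$demo)
  expect_identical(s1$db$drug, s2$db$drug)
  expect_identical(s1$db$reac, s2$db$reac)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_database(base_spec(), seed = 6)
  expect_false(identical(s1$db$drug, s3$db$drug))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(3)
  set.seed(123)
  invisible(runif(0))
  invisible(generate_database(base_spec()))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("realized marginals stay within 3 binomial SDs of the spec", {
  spec <- base_spec(n = 20000)
  sim <- generate_database(spec)
  n <- spec$n_cases
  within3 <- function(obs, p) abs(obs - n * p) <= 3 * sqrt(n * p * (1 - p))
  for (i in seq_along(spec$drugs)) {
    expect_true(within3(sim$truth$drugs$n_exposed[i],
                        spec$drugs[[i]]$prevalence))
  }
  n_male <- sum(sim$db$demo$sex == "male", na.rm = TRUE)
  n_sex_obs <- sum(!is.na(sim$db$demo$sex))
  expect_true(abs(n_male - n_sex_obs * 0.5) <= 3 * sqrt(n_sex_obs * 0.25))
  # missingness fractions are honoured
  expect_true(within3(sum(is.na(sim$db$demo$height_code)), 0.5))
})

test_that("planted contingencies match what the pipeline counts", {
  spec <- base_spec(n = 5000, dup = 0.1)
  sim <- generate_database(spec)
  records <- build_all_data_table(deduplicate_reports(sim$db))
  # all-involvement case-level table equals the recorded ground truth
  for (i in seq_len(nrow(sim$truth$drugs))) {
    t <- build_contingency(records, drug_is(sim$truth$drugs$drug[i]),
                           event_is("hiccups"), unit = "case")
    expect_identical(
      unlist(t),
      c(a = sim$truth$drugs$a[i], b = sim$truth$drugs$b[i],
        c = sim$truth$drugs$c[i], d = sim$truth$drugs$d[i])
    )
  }
})

test_that("injected duplicates are exactly what deduplication removes", {
  spec <- base_spec(n = 5000, dup = 0.1)
  sim <- generate_database(spec)
  n_drug <- nrow(sim$db$drug)
  dedup <- deduplicate_reports(sim$db)
  removed <- attr(dedup, "dedup_removed")
  # 10% of the base rows were re-emitted: removed / retained = 1/10
  expect_identical(unname(removed["drug"]), n_drug - nrow(dedup$drug))
  # exactly floor(fraction * base rows) copies were re-emitted
  expect_identical(removed[["drug"]], as.integer(floor(0.1 * nrow(dedup$drug))))
  expect_identical(removed[["reac"]], as.integer(floor(0.1 * nrow(dedup$reac))))
  expect_equal(removed[["drug"]] / nrow(dedup$drug), 0.1, tolerance = 5e-3)
  # dedup restores the pre-injection tables exactly
  expect_identical(nrow(dplyr::distinct(sim$db$drug)), nrow(dedup$drug))
})

test_that("null drug screens contain ROR = 1 at close to nominal rate", {
  covered <- 0L
  n_seed <- 150
  for (s in seq_len(n_seed)) {
    spec <- synthetic_spec(
      n_cases = 10000,
      drugs = list(drug_spec("null_drug", 0.05, 1,
                             involvement_distribution = c(suspected = 1,
                                                          concomitant = 0,
                                                          interaction = 0))),
      background_event_rate = 0.02,
      duplicate_fraction = 0,
      seed = 20000 + s
    )
    sim <- generate_database(spec)
    records <- filter_suspected(build_all_data_table(sim$db))
    res <- screen_exposures(records, vary = "drug_name",
                            event = event_is("hiccups"), unit = "case")
    row <- res[res$exposure == "null_drug", ]
    if (!is.na(row$ci_low) && row$ci_low <= 1 && row$ci_high >= 1) {
      covered <- covered + 1L
    }
  }
  # ~95% coverage; 3 SDs of binomial(150, 0.95) is about 5.3%
  expect_gte(covered / n_seed, 0.89)
  expect_lte(covered / n_seed, 1.0)
})

test_that("a planted multiplier is recovered within the screen CI", {
  spec <- synthetic_spec(
    n_cases = 50000,
    drugs = list(drug_spec("drug_x", 0.05, 5,
                           involvement_distribution = c(suspected = 1,
                                                        concomitant = 0,
                                                        interaction = 0))),
    background_event_rate = 0.01,
    duplicate_fraction = 0.05,
    seed = 42
  )
  sim <- generate_database(spec)
  records <- filter_suspected(build_all_data_table(
    deduplicate_reports(sim$db)
  ))
  res <- screen_exposures(records, vary = "drug_name",
                          event = event_is("hiccups"), unit = "case")
  row <- res[res$exposure == "drug_x", ]
  expect_true(row$ci_low <= 5 && 5 <= row$ci_high)
  expect_true(row$is_signal)
})

test_that("2x2 fixtures replay printed tables through the pipeline", {
  db <- fixture_from_counts(2, 3379, 158, 968681,
                            exposure_label = "dexamethasone")
  records <- filter_suspected(build_all_data_table(db))
  res <- screen_exposures(records, vary = "drug_name",
                          event = event_is("hiccups"))
  row <- res[res$exposure == "dexamethasone", ]
  expect_identical(c(row$a, row$b, row$c, row$d),
                   c(2L, 3379L, 158L, 968681L))
  expect_equal(row$p_value,
               fisher_exact_two_sided(contingency(2, 3379, 158, 968681)))

  sym <- fixture_from_counts(1, 1, 1, 1)
  res_sym <- screen_exposures(filter_suspected(build_all_data_table(sym)),
                              vary = "drug_name", event = event_is("hiccups"))
  expect_equal(res_sym$ror[res_sym$exposure == "drug_x"], 1)
})

test_that("databases round-trip through disk including ground truth", {
  dir <- withr::local_tempdir()
  spec <- base_spec(n = 500)
  sim <- generate_database(spec)
  paths <- write_report_db(sim$db, dir, truth = sim$truth)
  expect_true(all(file.exists(paths)))
  back <- read_report_tables(paths["demo"], paths["drug"], paths["reac"])
  expect_identical(db_counts(back), db_counts(sim$db))
  expect_identical(back$drug, sim$db$drug)
  manifest <- yaml::read_yaml(paths["manifest"])
  expect_identical(manifest$seed, 5L)
  expect_identical(length(manifest$drugs), 2L)
})
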