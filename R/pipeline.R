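#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Every analysis threshold
#' surfaces as a named key with its conventional default: 0.05 significance,
#' report-count filter 3, Spearman rho-squared collinearity threshold 0.9,
#' 95% confidence level. Unknown keys are rejected; validation (including the
#' existence of input files) happens before any computation.
#'
#' @param input List with entries `demo`, `drug`, `reac` (paths) and optional
#'   `delim`, `encoding`, `columns` (see [read_report_tables()]). `NULL` when
#'   a database object is passed to [run_pipeline()] directly.
#' @param output_dir Directory for all artifacts (created if needed).
#' @param event_term Target adverse-event term (default `"hiccups"`).
#' @param synonym_map Named character vector `c(registered = "canonical")`,
#'   or a path to a two-column CSV (`registered,canonical`), or `NULL`.
#' @param anticancer_drugs Character vector of co-treatment class drug names,
#'   or a path to a one-column text file, or `NULL` to skip the co-treatment
#'   stage.
#' @param stratify_drug Drug for the route analysis (default
#'   `"dexamethasone"`); `NULL` skips it.
#' @param min_reports Strict report-count filter for predictor selection.
#' @param alpha Significance level.
#' @param ci_level Confidence level.
#' @param collinearity_threshold Rho-squared threshold.
#' @param t_test_variant `"welch"` or `"pooled"`.
#' @param continuity_correction Haldane-Anscombe correction flag.
#' @param screen_unit Analysis unit of the drug screen (`"record"` default).
#' @param model_unit Analysis unit of the logistic model (`"case"` default).
#' @param seed Seed for synthetic mode (`synthetic` entry), otherwise unused.
#' @param synthetic Optional [synthetic_spec()]: generate the database
#'   instead of reading `input`.
#' @param ... Unknown keys: rejected with an error.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, output_dir,
                            event_term = "hiccups",
                            synonym_map = NULL,
                            anticancer_drugs = NULL,
                            stratify_drug = "dexamethasone",
                            min_reports = 3,
                            alpha = 0.05,
                            ci_level = 0.95,
                            collinearity_threshold = 0.9,
                            t_test_variant = c("welch", "pooled"),
                            continuity_correction = FALSE,
                            screen_unit = c("record", "case"),
                            model_unit = c("case", "record"),
                            seed = 1L,
                            synthetic = NULL,
                            ...) {
  extra <- list(...)
  if (length(extra)) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(names(extra), collapse = ", ")),
          class = "rorscreen_config_error")
  }
  t_test_variant <- match.arg(t_test_variant)
  screen_unit <- match.arg(screen_unit)
  model_unit <- match.arg(model_unit)
  if (is.null(input) && is.null(synthetic)) {
    abort("supply `input` paths or a `synthetic` spec.",
          class = "rorscreen_config_error")
  }
  if (!is.null(input)) {
    for (k in c("demo", "drug", "reac")) {
      if (is.null(input[[k]])) {
        abort(sprintf("`input$%s` path is required.", k),
              class = "rorscreen_config_error")
      }
      if (!file.exists(input[[k]])) {
        abort(sprintf("`input$%s` does not exist: %s", k, input[[k]]),
              class = "rorscreen_config_error")
      }
    }
  }
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_spec")) {
    abort("`synthetic` must be a synthetic_spec object.",
          class = "rorscreen_config_error")
  }
  if (!is_prob(alpha) || !is_prob(ci_level) || ci_level <= 0 || ci_level >= 1) {
    abort("`alpha` and `ci_level` must be probabilities (ci_level in (0,1)).",
          class = "rorscreen_config_error")
  }
  if (!is_count(min_reports)) {
    abort("`min_reports` must be a non-negative integer.",
          class = "rorscreen_config_error")
  }
  if (is.character(synonym_map) && length(synonym_map) == 1 &&
      file.exists(synonym_map) && is.null(names(synonym_map))) {
    tbl <- readr::read_csv(synonym_map, col_types = "cc", progress = FALSE,
                           show_col_types = FALSE)
    synonym_map <- setNames(tbl[[2]], tbl[[1]])
  }
  if (is.character(anticancer_drugs) && length(anticancer_drugs) == 1 &&
      file.exists(anticancer_drugs)) {
    anticancer_drugs <- readr::read_lines(anticancer_drugs, progress = FALSE)
    anticancer_drugs <- anticancer_drugs[nzchar(trimws(anticancer_drugs))]
  }
  structure(
    list(input = input, output_dir = output_dir, event_term = event_term,
         synonym_map = synonym_map, anticancer_drugs = anticancer_drugs,
         stratify_drug = stratify_drug, min_reports = min_reports,
         alpha = alpha, ci_level = ci_level,
         collinearity_threshold = collinearity_threshold,
         t_test_variant = t_test_variant,
         continuity_correction = continuity_correction,
         screen_unit = screen_unit, model_unit = model_unit,
         seed = as.integer(seed), synthetic = synthetic),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [pipeline_config()] (the `synthetic` block, when present, holds
#'   [synthetic_spec()] arguments with `drugs` as a list of [drug_spec()]
#'   argument lists).
#' @return A validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file does not exist: %s", path),
          class = "rorscreen_config_error")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$synthetic)) {
    syn <- raw$synthetic
    syn$drugs <- lapply(syn$drugs, function(d) {
      d <- lapply(d, function(v) if (is.list(v)) unlist(v) else v)
      do.call(drug_spec, d)
    })
    for (nm in c("age_decades", "height_ranges", "weight_ranges",
                 "missing_fractions")) {
      if (!is.null(syn[[nm]])) syn[[nm]] <- unlist(syn[[nm]])
    }
    if (!is.null(syn$year_range)) syn$year_range <- unlist(syn$year_range)
    raw$synthetic <- do.call(synthetic_spec, syn)
  }
  if (!is.null(raw$synonym_map) && is.list(raw$synonym_map)) {
    raw$synonym_map <- unlist(raw$synonym_map)
  }
  if (!is.null(raw$anticancer_drugs)) {
    raw$anticancer_drugs <- unlist(raw$anticancer_drugs)
  }
  do.call(pipeline_config, raw)
}

#' Run the full screening pipeline
#'
#' Sequences the stages end-to-end: read (or generate) the raw tables,
#' deduplicate, join into the all-data table, extract the suspected-medicine
#' table, normalize drug names, compare patient backgrounds, test the
#' reporting-year trend, screen drugs (and gender) for disproportionate
#' event reporting with volcano plots, select predictors and fit the
#' multiple logistic regression, and run the administration-route and
#' co-treatment analyses. All tabular outputs are written as TSV, plots as
#' PNG, and a run log records the record count after every stage. Any stage
#' error aborts with a message naming the stage. Re-running with the same
#' configuration and inputs reproduces identical tabular outputs.
#'
#' @param config A [pipeline_config()].
#' @param db Optional [report_db()] to use instead of reading `config$input`.
#' @return Invisibly, a list with `artifacts` (named paths), `stage_counts`
#'   (tibble of record counts per stage) and the in-memory results.
#' @export
run_pipeline <- function(config, db = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  results <- list()
  counts <- list()
  log_lines <- character()
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    inform(paste0("[rorscreen] ", line))
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage \"%s\" failed: %s", name,
                    conditionMessage(e)), parent = e)
    })
  }
  out_path <- function(name) file.path(config$output_dir, name)
  save_tsv <- function(x, name) {
    p <- out_path(name)
    readr::write_tsv(tibble::as_tibble(x), p, progress = FALSE)
    artifacts[[name]] <<- p
    p
  }
  save_plot <- function(p, name) {
    path <- out_path(name)
    suppressMessages(ggplot2::ggsave(path, p, width = 7, height = 5, dpi = 150))
    artifacts[[name]] <<- path
    path
  }

  ev <- event_is(config$event_term)

  db <- stage("read", {
    if (!is.null(db)) {
      db
    } else if (!is.null(config$synthetic)) {
      sim <- generate_database(config$synthetic, seed = config$seed)
      results$ground_truth <- sim$truth
      sim$db
    } else {
      read_report_tables(
        config$input$demo, config$input$drug, config$input$reac,
        format_options = config$input
      )
    }
  })
  raw <- db_counts(db)
  counts$raw_drug_rows <- raw[["drugs"]]
  counts$raw_reaction_rows <- raw[["events"]]
  counts$cases <- raw[["cases"]]
  note("read: %d cases, %d drug rows, %d reaction rows.",
       raw[["cases"]], raw[["drugs"]], raw[["events"]])

  db <- stage("deduplicate", deduplicate_reports(db))
  removed <- attr(db, "dedup_removed")
  counts$deduplicated_drug_rows <- nrow(db$drug)
  counts$deduplicated_reaction_rows <- nrow(db$reac)
  note("deduplicate: removed %d drug and %d reaction duplicate row(s).",
       removed[["drug"]], removed[["reac"]])

  all_data <- stage("join", {
    withCallingHandlers(
      build_all_data_table(db),
      warning = function(w) {
        note("join: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
  })
  counts$all_data_records <- nrow(all_data)
  note("join: all-data table has %d records.", nrow(all_data))

  all_data <- stage("normalize",
                    normalize_drug_names(all_data, config$synonym_map %||%
                                           character()))
  suspected <- stage("suspected_filter", filter_suspected(all_data))
  counts$suspected_records <- nrow(suspected)
  note("suspected filter: %d records retained.", nrow(suspected))
  save_tsv(suspected, "suspected_table.tsv")

  results$background <- stage("background", {
    patient_background(suspected, ev, variant = config$t_test_variant)
  })
  save_tsv(results$background, "patient_background.tsv")

  results$trend <- stage("yearly_trend", {
    tryCatch(yearly_trend(suspected, ev), error = function(e) NULL)
  })
  if (!is.null(results$trend)) {
    save_tsv(tibble::tibble(year = results$trend$years,
                            value = results$trend$per_year,
                            rho = results$trend$rho,
                            p_value = results$trend$p_value),
             "yearly_trend.tsv")
    note("yearly trend: rho = %.4f, p = %.4f.",
         results$trend$rho, results$trend$p_value)
  } else {
    note("yearly trend: skipped (fewer than 2 report years).")
  }

  results$drug_screen <- stage("drug_screen", {
    screen_exposures(suspected, vary = "drug_name", event = ev,
                     unit = config$screen_unit, level = config$ci_level,
                     correction = config$continuity_correction)
  })
  save_tsv(results$drug_screen, "drug_screen.tsv")
  save_plot(volcano_plot(results$drug_screen, p_baseline = config$alpha,
                         title = paste("Drug screen:", config$event_term)),
            "volcano_drugs.png")
  note("drug screen: %d exposures, %d signal(s).",
       nrow(results$drug_screen), sum(results$drug_screen$is_signal))

  results$gender_screen <- stage("gender_screen", {
    if (all(is.na(suspected$sex))) NULL
    else screen_exposures(suspected, vary = "event_term",
                          exposure = function(r) r$sex == "male",
                          unit = config$screen_unit, level = config$ci_level,
                          correction = config$continuity_correction)
  })
  if (!is.null(results$gender_screen)) {
    save_tsv(results$gender_screen, "gender_screen.tsv")
    save_plot(volcano_plot(results$gender_screen, p_baseline = config$alpha,
                           title = "Adverse events by gender (male exposure)"),
              "volcano_gender.png")
  }

  results$model <- stage("logistic_model", {
    sel <- select_predictors(results$drug_screen, alpha = config$alpha,
                             min_reports = config$min_reports)
    mm <- tryCatch(
      build_model_matrix(suspected, sel$drugs, ev, unit = config$model_unit),
      error = function(e) {
        note("logistic model: skipped (%s)", conditionMessage(e))
        NULL
      }
    )
    if (is.null(mm)) NULL else {
      counts$complete_case_rows <- nrow(mm)
      note("logistic model: %d complete-%s rows (%d dropped for missingness).",
           nrow(mm), config$model_unit, attr(mm, "n_dropped_missing"))
      coll <- collinearity_screen(mm[setdiff(names(mm), "event")],
                                  threshold = config$collinearity_threshold)
      save_tsv(coll, "collinearity.tsv")
      if (isTRUE(attr(coll, "any_flagged"))) {
        note("collinearity: %d pair(s) flagged.", sum(coll$flagged))
      }
      fit <- fit_logistic(mm, level = config$ci_level, alpha = config$alpha)
      save_tsv(fit, "logistic_model.tsv")
      fit
    }
  })

  results$routes <- stage("route_screen", {
    if (is.null(config$stratify_drug) ||
        !config$stratify_drug %in% suspected$drug_name) NULL
    else route_screen(suspected, config$stratify_drug, ev)
  })
  if (!is.null(results$routes)) {
    save_tsv(results$routes, "route_screen.tsv")
    iv <- suspected$route %in% "intravenous"
    if (any(iv)) {
      results$route_volcano <- screen_exposures(
        suspected, vary = "event_term",
        exposure = function(r) r$route %in% "intravenous",
        unit = config$screen_unit, level = config$ci_level,
        correction = config$continuity_correction
      )
      save_tsv(results$route_volcano, "route_event_screen.tsv")
      save_plot(volcano_plot(results$route_volcano, p_baseline = config$alpha,
                             title = "Adverse events by intravenous route"),
                "volcano_route.png")
    }
  }

  results$cotreatment <- stage("cotreatment", {
    if (is.null(config$anticancer_drugs) ||
        is.null(config$stratify_drug)) NULL
    else {
      tab <- cotreatment_cross_tab(all_data, ev, config$stratify_drug,
                                   config$anticancer_drugs)
      pct <- cotreatment_percentages(tab)
      save_tsv(tibble::tibble(
        n_both = tab$n_both, n_drug_a_only = tab$n_drug_a_only,
        n_class_b_only = tab$n_class_b_only, n_neither = tab$n_neither,
        n_cases = tab$n_cases, !!!as.list(pct)
      ), "cotreatment.tsv")
      list(table = tab, percentages = pct)
    }
  })

  stage_counts <- tibble::tibble(stage = names(counts),
                                 n = unlist(counts, use.names = FALSE))
  save_tsv(stage_counts, "stage_counts.tsv")
  writeLines(log_lines, out_path("run_log.txt"))
  artifacts[["run_log.txt"]] <- out_path("run_log.txt")

  invisible(list(artifacts = artifacts, stage_counts = stage_counts,
                 results = results))
}
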