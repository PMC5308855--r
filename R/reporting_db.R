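#' Report-database container
#'
#' Bundles the three tables of a JADER-style spontaneous reporting database:
#' case demographics (`demo`), case-linked drug exposures (`drug`) and
#' case-linked adverse-event terms (`reac`). Construction validates the schema
#' and the categorical fields; drug or reaction rows whose `case_id` has no
#' demographics row are tolerated here (they are resolved by the orphan policy
#' of [build_all_data_table()]) but their count is attached as the
#' `"n_orphans"` attribute.
#'
#' @param demo Tibble with columns `case_id`, `sex`, `age_code`, `height_code`,
#'   `weight_code`, `report_year`.
#' @param drug Tibble with columns `case_id`, `drug_name`, `involvement`,
#'   `route`.
#' @param reac Tibble with columns `case_id`, `event_term`.
#' @return An object of class `report_db`: a list with elements `demo`, `drug`,
#'   `reac`.
#' @export
report_db <- function(demo, drug, reac) {
  demo <- tibble::as_tibble(demo)
  drug <- tibble::as_tibble(drug)
  reac <- tibble::as_tibble(reac)

  need <- function(tbl, cols, what) {
    missing <- setdiff(cols, names(tbl))
    if (length(missing)) {
      abort(sprintf(
        "%s table is missing required column(s): %s",
        what, paste0("`", missing, "`", collapse = ", ")
      ), class = "rorscreen_schema_error")
    }
  }
  need(demo, c("case_id", "sex", "age_code", "height_code", "weight_code",
               "report_year"), "demographics")
  need(drug, c("case_id", "drug_name", "involvement", "route"), "drug")
  need(reac, c("case_id", "event_term"), "reaction")

  if (anyNA(demo$case_id) || any(!nzchar(demo$case_id))) {
    abort("demographics `case_id` must be non-empty.",
          class = "rorscreen_schema_error")
  }
  if (anyDuplicated(demo$case_id)) {
    abort("demographics `case_id` must be unique (deduplicate upstream).",
          class = "rorscreen_schema_error")
  }
  bad_inv <- setdiff(unique(drug$involvement), INVOLVEMENT_LEVELS)
  if (length(bad_inv)) {
    abort(sprintf(
      "unknown involvement categor%s: %s (expected %s)",
      if (length(bad_inv) > 1) "ies" else "y",
      paste0("\"", bad_inv, "\"", collapse = ", "),
      paste(INVOLVEMENT_LEVELS, collapse = "/")
    ), class = "rorscreen_schema_error")
  }
  if (any(!nzchar(drug$drug_name) | is.na(drug$drug_name))) {
    abort("`drug_name` must be non-empty.", class = "rorscreen_schema_error")
  }
  if (any(!nzchar(reac$event_term) | is.na(reac$event_term))) {
    abort("`event_term` must be non-empty.", class = "rorscreen_schema_error")
  }

  orphans <- c(
    drug = sum(!drug$case_id %in% demo$case_id),
    reac = sum(!reac$case_id %in% demo$case_id)
  )
  structure(
    list(demo = demo, drug = drug, reac = reac),
    n_orphans = orphans,
    class = "report_db"
  )
}

INVOLVEMENT_LEVELS <- c("suspected", "concomitant", "interaction")
ROUTE_LEVELS <- c("intravenous", "oral", "other")

#' @export
print.report_db <- function(x, ...) {
  n <- db_counts(x)
  cat("<report_db> ", n["cases"], " cases, ", n["drugs"], " drug rows, ",
      n["events"], " reaction rows\n", sep = "")
  invisible(x)
}

#' Row counts of a report database
#'
#' @param db A [report_db()].
#' @return Named integer vector `c(cases, drugs, events)`.
#' @export
db_counts <- function(db) {
  stopifnot(inherits(db, "report_db"))
  c(cases = nrow(db$demo), drugs = nrow(db$drug), events = nrow(db$reac))
}

# Canonical column names of each raw table.
DEMO_COLS <- c("case_id", "sex", "age_code", "height_code", "weight_code",
               "report_year")
DRUG_COLS <- c("case_id", "drug_name", "involvement", "route")
REAC_COLS <- c("case_id", "event_term")

#' Read the three raw reporting tables
#'
#' Reads delimited demographics, drug and reaction tables into a validated
#' [report_db()]. Columns can be renamed via `format_options$columns`, a named
#' list per table mapping canonical names to the file's header names.
#' Mandatory columns (`case_id` in each table, `drug_name` and `involvement`
#' in the drug table, `event_term` in the reaction table) raise a schema error
#' when absent; optional demographics columns absent from the file are filled
#' with missing values. Unparseable demographic codes, report years, sexes and
#' routes become missing values and their count is reported via a message.
#'
#' @param demo_path,drug_path,reac_path Paths to the delimited tables.
#' @param format_options List with optional entries `delim` (default `","`),
#'   `encoding` (default `"UTF-8"`) and `columns` (list with optional entries
#'   `demo`, `drug`, `reac`; each a named character vector
#'   `c(canonical = "file column")`).
#' @return A [report_db()].
#' @export
read_report_tables <- function(demo_path, drug_path, reac_path,
                               format_options = list()) {
  delim <- format_options$delim %||% ","
  enc <- format_options$encoding %||% "UTF-8"
  maps <- format_options$columns %||% list()

  for (p in c(demo_path, drug_path, reac_path)) {
    if (!file.exists(p)) {
      abort(sprintf("input file does not exist: %s", p),
            class = "rorscreen_io_error")
    }
  }

  read_one <- function(path, canonical, mandatory, map) {
    tbl <- readr::read_delim(
      path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
      locale = readr::locale(encoding = enc), progress = FALSE,
      show_col_types = FALSE
    )
    if (!is.null(map)) {
      for (canon in names(map)) {
        if (!map[[canon]] %in% names(tbl)) next
        names(tbl)[names(tbl) == map[[canon]]] <- canon
      }
    }
    missing_mand <- setdiff(mandatory, names(tbl))
    if (length(missing_mand)) {
      abort(sprintf(
        "file %s is missing mandatory column(s): %s",
        path, paste0("`", missing_mand, "`", collapse = ", ")
      ), class = "rorscreen_schema_error")
    }
    for (col in setdiff(canonical, names(tbl))) tbl[[col]] <- NA_character_
    tbl <- tbl[canonical]
    # exact matching downstream is defined after whitespace trimming
    for (col in canonical) tbl[[col]] <- trimws(tbl[[col]])
    tbl[tbl == ""] <- NA
    tbl
  }

  demo <- read_one(demo_path, DEMO_COLS, "case_id", maps$demo)
  drug <- read_one(drug_path, DRUG_COLS, c("case_id", "drug_name", "involvement"),
                   maps$drug)
  reac <- read_one(reac_path, REAC_COLS, c("case_id", "event_term"), maps$reac)

  n_bad <- 0L
  parse_enum <- function(x, levels) {
    out <- tolower(x)
    bad <- !is.na(out) & !out %in% levels
    n_bad <<- n_bad + sum(bad)
    out[bad] <- NA_character_
    out
  }
  demo$sex <- parse_enum(demo$sex, c("male", "female"))
  year <- suppressWarnings(as.integer(demo$report_year))
  n_bad <- n_bad + sum(!is.na(demo$report_year) & is.na(year))
  demo$report_year <- year
  drug$route <- parse_enum(drug$route, ROUTE_LEVELS)
  drug$involvement <- tolower(drug$involvement)
  if (n_bad > 0) {
    inform(sprintf("read_report_tables: %d unparseable value(s) set to missing.",
                   n_bad))
  }
  report_db(demo, drug, reac)
}

#' Remove duplicated drug and reaction rows
#'
#' A duplicate is a row identical on all fields of its table (the most
#' conservative reading; pass `keys` to deduplicate on a column subset).
#' The first occurrence of each row is kept in its original position. The
#' demographics table is untouched: its `case_id` uniqueness is enforced at
#' construction. The numbers of removed rows are attached as the
#' `"dedup_removed"` attribute of the returned database.
#'
#' @param db A [report_db()].
#' @param keys Optional list with entries `drug` and/or `reac` naming the
#'   columns that define a duplicate; default: all columns.
#' @return The deduplicated [report_db()] with attribute
#'   `dedup_removed = c(drug = , reac = )`.
#' @export
deduplicate_reports <- function(db, keys = list()) {
  stopifnot(inherits(db, "report_db"))
  dedup <- function(tbl, key_cols) {
    if (is.null(key_cols)) dplyr::distinct(tbl)
    else dplyr::distinct(tbl, dplyr::pick(dplyr::all_of(key_cols)),
                         .keep_all = TRUE)
  }
  drug <- dedup(db$drug, keys$drug)
  reac <- dedup(db$reac, keys$reac)
  removed <- c(drug = nrow(db$drug) - nrow(drug),
               reac = nrow(db$reac) - nrow(reac))
  out <- report_db(db$demo, drug, reac)
  attr(out, "dedup_removed") <- removed
  out
}

#' Join demographics, drugs and reactions into the all-data table
#'
#' Inner-joins the three tables on `case_id`: each case contributes one record
#' per (drug row, reaction row) pair, so a case with two drugs and two events
#' yields four records. Drug or reaction rows whose `case_id` has no
#' demographics row ("orphans") are dropped with a warning under the default
#' policy; `orphan_policy = "error"` aborts instead. The number of dropped
#' orphan rows is attached as attribute `"n_orphans"`.
#'
#' @param db A deduplicated [report_db()].
#' @param orphan_policy `"drop"` (default) or `"error"`.
#' @return A tibble of analysis records with columns `case_id`, `sex`,
#'   `age_code`, `height_code`, `weight_code`, `report_year`, `drug_name`,
#'   `involvement`, `route`, `event_term`.
#' @export
build_all_data_table <- function(db, orphan_policy = c("drop", "error")) {
  stopifnot(inherits(db, "report_db"))
  orphan_policy <- match.arg(orphan_policy)
  n_orphans <- sum(attr(db, "n_orphans") %||%
                     c(sum(!db$drug$case_id %in% db$demo$case_id),
                       sum(!db$reac$case_id %in% db$demo$case_id)))
  if (n_orphans > 0) {
    if (orphan_policy == "error") {
      abort(sprintf("%d drug/reaction row(s) reference unknown case IDs.",
                    n_orphans))
    }
    warn(sprintf(
      "build_all_data_table: dropped %d orphan drug/reaction row(s).",
      n_orphans
    ))
  }
  records <- db$demo |>
    dplyr::inner_join(db$drug, by = "case_id",
                      relationship = "one-to-many") |>
    dplyr::inner_join(db$reac, by = "case_id",
                      relationship = "many-to-many")
  records <- records[ANALYSIS_COLS]
  attr(records, "n_orphans") <- n_orphans
  records
}

ANALYSIS_COLS <- c("case_id", "sex", "age_code", "height_code", "weight_code",
                   "report_year", "drug_name", "involvement", "route",
                   "event_term")

#' Keep only suspected-medicine records
#'
#' Restricts an all-data record table to rows whose drug involvement was
#' reported as `"suspected"`; the primary disproportionality screen runs on
#' this table.
#'
#' @param records Analysis records from [build_all_data_table()].
#' @return The suspected-medicine subset, same columns.
#' @export
filter_suspected <- function(records) {
  assert_records(records)
  dplyr::filter(records, .data$involvement == "suspected")
}

#' Map route-specific registered names to canonical generic names
#'
#' Registered drug names can differ by formulation or administration route
#' (e.g. "dexamethasone sodium phosphate" vs "dexamethasone"); counting them
#' separately splits a drug's reports. Applies a synonym map; unmapped names
#' pass through unchanged.
#'
#' @param records Analysis records.
#' @param synonym_map Named character vector `c(registered = "canonical")`.
#' @return Records with canonical `drug_name`.
#' @export
normalize_drug_names <- function(records, synonym_map = character()) {
  assert_records(records)
  if (!length(synonym_map)) return(records)
  if (is.null(names(synonym_map)) || any(!nzchar(names(synonym_map)))) {
    abort("`synonym_map` must be a named character vector.")
  }
  hit <- records$drug_name %in% names(synonym_map)
  records$drug_name[hit] <- unname(synonym_map[records$drug_name[hit]])
  records
}

#' Write an analysis-record table as tab-separated text
#'
#' @param records Analysis records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_analysis_table <- function(records, path) {
  assert_records(records)
  readr::write_tsv(records[ANALYSIS_COLS], path, progress = FALSE)
  invisible(path)
}
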