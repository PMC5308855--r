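#' Specification of one simulated drug
#'
#' @param name Drug generic name.
#' @param prevalence Probability that a case is exposed, in (0, 1).
#' @param event_odds_multiplier Planted reporting odds multiplier: the factor
#'   applied to a case's event odds when exposed (1 = null drug).
#' @param route_distribution Named probabilities over
#'   intravenous/oral/other (must sum to 1).
#' @param involvement_distribution Named probabilities over
#'   suspected/concomitant/interaction (must sum to 1).
#' @return Object of class `drug_spec`.
#' @export
drug_spec <- function(name, prevalence, event_odds_multiplier = 1,
                      route_distribution = c(intravenous = 0.3, oral = 0.6,
                                             other = 0.1),
                      involvement_distribution = c(suspected = 0.6,
                                                   concomitant = 0.35,
                                                   interaction = 0.05)) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    abort("`name` must be a non-empty string.", class = "rorscreen_spec_error")
  }
  if (!is_prob(prevalence) || prevalence <= 0 || prevalence >= 1) {
    abort("`prevalence` must lie in (0, 1).", class = "rorscreen_spec_error")
  }
  if (!is.numeric(event_odds_multiplier) || event_odds_multiplier <= 0) {
    abort("`event_odds_multiplier` must be positive.",
          class = "rorscreen_spec_error")
  }
  check_dist(route_distribution, ROUTE_LEVELS, "route_distribution")
  check_dist(involvement_distribution, INVOLVEMENT_LEVELS,
             "involvement_distribution")
  structure(
    list(name = name, prevalence = prevalence,
         event_odds_multiplier = event_odds_multiplier,
         route_distribution = route_distribution,
         involvement_distribution = involvement_distribution),
    class = "drug_spec"
  )
}

check_dist <- function(p, levels, what) {
  if (is.null(names(p)) || !setequal(names(p), levels) ||
      any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    abort(sprintf("`%s` must be probabilities named %s summing to 1.",
                  what, paste(levels, collapse = "/")),
          class = "rorscreen_spec_error")
  }
  invisible(p)
}

#' Specification of a simulated reporting database
#'
#' Parameterizes a JADER-shaped database with known ground truth. Each case
#' draws a latent sex and coded age/height/weight (masked afterwards by
#' per-field missing-completely-at-random fractions), a report year, an
#' independent exposure per listed drug, plus one background medicine from a
#' null pool so every case has at least one drug row. The event indicator is
#' drawn from a logistic model whose log-odds are
#' `logit(background_event_rate) + male * log(male_odds_multiplier) + sum of
#' log(event_odds_multiplier)` over the case's exposures — multiplicative on
#' the odds scale, so at low event rates each planted multiplier is directly
#' comparable to the marginal reporting odds ratio the screen estimates.
#' Duplicate rows are injected by re-emitting a fraction of drug and reaction
#' rows as exact copies.
#'
#' @param n_cases Number of cases.
#' @param drugs List of [drug_spec()] objects (at least one; names unique and
#'   disjoint from the background pool).
#' @param background_event_rate Event probability for an unexposed female
#'   case, in (0, 1); `n_cases * background_event_rate` must be at least 1.
#' @param event_term Target adverse-event term (default `"hiccups"`).
#' @param male_fraction Probability of male sex (default 0.5).
#' @param male_odds_multiplier Optional male event-odds multiplier (default 1;
#'   set above 1 to emulate male-skewed event risk).
#' @param age_decades,height_ranges,weight_ranges Named categorical
#'   distributions over the range codes.
#' @param missing_fractions Named vector with entries `sex`, `age`, `height`,
#'   `weight`: per-field MCAR missingness.
#' @param year_range Length-2 integer vector of report years.
#' @param duplicate_fraction Fraction of drug/reaction rows re-emitted as
#'   exact duplicates, in [0, 1).
#' @param extra_event_rate Probability that a case carries a second,
#'   background adverse-event term (default 0.2).
#' @param n_background_drugs Size of the null background-medicine pool.
#' @param seed Default random seed used by [generate_database()].
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cases,
                           drugs,
                           background_event_rate,
                           event_term = "hiccups",
                           male_fraction = 0.5,
                           male_odds_multiplier = 1,
                           age_decades = DEFAULT_AGE_DECADES,
                           height_ranges = DEFAULT_HEIGHT_RANGES,
                           weight_ranges = DEFAULT_WEIGHT_RANGES,
                           missing_fractions = c(sex = 0.02, age = 0.04,
                                                 height = 0.50, weight = 0.45),
                           year_range = c(2004L, 2015L),
                           duplicate_fraction = 0.05,
                           extra_event_rate = 0.2,
                           n_background_drugs = 30,
                           seed = 1L) {
  if (!is_count(n_cases) || n_cases < 1) {
    abort("`n_cases` must be a positive integer.",
          class = "rorscreen_spec_error")
  }
  if (inherits(drugs, "drug_spec")) drugs <- list(drugs)
  if (!length(drugs) || !all(vapply(drugs, inherits, logical(1), "drug_spec"))) {
    abort("`drugs` must be a non-empty list of drug_spec objects.",
          class = "rorscreen_spec_error")
  }
  drug_names <- vapply(drugs, `[[`, character(1), "name")
  if (anyDuplicated(drug_names)) {
    abort("drug names must be unique.", class = "rorscreen_spec_error")
  }
  if (!is_prob(background_event_rate) || background_event_rate <= 0 ||
      background_event_rate >= 1) {
    abort("`background_event_rate` must lie in (0, 1).",
          class = "rorscreen_spec_error")
  }
  if (n_cases * background_event_rate < 1) {
    abort("expected event count is below 1; raise `n_cases` or the rate.",
          class = "rorscreen_spec_error")
  }
  if (!is_prob(male_fraction)) {
    abort("`male_fraction` must lie in [0, 1].", class = "rorscreen_spec_error")
  }
  if (!is.numeric(male_odds_multiplier) || male_odds_multiplier <= 0) {
    abort("`male_odds_multiplier` must be positive.",
          class = "rorscreen_spec_error")
  }
  for (nm in c("sex", "age", "height", "weight")) {
    if (!is_prob(missing_fractions[[nm]])) {
      abort(sprintf("`missing_fractions[\"%s\"]` must lie in [0, 1].", nm),
            class = "rorscreen_spec_error")
    }
  }
  for (d in list(age_decades = age_decades, height_ranges = height_ranges,
                 weight_ranges = weight_ranges)) {
    if (any(d < 0) || abs(sum(d) - 1) > 1e-8 || is.null(names(d))) {
      abort("range-code distributions must be named and sum to 1.",
            class = "rorscreen_spec_error")
    }
  }
  if (!is_prob(duplicate_fraction) || duplicate_fraction >= 1) {
    abort("`duplicate_fraction` must lie in [0, 1).",
          class = "rorscreen_spec_error")
  }
  if (!is_prob(extra_event_rate)) {
    abort("`extra_event_rate` must lie in [0, 1].",
          class = "rorscreen_spec_error")
  }
  background_pool <- sprintf("medicine_%02d", seq_len(n_background_drugs))
  if (any(drug_names %in% background_pool)) {
    abort("drug names must not collide with the background-medicine pool.",
          class = "rorscreen_spec_error")
  }
  structure(
    list(n_cases = as.integer(n_cases), drugs = drugs,
         background_event_rate = background_event_rate,
         event_term = event_term, male_fraction = male_fraction,
         male_odds_multiplier = male_odds_multiplier,
         age_decades = age_decades, height_ranges = height_ranges,
         weight_ranges = weight_ranges, missing_fractions = missing_fractions,
         year_range = as.integer(year_range),
         duplicate_fraction = duplicate_fraction,
         extra_event_rate = extra_event_rate,
         background_pool = background_pool, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

DEFAULT_AGE_DECADES <- c("0s" = 0.02, "10s" = 0.03, "20s" = 0.06, "30s" = 0.09,
                         "40s" = 0.12, "50s" = 0.16, "60s" = 0.22, "70s" = 0.20,
                         "80s" = 0.08, "90s" = 0.02)
DEFAULT_HEIGHT_RANGES <- c("130-139" = 0.05, "140-149" = 0.15, "150-159" = 0.30,
                           "160-169" = 0.30, "170-179" = 0.15, "180-189" = 0.05)
DEFAULT_WEIGHT_RANGES <- c("30-39" = 0.08, "40-49" = 0.25, "50-59" = 0.30,
                           "60-69" = 0.22, "70-79" = 0.10, "80-89" = 0.04,
                           "90-99" = 0.01)
BACKGROUND_EVENT_POOL <- c("nausea", "rash", "pyrexia", "headache", "vomiting",
                           "diarrhoea", "dizziness", "pruritus", "fatigue",
                           "insomnia", "anaemia", "cough", "constipation",
                           "oedema", "dyspnoea")

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate a synthetic report database with known ground truth
#'
#' Draws a database from a [synthetic_spec()]; identical spec and seed give
#' byte-identical tables. The returned ground truth records every planted
#' parameter together with the realized case-level exposure-by-event
#' contingency of each listed drug (exposure regardless of involvement
#' category, before duplicate injection), so screens can be checked against
#' what was actually planted.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed (default `spec$seed`).
#' @return List with elements `db` (a [report_db()]) and `truth`.
#' @export
generate_database <- function(spec, seed = spec$seed) {
  if (!inherits(spec, "synthetic_spec")) {
    abort("`spec` must be a synthetic_spec object.",
          class = "rorscreen_spec_error")
  }
  with_local_seed(seed, {
    n <- spec$n_cases
    case_id <- sprintf("C%07d", seq_len(n))
    male <- runif(n) < spec$male_fraction

    draw_code <- function(dist) {
      sample(names(dist), n, replace = TRUE, prob = dist)
    }
    age <- draw_code(spec$age_decades)
    height <- draw_code(spec$height_ranges)
    weight <- draw_code(spec$weight_ranges)
    year <- sample(seq(spec$year_range[1], spec$year_range[2]), n,
                   replace = TRUE)

    mask <- function(x, frac) {
      x[runif(n) < frac] <- NA
      x
    }
    mf <- spec$missing_fractions
    sex_obs <- mask(ifelse(male, "male", "female"), mf[["sex"]])
    demo <- tibble::tibble(
      case_id = case_id,
      sex = sex_obs,
      age_code = mask(age, mf[["age"]]),
      height_code = mask(height, mf[["height"]]),
      weight_code = mask(weight, mf[["weight"]]),
      report_year = as.integer(year)
    )

    # independent exposures, multiplicative event odds
    k <- length(spec$drugs)
    exposed <- matrix(FALSE, n, k)
    lp <- rep(qlogis(spec$background_event_rate), n) +
      male * log(spec$male_odds_multiplier)
    for (j in seq_len(k)) {
      exposed[, j] <- runif(n) < spec$drugs[[j]]$prevalence
      lp <- lp + exposed[, j] * log(spec$drugs[[j]]$event_odds_multiplier)
    }
    event <- runif(n) < plogis(lp)

    # drug rows: planted drugs for exposed cases + one background medicine
    # per case (names disjoint, so the base rows are exact-copy free)
    drug_parts <- vector("list", k + 1)
    for (j in seq_len(k)) {
      ds <- spec$drugs[[j]]
      idx <- which(exposed[, j])
      drug_parts[[j]] <- tibble::tibble(
        case_id = case_id[idx],
        drug_name = ds$name,
        involvement = sample(names(ds$involvement_distribution), length(idx),
                             replace = TRUE, prob = ds$involvement_distribution),
        route = sample(names(ds$route_distribution), length(idx),
                       replace = TRUE, prob = ds$route_distribution)
      )
    }
    drug_parts[[k + 1]] <- tibble::tibble(
      case_id = case_id,
      drug_name = sample(spec$background_pool, n, replace = TRUE),
      involvement = sample(INVOLVEMENT_LEVELS, n, replace = TRUE,
                           prob = c(0.6, 0.35, 0.05)),
      route = mask(sample(ROUTE_LEVELS, n, replace = TRUE,
                          prob = c(0.3, 0.6, 0.1)), 0.1)
    )
    drug_tbl <- dplyr::arrange(dplyr::bind_rows(drug_parts), .data$case_id,
                               .data$drug_name)

    # reaction rows: the case's primary term, plus an occasional second
    # background term (kept distinct so base rows stay exact-copy free)
    pool <- setdiff(BACKGROUND_EVENT_POOL, spec$event_term)
    primary <- ifelse(event, spec$event_term,
                      sample(pool, n, replace = TRUE))
    has_extra <- runif(n) < spec$extra_event_rate
    extra <- sample(pool, n, replace = TRUE)
    clash <- has_extra & extra == primary
    extra[clash] <- pool[match(extra[clash], pool) %% length(pool) + 1]
    reac_tbl <- dplyr::bind_rows(
      tibble::tibble(case_id = case_id, event_term = primary),
      tibble::tibble(case_id = case_id[has_extra],
                     event_term = extra[has_extra])
    ) |>
      dplyr::arrange(.data$case_id, .data$event_term)

    inject <- function(tbl, frac) {
      nd <- floor(frac * nrow(tbl))
      if (nd == 0) return(tbl)
      dplyr::bind_rows(tbl, tbl[sample.int(nrow(tbl), nd), ])
    }
    drug_tbl <- inject(drug_tbl, spec$duplicate_fraction)
    reac_tbl <- inject(reac_tbl, spec$duplicate_fraction)

    realized <- dplyr::bind_rows(lapply(seq_len(k), function(j) {
      ex <- exposed[, j]
      tibble::tibble(
        drug = spec$drugs[[j]]$name,
        prevalence = spec$drugs[[j]]$prevalence,
        event_odds_multiplier = spec$drugs[[j]]$event_odds_multiplier,
        n_exposed = sum(ex),
        a = sum(ex & event), b = sum(ex & !event),
        c = sum(!ex & event), d = sum(!ex & !event)
      )
    }))

    list(
      db = report_db(demo, drug_tbl, reac_tbl),
      truth = list(
        seed = seed,
        event_term = spec$event_term,
        background_event_rate = spec$background_event_rate,
        male_odds_multiplier = spec$male_odds_multiplier,
        n_events = sum(event),
        drugs = realized
      )
    )
  })
}

#' Write a report database as delimited text
#'
#' Writes `demo`, `drug` and `reac` tables (plus an optional ground-truth
#' manifest in YAML) into a directory, in the dialect [read_report_tables()]
#' reads back.
#'
#' @param db A [report_db()].
#' @param dir Output directory (created if needed).
#' @param delim Field delimiter (default `","`).
#' @param truth Optional ground-truth list from [generate_database()].
#' @return Named character vector of the written paths, invisibly.
#' @export
write_report_db <- function(db, dir, delim = ",", truth = NULL) {
  stopifnot(inherits(db, "report_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    demo = file.path(dir, "demo.csv"),
    drug = file.path(dir, "drug.csv"),
    reac = file.path(dir, "reac.csv")
  )
  readr::write_delim(db$demo, paths["demo"], delim = delim, progress = FALSE)
  readr::write_delim(db$drug, paths["drug"], delim = delim, progress = FALSE)
  readr::write_delim(db$reac, paths["reac"], delim = delim, progress = FALSE)
  if (!is.null(truth)) {
    manifest <- truth
    manifest$drugs <- lapply(seq_len(nrow(truth$drugs)), function(i) {
      as.list(truth$drugs[i, ])
    })
    yaml::write_yaml(manifest, file.path(dir, "ground_truth.yaml"))
    paths <- c(paths, manifest = file.path(dir, "ground_truth.yaml"))
  }
  invisible(paths)
}

#' Replay a printed 2x2 table as a report database
#'
#' Builds a database of exactly `a + b + c + d` single-drug, single-event
#' cases whose screen reproduces the given contingency table, so any printed
#' cross-tabulation can be pushed through the full pipeline.
#'
#' @param a,b,c,d Cell counts (exposed/event layout as in [contingency()]).
#' @param exposure_label Drug name of the exposed cases.
#' @param event_term Target event term.
#' @param other_drug,other_event Labels used for the unexposed/non-event
#'   cells.
#' @param route Optional administration route for the exposed cases' drug
#'   rows.
#' @return A [report_db()].
#' @export
fixture_from_counts <- function(a, b, c, d, exposure_label = "drug_x",
                                event_term = "hiccups",
                                other_drug = "other_medicine",
                                other_event = "other_event",
                                route = NA_character_) {
  layout <- tibble::tibble(
    n = c(a, b, c, d),
    drug_name = c(exposure_label, exposure_label, other_drug, other_drug),
    event_term = c(event_term, other_event, event_term, other_event),
    route = c(route, route, NA_character_, NA_character_)
  )
  fixture_from_layout(layout)
}

#' Build a report database from a record layout
#'
#' Each layout row stands for `n` cases, each carrying one drug row (name,
#' involvement, route as given) and one reaction row. Useful for replaying
#' printed tables that mix routes or involvement categories.
#'
#' @param layout Tibble with columns `n`, `drug_name`, `event_term` and
#'   optionally `route`, `involvement` (default `"suspected"`).
#' @return A [report_db()].
#' @export
fixture_from_layout <- function(layout) {
  layout <- tibble::as_tibble(layout)
  if (!all(c("n", "drug_name", "event_term") %in% names(layout))) {
    abort("`layout` needs columns n, drug_name, event_term.")
  }
  if (!all(vapply(layout$n, is_count, logical(1))) || sum(layout$n) < 1) {
    abort("`n` must be non-negative counts with a positive total.")
  }
  if (!"route" %in% names(layout)) layout$route <- NA_character_
  if (!"involvement" %in% names(layout)) layout$involvement <- "suspected"
  idx <- rep(seq_len(nrow(layout)), layout$n)
  total <- length(idx)
  case_id <- sprintf("F%07d", seq_len(total))
  demo <- tibble::tibble(
    case_id = case_id, sex = NA_character_, age_code = NA_character_,
    height_code = NA_character_, weight_code = NA_character_,
    report_year = NA_integer_
  )
  drug <- tibble::tibble(
    case_id = case_id,
    drug_name = layout$drug_name[idx],
    involvement = layout$involvement[idx],
    route = layout$route[idx]
  )
  reac <- tibble::tibble(case_id = case_id, event_term = layout$event_term[idx])
  report_db(demo, drug, reac)
}

#' Build an event-case co-treatment fixture
#'
#' All cases report the target event; drug rows plant the four co-treatment
#' cells (index drug and co-treatment class drug in all combinations, a
#' filler medicine for the "neither" cell), so
#' [cotreatment_cross_tab()] on the joined table returns exactly the given
#' counts.
#'
#' @param n_both,n_drug_a_only,n_class_b_only,n_neither Cell counts of unique
#'   event cases.
#' @param drug_a Index drug name.
#' @param class_b_drug Representative co-treatment class drug name.
#' @param event_term Target event term.
#' @param other_drug Filler drug for the "neither" cell.
#' @return A [report_db()].
#' @export
fixture_cotreatment <- function(n_both, n_drug_a_only, n_class_b_only,
                                n_neither, drug_a = "dexamethasone",
                                class_b_drug = "anticancer_agent",
                                event_term = "hiccups",
                                other_drug = "other_medicine") {
  counts <- c(n_both, n_drug_a_only, n_class_b_only, n_neither)
  if (!all(vapply(counts, is_count, logical(1))) || sum(counts) < 1) {
    abort("cell counts must be non-negative with a positive total.")
  }
  total <- sum(counts)
  case_id <- sprintf("F%07d", seq_len(total))
  group <- rep(c("both", "a_only", "b_only", "neither"), counts)
  drugs_of <- list(both = c(drug_a, class_b_drug), a_only = drug_a,
                   b_only = class_b_drug, neither = other_drug)
  drug <- dplyr::bind_rows(lapply(seq_len(total), function(i) {
    tibble::tibble(case_id = case_id[i], drug_name = drugs_of[[group[i]]],
                   involvement = "suspected", route = NA_character_)
  }))
  demo <- tibble::tibble(
    case_id = case_id, sex = NA_character_, age_code = NA_character_,
    height_code = NA_character_, weight_code = NA_character_,
    report_year = NA_integer_
  )
  reac <- tibble::tibble(case_id = case_id, event_term = event_term)
  report_db(demo, drug, reac)
}
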