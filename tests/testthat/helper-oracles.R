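# Independent oracles and tiny fixture builders shared across tests.

# Brute-force two-sided Fisher p: enumerate every table with the observed
# margins, probability from binomial coefficients (lchoose), minimum-
# likelihood summation. Independent of the package's dhyper-based path.
oracle_fisher_p <- function(a, b, c, d, tol = 1e-7) {
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  xs <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, xs) + lchoose(m2, k - xs) - lchoose(m1 + m2, k)
  pr <- exp(logp)
  obs <- pr[xs == a]
  min(1, sum(pr[pr <= obs * (1 + tol)]))
}

# Average-rank assignment built from sort order only (oracle for Spearman).
oracle_ranks <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

oracle_spearman <- function(x, y) {
  rx <- oracle_ranks(x)
  ry <- oracle_ranks(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Hand-computed Welch t-test p from first principles.
oracle_welch_p <- function(x, y) {
  vx <- sum((x - mean(x))^2) / (length(x) - 1)
  vy <- sum((y - mean(y))^2) / (length(y) - 1)
  se2 <- vx / length(x) + vy / length(y)
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / length(x))^2 / (length(x) - 1) +
                 (vy / length(y))^2 / (length(y) - 1))
  2 * stats::pt(-abs(t_stat), df)
}

# A small handcrafted database touching every categorical level.
tiny_db <- function() {
  demo <- tibble::tibble(
    case_id = c("c1", "c2", "c3", "c4"),
    sex = c("male", "female", "male", NA),
    age_code = c("50s", "60s", NA, "20s"),
    height_code = c("160-169", "150-159", "170-179", NA),
    weight_code = c("60-69", "40-49", NA, "50-59"),
    report_year = c(2010L, 2011L, 2012L, 2011L)
  )
  drug <- tibble::tibble(
    case_id = c("c1", "c1", "c2", "c3", "c4"),
    drug_name = c("dexamethasone", "cisplatin", "dexamethasone",
                  "medicine_01", "medicine_02"),
    involvement = c("suspected", "concomitant", "suspected", "suspected",
                    "interaction"),
    route = c("intravenous", "intravenous", "oral", NA, "other")
  )
  reac <- tibble::tibble(
    case_id = c("c1", "c2", "c2", "c3", "c4"),
    event_term = c("hiccups", "hiccups", "nausea", "rash", "nausea")
  )
  report_db(demo, drug, reac)
}

# Random small database for property-style loops.
random_db <- function(n_cases = 30, n_drugs = 4, n_events = 3) {
  demo <- tibble::tibble(
    case_id = sprintf("r%03d", seq_len(n_cases)),
    sex = sample(c("male", "female", NA), n_cases, replace = TRUE),
    age_code = sample(c("40s", "50s", NA), n_cases, replace = TRUE),
    height_code = NA_character_,
    weight_code = NA_character_,
    report_year = sample(2008:2012, n_cases, replace = TRUE)
  )
  drug <- tibble::tibble(
    case_id = sample(demo$case_id, n_cases * 2, replace = TRUE),
    drug_name = sample(sprintf("drug%02d", seq_len(n_drugs)), n_cases * 2,
                       replace = TRUE),
    involvement = sample(c("suspected", "concomitant", "interaction"),
                         n_cases * 2, replace = TRUE),
    route = sample(c("intravenous", "oral", "other", NA), n_cases * 2,
                   replace = TRUE)
  ) |> dplyr::distinct()
  reac <- tibble::tibble(
    case_id = sample(demo$case_id, n_cases, replace = TRUE),
    event_term = sample(c("hiccups", sprintf("event%02d", seq_len(n_events))),
                        n_cases, replace = TRUE)
  ) |> dplyr::distinct()
  report_db(demo, drug, reac)
}

write_tiny_csvs <- function(db, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  write_report_db(db, dir)
}
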