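#' Screen explanatory variables for internal correlation
#'
#' Pairwise-complete Spearman rank correlations between every pair of
#' explanatory columns; a pair with squared correlation above the threshold is
#' flagged as internally correlated and should not enter the model together.
#' Constant columns have undefined correlations, reported as `NA` with a
#' warning rather than silently.
#'
#' @param x Data frame or matrix of explanatory columns (numeric or 0/1
#'   indicators).
#' @param threshold Flagging threshold on rho squared (default 0.9).
#' @return Tibble `var1`, `var2`, `rho`, `rho2`, `flagged`, sorted by
#'   descending `rho2`; attribute `"any_flagged"`.
#' @export
collinearity_screen <- function(x, threshold = 0.9) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) abort("need at least two explanatory columns.")
  constant <- vapply(x, function(col) {
    v <- col[!is.na(col)]
    length(v) == 0 || all(v == v[1])
  }, logical(1))
  if (any(constant)) {
    warn(sprintf("constant column(s) with undefined correlation: %s",
                 paste(names(x)[constant], collapse = ", ")))
  }
  rho <- suppressWarnings(
    cor(data.matrix(x), method = "spearman", use = "pairwise.complete.obs")
  )
  pairs <- which(upper.tri(rho), arr.ind = TRUE)
  vals <- rho[pairs]
  out <- tibble::tibble(
    var1 = colnames(rho)[pairs[, 1]],
    var2 = colnames(rho)[pairs[, 2]],
    rho = vals,
    rho2 = vals^2,
    flagged = vals^2 > threshold
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$rho2))
  attr(out, "any_flagged") <- isTRUE(any(out$flagged))
  out
}

#' Select model predictors from the univariate drug screen
#'
#' Drugs enter the multivariate model when their univariate screen p-value is
#' below `alpha` and the event was reported for them more than `min_reports`
#' times; the patient covariates always enter.
#'
#' @param univariate_results Screen results from [screen_exposures()].
#' @param alpha Significance threshold (default 0.05).
#' @param min_reports Strict report-count threshold (default 3).
#' @param covariates Patient covariates to include (default sex, age, height,
#'   weight).
#' @return List with elements `drugs` and `covariates`.
#' @export
select_predictors <- function(univariate_results, alpha = 0.05,
                              min_reports = 3,
                              covariates = c("sex", "age", "height", "weight")) {
  kept <- filter_min_reports(univariate_results, min_reports)
  kept <- dplyr::filter(kept, .data$p_value < alpha)
  list(drugs = as.character(kept$exposure), covariates = covariates)
}

#' Build the case-level logistic model matrix
#'
#' One row per case with complete covariates: the event indicator (1 when any
#' of the case's records reports the event), a male indicator, decoded
#' age/height/weight, and one 0/1 indicator per selected drug (1 when any of
#' the case's suspected-medicine records names the drug). Cases missing any
#' covariate are dropped (complete-case analysis); the number dropped is
#' attached as attribute `"n_dropped_missing"`. `unit = "record"` keeps one
#' row per record instead.
#'
#' @param records Analysis records (the suspected-medicine table).
#' @param drugs Character vector of drug names to enter as indicators.
#' @param event Event predicate.
#' @param unit `"case"` (default) or `"record"`.
#' @param code_method Range-code decoding, see [numeric_from_code()].
#' @return Tibble with columns `event`, `male`, `age`, `height`, `weight` and
#'   one column per drug; attributes `n_dropped_missing`, `drug_terms`.
#' @export
build_model_matrix <- function(records, drugs, event,
                               unit = c("case", "record"),
                               code_method = c("lower", "midpoint")) {
  assert_records(records)
  unit <- match.arg(unit)
  code_method <- match.arg(code_method)
  ev <- eval_predicate(event, records, "event")

  base <- tibble::tibble(
    case_id = records$case_id,
    event = ev,
    male = ifelse(is.na(records$sex), NA, records$sex == "male"),
    age = numeric_from_code(records$age_code, code_method),
    height = numeric_from_code(records$height_code, code_method),
    weight = numeric_from_code(records$weight_code, code_method)
  )
  drug_flags <- lapply(drugs, function(dn) records$drug_name == dn)
  names(drug_flags) <- make.names(drugs, unique = TRUE)
  for (nm in names(drug_flags)) base[[nm]] <- drug_flags[[nm]]

  if (unit == "case") {
    base <- base |>
      dplyr::summarise(
        event = any(.data$event),
        male = dplyr::first(.data$male),
        age = dplyr::first(.data$age),
        height = dplyr::first(.data$height),
        weight = dplyr::first(.data$weight),
        dplyr::across(dplyr::all_of(names(drug_flags)), any),
        .by = "case_id"
      )
  }
  base$case_id <- NULL
  complete <- complete.cases(base)
  out <- base[complete, ]
  out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.logical), as.integer))
  if (sum(out$event) == 0 || sum(out$event) == nrow(out)) {
    abort("model matrix needs at least one event and one non-event row.")
  }
  attr(out, "n_dropped_missing") <- sum(!complete)
  attr(out, "drug_terms") <- names(drug_flags)
  out
}

#' Fit the multiple logistic regression
#'
#' Maximum-likelihood logistic regression of the event indicator on all other
#' columns of the model matrix (intercept included), fitted by iteratively
#' reweighted least squares (relative deviance tolerance 1e-8, at most 100
#' iterations); non-convergence is an error, never silent. Inference is Wald:
#' per-term z tests and confidence intervals on the log-odds scale,
#' exponentiated to odds ratios. Complete separation, which sends a
#' coefficient and its standard error to infinity, is detected and reported
#' as an error naming the separating term; `method = "firth"` fits the
#' Jeffreys-penalized likelihood instead, which remains finite under
#' separation.
#'
#' @param x Model matrix from [build_model_matrix()] (column `event` plus
#'   predictors).
#' @param level Confidence level (default 0.95).
#' @param alpha Significance threshold for the `significant` flag (default
#'   0.05).
#' @param method `"mle"` (default) or `"firth"`.
#' @return Tibble of class `logistic_fit` rows: `term`, `coefficient`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `significant`; predictors
#'   sorted by descending odds ratio, intercept last. Attributes:
#'   `n`, `n_events`, `converged`, `log_likelihood`.
#' @export
fit_logistic <- function(x, level = 0.95, alpha = 0.05,
                         method = c("mle", "firth")) {
  method <- match.arg(method)
  x <- as.data.frame(x)
  if (!"event" %in% names(x)) abort("model matrix must contain `event`.")
  if (anyNA(x)) abort("model matrix must be complete (no missing values).")

  if (method == "firth") {
    fit <- firth_logistic(x)
    est <- fit$coef
    se <- fit$se
    ll <- fit$log_likelihood
    converged <- fit$converged
    if (!converged) abort("Firth logistic fit did not converge.")
  } else {
    fit <- suppressWarnings(
      glm(event ~ ., data = x, family = binomial(),
          control = glm.control(epsilon = 1e-8, maxit = 100))
    )
    if (!fit$converged) {
      abort("logistic fit did not converge within 100 IRLS iterations.")
    }
    est <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    ll <- as.numeric(stats::logLik(fit))
    converged <- TRUE
    # diverging coefficient + exploding SE is the separation signature
    sep <- names(est)[abs(est) > 15 & se > 200]
    sep <- setdiff(sep, "(Intercept)")
    if (length(sep)) {
      abort(sprintf(
        "complete separation detected for term(s): %s (coefficient diverges); consider method = \"firth\".",
        paste(sep, collapse = ", ")
      ), class = "rorscreen_separation_error")
    }
  }

  z <- qnorm(1 - (1 - level) / 2)
  p <- 2 * pnorm(-abs(est / se))
  out <- tibble::tibble(
    term = names(est),
    coefficient = unname(est),
    odds_ratio = exp(unname(est)),
    ci_low = exp(unname(est) - z * se),
    ci_high = exp(unname(est) + z * se),
    p_value = unname(p)
  )
  out$significant <- out$p_value < alpha & (out$ci_low > 1 | out$ci_high < 1)
  is_int <- out$term == "(Intercept)"
  out <- dplyr::bind_rows(
    dplyr::arrange(out[!is_int, ], dplyr::desc(.data$odds_ratio)),
    out[is_int, ]
  )
  attr(out, "n") <- nrow(x)
  attr(out, "n_events") <- sum(x$event)
  attr(out, "converged") <- converged
  attr(out, "log_likelihood") <- ll
  class(out) <- c("logistic_fit", class(out))
  out
}

# Jeffreys-penalized (Firth) logistic regression by Newton iteration on the
# modified score U* = X'(y - p + h (1/2 - p)), h the hat diagonals.
firth_logistic <- function(x, max_iter = 100, tol = 1e-8) {
  y <- x$event
  X <- cbind(`(Intercept)` = 1, data.matrix(x[setdiff(names(x), "event")]))
  beta <- numeric(ncol(X))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), .Machine$double.eps)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    info_inv <- solve(info)
    h <- rowSums((XW %*% info_inv) * XW)
    u <- drop(crossprod(X, y - p + h * (0.5 - p)))
    step <- drop(info_inv %*% u)
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  w <- pmax(p * (1 - p), .Machine$double.eps)
  info <- crossprod(X * sqrt(w))
  ll <- sum(y * log(p) + (1 - y) * log1p(-p)) +
    0.5 * determinant(info, logarithm = TRUE)$modulus
  list(coef = setNames(beta, colnames(X)),
       se = sqrt(diag(solve(info))),
       log_likelihood = as.numeric(ll),
       converged = converged)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d (%d events), logLik = %.2f\n",
              attr(x, "n"), attr(x, "n_events"), attr(x, "log_likelihood")))
  NextMethod()
}
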