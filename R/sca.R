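#' Enumerate the specification space
#'
#' A specification is one regression model: age predicting one outcome,
#' adjusted for one subset of the covariate pool (the empty subset
#' included).  Every (outcome, subset) combination appears exactly once, in
#' a deterministic canonical order (outcomes in the given order; subsets in
#' binary-counter order over the pool).
#'
#' @param outcomes Character vector of outcome column names (default the 24
#'   canonical labels).
#' @param covariate_pool Character vector of optional covariates (default
#'   the five study covariates).
#' @return A tibble with one row per specification: `spec_id`, `outcome`, a
#'   `covariates` list-column, `n_covariates`, and one logical flag column
#'   per pool member.
#' @examples
#' nrow(enumerate_specifications())  # 24 * 2^5 = 768
#' @export
enumerate_specifications <- function(outcomes = outcome_labels(),
                                     covariate_pool = covariate_labels()) {
  if (anyDuplicated(outcomes) || anyDuplicated(covariate_pool)) {
    abort("outcome and covariate labels must be unique",
          class = "agespec_config_error")
  }
  k <- length(covariate_pool)
  subsets <- purrr::map(seq_len(2^k) - 1L, function(s) {
    covariate_pool[bitwAnd(s, bitwShiftL(1L, seq_len(k) - 1L)) > 0L]
  })
  grid <- tidyr::expand_grid(outcome = outcomes, covariates = subsets)
  out <- tibble::tibble(
    spec_id = seq_len(nrow(grid)),
    outcome = grid$outcome,
    covariates = grid$covariates,
    n_covariates = lengths(grid$covariates)
  )
  for (cv in covariate_pool) {
    out[[cv]] <- purrr::map_lgl(grid$covariates, function(s) cv %in% s)
  }
  out
}

# design pieces for one specification: complete-case rows, standardized
# outcome/age, covariate matrix with intercept (binary gender stays 0/1)
prep_spec <- function(data, outcome, covariates, standardize_covariates = TRUE) {
  cols <- c("age", outcome, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")),
          class = "agespec_data_error")
  }
  rows <- which(complete.cases(data[cols]))
  n <- length(rows)
  if (n < length(covariates) + 3L) {
    abort("too few complete rows to fit this specification",
          class = "agespec_data_error")
  }
  y <- zscore(data[[outcome]][rows])
  a <- zscore(data$age[rows])
  Z <- matrix(1, nrow = n, ncol = 1L + length(covariates))
  colnames(Z) <- c("(Intercept)", covariates)
  for (cv in covariates) {
    x <- data[[cv]][rows]
    binary <- length(unique(x)) <= 2L
    Z[, cv] <- if (standardize_covariates && !binary) zscore(x) else x
  }
  if (qr(cbind(Z, a))$rank < ncol(Z) + 1L) {
    abort("singular fit: predictors are collinear", class = "agespec_singular")
  }
  list(rows = rows, n = n, y = y, a = a, qz = qr(Z), m = ncol(Z))
}

# partitioned OLS: age coefficient, inference and fit statistics after
# projecting out the covariate block (equivalent to the full regression)
ols_age <- function(y, a, qz, m, alpha = 0.05) {
  n <- length(y)
  ystar <- qr.resid(qz, y)
  astar <- qr.resid(qz, a)
  saa <- sum(astar^2)
  if (saa < 1e-12) {
    abort("singular fit: age is collinear with the covariates",
          class = "agespec_singular")
  }
  beta <- sum(astar * ystar) / saa
  rss <- max(0, sum(ystar^2) - beta^2 * saa)
  df <- n - m - 1L
  se <- sqrt(rss / df / saa)
  t <- beta / se
  p <- 2 * pt(-abs(t), df)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  half <- qt(1 - alpha / 2, df) * se
  list(beta = beta, se = se, t = t, p = p, df = df,
       ci_low = beta - half, ci_high = beta + half,
       adj_r2 = 1 - (1 - r2) * (n - 1) / df)
}

classify_effect <- function(p, beta, alpha) {
  dplyr::case_when(
    p <= alpha & beta > 0 ~ "positive",
    p <= alpha & beta < 0 ~ "negative",
    .default = "null"
  )
}

#' Fit one specification
#'
#' Ordinary least squares of the standardized outcome on standardized age
#' plus the requested covariates, over the rows complete for the model's
#' variables.  Continuous covariates are z-scored on those rows; a binary
#' covariate (gender) enters as coded.  The reported `beta_age` is the
#' standardized age coefficient, with a two-sided p-value on
#' `n - k - 2` residual degrees of freedom (k covariates, intercept, age).
#'
#' @param data A cohort tibble (see [generate_cohort()]).
#' @param outcome Outcome column name.
#' @param covariates Character vector of covariate column names (possibly
#'   empty).
#' @param alpha Two-sided significance level used for the effect class and
#'   the confidence interval (default 0.05; `p <= alpha` is significant).
#' @param standardize_covariates Should continuous covariates be z-scored
#'   (default `TRUE`)?
#' @return A one-row tibble: `outcome`, `covariates` (list-column),
#'   `beta_age`, `se`, `ci_low`, `ci_high`, `p_value`, `n_used`, `df`,
#'   `adj_r2`, `class`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 100, seed = 1))
#' fit_specification(cohort, "bart_adjpumps_all", c("gender", "numeracy"))
#' @export
fit_specification <- function(data, outcome, covariates = character(),
                              alpha = 0.05, standardize_covariates = TRUE) {
  pr <- prep_spec(data, outcome, covariates, standardize_covariates)
  fit <- ols_age(pr$y, pr$a, pr$qz, pr$m, alpha)
  tibble::tibble(
    outcome = outcome, covariates = list(covariates),
    beta_age = fit$beta, se = fit$se,
    ci_low = fit$ci_low, ci_high = fit$ci_high,
    p_value = fit$p, n_used = pr$n, df = fit$df, adj_r2 = fit$adj_r2,
    class = classify_effect(fit$p, fit$beta, alpha)
  )
}

#' Run a full specification-curve analysis
#'
#' Fits every specification in the (outcome x covariate-subset) space and
#' summarizes the curve: each fit is classified as positive
#' (`p <= alpha`, `beta > 0`), negative (`p <= alpha`, `beta < 0`) or null,
#' and the fits are ordered by effect size for curve plotting (ties broken
#' by canonical specification order).
#'
#' @inheritParams enumerate_specifications
#' @inheritParams fit_specification
#' @return An object of class `sca`: a list with `fits` (tibble of
#'   specification fits, sorted by `beta_age`, with `curve_rank`), `alpha`,
#'   `n_specifications`, `n_positive`, `n_negative`, `n_null`,
#'   `median_beta`, `outcomes`, `covariate_pool`.  Use [tidy()],
#'   [glance()], [sca_summary()], [autoplot()].
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 100, seed = 1))
#' curve <- run_sca(cohort, outcomes = outcome_labels()[1:2],
#'                  covariate_pool = c("gender", "numeracy"))
#' glance(curve)
#' @export
run_sca <- function(data, outcomes = outcome_labels(),
                    covariate_pool = covariate_labels(), alpha = 0.05,
                    standardize_covariates = TRUE) {
  specs <- enumerate_specifications(outcomes, covariate_pool)
  fits <- purrr::map(seq_len(nrow(specs)), function(i) {
    fit_specification(data, specs$outcome[i], specs$covariates[[i]],
                      alpha = alpha,
                      standardize_covariates = standardize_covariates)
  })
  fits <- dplyr::bind_cols(
    specs[c("spec_id", covariate_pool)],
    dplyr::bind_rows(fits)
  )
  fits <- fits[order(fits$beta_age, fits$spec_id), ]
  fits$curve_rank <- seq_len(nrow(fits))
  counts <- table(factor(fits$class, levels = c("positive", "negative", "null")))
  structure(
    list(
      fits = fits, alpha = alpha,
      n_specifications = nrow(fits),
      n_positive = unname(counts[["positive"]]),
      n_negative = unname(counts[["negative"]]),
      n_null = unname(counts[["null"]]),
      median_beta = median(fits$beta_age),
      outcomes = outcomes, covariate_pool = covariate_pool
    ),
    class = "sca"
  )
}

#' Tally specification classes with percentages
#'
#' Turns counts of positive, negative and null effects into the summary
#' table reported for a specification curve, with percentages of the total
#' rounded to two decimals.
#'
#' @param n_positive,n_negative,n_null Non-negative integer counts.
#' @return A tibble with columns `effect`, `n`, `pct`.
#' @examples
#' tally_percentages(58, 86, 624)
#' @export
tally_percentages <- function(n_positive, n_negative, n_null) {
  n <- c(positive = n_positive, negative = n_negative, null = n_null)
  total <- sum(n)
  tibble::tibble(
    effect = names(n),
    n = unname(n),
    pct = round(100 * unname(n) / total, 2)
  )
}

#' Summary table of a specification curve
#'
#' @param x An `sca` object from [run_sca()].
#' @return The [tally_percentages()] tibble for the curve, with the median
#'   age effect attached as attribute `median_beta`.
#' @export
sca_summary <- function(x) {
  stopifnot(inherits(x, "sca"))
  out <- tally_percentages(x$n_positive, x$n_negative, x$n_null)
  attr(out, "median_beta") <- x$median_beta
  out
}

#' @export
print.sca <- function(x, ...) {
  cat("Specification curve analysis\n")
  cat(sprintf("  %d specifications (%d outcomes x %d covariate subsets), alpha = %g\n",
              x$n_specifications, length(x$outcomes),
              2^length(x$covariate_pool), x$alpha))
  tal <- sca_summary(x)
  for (i in seq_len(nrow(tal))) {
    cat(sprintf("  %-8s %5d (%6.2f%%)\n", tal$effect[i], tal$n[i], tal$pct[i]))
  }
  cat(sprintf("  median age effect: %.4g\n", x$median_beta))
  invisible(x)
}

#' @rdname run_sca
#' @param x An `sca` object.
#' @param ... Unused.
#' @export
tidy.sca <- function(x, ...) x$fits

#' @rdname run_sca
#' @export
glance.sca <- function(x, ...) {
  tibble::tibble(
    n_specifications = x$n_specifications,
    n_positive = x$n_positive, n_negative = x$n_negative, n_null = x$n_null,
    pct_positive = round(100 * x$n_positive / x$n_specifications, 2),
    pct_negative = round(100 * x$n_negative / x$n_specifications, 2),
    pct_null = round(100 * x$n_null / x$n_specifications, 2),
    n_significant = x$n_positive + x$n_negative,
    median_beta = x$median_beta,
    alpha = x$alpha
  )
}

#' Specification curve plot
#'
#' The ordered standardized age effects with their confidence intervals,
#' colored by effect class.
#'
#' @param object An `sca` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sca <- function(object, ...) {
  fits <- object$fits
  ggplot2::ggplot(fits, ggplot2::aes(x = .data$curve_rank, y = .data$beta_age,
                                     colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$ci_low,
                                         ymax = .data$ci_high),
                            alpha = 0.4) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_manual(values = c(positive = "#2166ac",
                                            negative = "#e08214",
                                            null = "grey55")) +
    ggplot2::labs(x = "specification (ordered by effect size)",
                  y = "standardized age effect",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
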