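#' Resample the age variable
#'
#' Breaks the age-outcome association while leaving everything else (values,
#' column order, missingness pattern) untouched: the age column is replaced
#' by a draw from itself, with replacement by default (set
#' `replace = FALSE` for a classical permutation shuffle).
#'
#' @param data A cohort tibble with an `age` column.
#' @param seed Integer seed or `NULL`.
#' @param replace Sample with replacement (default `TRUE`)?
#' @return The tibble with its `age` column resampled.
#' @export
resample_age <- function(data, seed = NULL, replace = TRUE) {
  stopifnot(nrow(data) > 0L)
  with_seed_or_rng(seed, {
    data$age <- sample(data$age, size = nrow(data), replace = replace)
    data
  })
}

# per-spec precomputation for repeated significance counting: everything
# that does not involve age (covariate projector, residualized outcome)
sca_precompute <- function(data, specs, alpha = 0.05,
                           standardize_covariates = TRUE) {
  purrr::map(seq_len(nrow(specs)), function(i) {
    pr <- prep_spec(data, specs$outcome[i], specs$covariates[[i]],
                    standardize_covariates)
    ystar <- qr.resid(pr$qz, pr$y)
    list(rows = pr$rows, qz = pr$qz, m = pr$m, n = pr$n,
         ystar = ystar, ssy = sum(ystar^2))
  })
}

# count specifications significant at alpha for a given age vector; the
# t statistic is invariant to linear rescaling of age, so no z-scoring is
# needed here
count_significant <- function(pre, age, alpha) {
  sig <- 0L
  for (sp in pre) {
    a <- age[sp$rows]
    astar <- qr.resid(sp$qz, a)
    saa <- sum(astar^2)
    if (saa < 1e-12) next
    beta <- sum(astar * sp$ystar) / saa
    rss <- max(0, sp$ssy - beta^2 * saa)
    df <- sp$n - sp$m - 1L
    t2 <- beta^2 * saa * df / rss
    p <- 2 * pt(-sqrt(t2), df)
    if (p <= alpha) sig <- sig + 1L
  }
  sig
}

#' Global permutation test of a specification curve
#'
#' Tests whether the observed number of significant specifications exceeds
#' what a null world would produce.  Null datasets are built by resampling
#' the age variable (with replacement by default), the identical
#' specification-curve analysis is run on each, and the global p-value is
#' the fraction of null datasets yielding strictly more significant
#' specifications than observed (set `exceedance = "weak"` for
#' greater-or-equal; set `add_one = TRUE` for the (count + 1)/(N + 1)
#' convention).
#'
#' Per-resample seeds are derived from the master seed up front, so results
#' do not depend on execution order.
#'
#' @inheritParams run_sca
#' @param n_resamples Number of null datasets (default 500).
#' @param seed Integer master seed or `NULL`.
#' @param exceedance `"strict"` (default; strictly greater) or `"weak"`.
#' @param replace Resample age with replacement (default `TRUE`)?
#' @param add_one Apply the +1 small-sample correction to the p-value
#'   (default `FALSE`, reporting the plain ratio)?
#' @return An object of class `sca_perm`: `observed` (the [run_sca()]
#'   object for the unresampled data), `observed_significant`,
#'   `null_counts` (integer vector of length `n_resamples`),
#'   `exceedance_count`, `p_global`, plus the test settings.
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 80, seed = 1))
#' gt <- global_test(cohort, outcomes = outcome_labels()[1:3],
#'                   covariate_pool = c("gender", "numeracy"),
#'                   n_resamples = 50, seed = 2)
#' glance(gt)
#' @export
global_test <- function(data, outcomes = outcome_labels(),
                        covariate_pool = covariate_labels(), alpha = 0.05,
                        n_resamples = 500L, seed = NULL,
                        exceedance = c("strict", "weak"), replace = TRUE,
                        add_one = FALSE, standardize_covariates = TRUE) {
  exceedance <- match.arg(exceedance)
  if (n_resamples < 1L) {
    abort("`n_resamples` must be at least 1", class = "agespec_config_error")
  }
  observed <- run_sca(data, outcomes, covariate_pool, alpha,
                      standardize_covariates)
  observed_significant <- observed$n_positive + observed$n_negative

  specs <- enumerate_specifications(outcomes, covariate_pool)
  pre <- sca_precompute(data, specs, alpha, standardize_covariates)
  sub_seeds <- derive_seeds(seed, n_resamples)
  null_counts <- vapply(seq_len(n_resamples), function(i) {
    age <- withr::with_seed(sub_seeds[i],
                            sample(data$age, nrow(data), replace = replace))
    count_significant(pre, age, alpha)
  }, integer(1))

  exceedance_count <- if (exceedance == "strict") {
    sum(null_counts > observed_significant)
  } else {
    sum(null_counts >= observed_significant)
  }
  p_global <- if (add_one) {
    (exceedance_count + 1) / (n_resamples + 1)
  } else {
    exceedance_count / n_resamples
  }
  structure(
    list(
      observed = observed, observed_significant = observed_significant,
      null_counts = null_counts, exceedance_count = exceedance_count,
      p_global = p_global, n_resamples = as.integer(n_resamples),
      alpha = alpha, exceedance = exceedance, replace = replace,
      add_one = add_one, seed = seed
    ),
    class = "sca_perm"
  )
}

#' @export
print.sca_perm <- function(x, ...) {
  cat("Global permutation test of the specification curve\n")
  cat(sprintf("  observed significant specifications: %d of %d\n",
              x$observed_significant, x$observed$n_specifications))
  cat(sprintf("  resamples with %s significant count: %d of %d\n",
              if (x$exceedance == "strict") "a larger" else "at least the",
              x$exceedance_count, x$n_resamples))
  p_txt <- if (x$exceedance_count == 0L && !x$add_one) {
    sprintf("< %g", 1 / x$n_resamples)
  } else {
    sprintf("%g", x$p_global)
  }
  cat(sprintf("  global p value: %s\n", p_txt))
  invisible(x)
}

#' @rdname global_test
#' @param x An `sca_perm` object.
#' @param ... Unused.
#' @export
tidy.sca_perm <- function(x, ...) {
  tibble::tibble(resample = seq_along(x$null_counts),
                 n_significant = x$null_counts)
}

#' @rdname global_test
#' @export
glance.sca_perm <- function(x, ...) {
  tibble::tibble(
    n_resamples = x$n_resamples,
    observed_significant = x$observed_significant,
    exceedance_count = x$exceedance_count,
    p_global = x$p_global,
    alpha = x$alpha,
    exceedance = x$exceedance,
    replace = x$replace
  )
}

#' Null-distribution plot for the global test
#'
#' Histogram of the number of significant specifications across resampled
#' datasets, with the observed count marked.
#'
#' @param object An `sca_perm` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sca_perm <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$n_significant)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed_significant,
                        colour = "#b2182b", linewidth = 0.8) +
    ggplot2::labs(x = "significant specifications per resampled dataset",
                  y = "resamples") +
    ggplot2::theme_minimal()
}
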