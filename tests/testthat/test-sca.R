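test_that("the specification space is the full outcome x subset product", {
  expect_identical(nrow(enumerate_specifications()), 768L)
  expect_identical(nrow(enumerate_specifications("y", character(0))), 1L)
  expect_identical(nrow(enumerate_specifications(c("y1", "y2"),
                                                 c("a", "b", "c"))), 16L)
  specs <- enumerate_specifications(c("y1", "y2"), c("a", "b", "c"))
  key <- paste(specs$outcome,
               vapply(specs$covariates, paste, "", collapse = "+"))
  expect_identical(anyDuplicated(key), 0L)
  # deterministic canonical order
  expect_identical(specs, enumerate_specifications(c("y1", "y2"),
                                                   c("a", "b", "c")))
  expect_error(enumerate_specifications(c("y", "y")),
               class = "agespec_config_error")
})

test_that("an outcome equal to age fits perfectly", {
  co <- tiny_cohort(n = 100, seed = 41)
  co$bart_adjpumps_all <- co$age
  f <- fit_specification(co, "bart_adjpumps_all")
  expect_equal(f$beta_age, 1, tolerance = 1e-12)
  expect_lt(f$p_value, 1e-12)
})

test_that("without covariates the standardized slope is the Pearson correlation", {
  co <- tiny_cohort(n = 150, seed = 42)
  for (lab in outcome_labels()[c(1, 4, 10, 24)]) {
    f <- fit_specification(co, lab)
    expect_equal(f$beta_age, cor(co$age, co[[lab]]), tolerance = 1e-10)
  }
})

test_that("every fit matches the independent normal-equations oracle", {
  co <- tiny_cohort(n = 90, seed = 43)
  cases <- list(
    character(0), "gender", c("education", "income"),
    c("gender", "numeracy", "working_memory"), covariate_labels()
  )
  for (covs in cases) {
    f <- fit_specification(co, "dd_immediacy_nacc", covs)
    o <- oracle_age_fit(co, "dd_immediacy_nacc", covs)
    expect_equal(f$beta_age, o$beta, tolerance = 1e-8)
    expect_equal(f$se, o$se, tolerance = 1e-8)
    expect_equal(f$p_value, o$p, tolerance = 1e-8)
    expect_identical(f$n_used, o$n)
    expect_identical(f$df, o$df)
  }
})

test_that("fits are invariant to row order, covariate order and outcome scaling", {
  co <- tiny_cohort(n = 110, seed = 44)
  covs <- c("income", "gender", "numeracy")
  base <- fit_specification(co, "bart_parametric_mpfc", covs)

  shuffled <- co[sample(nrow(co)), ]
  f2 <- fit_specification(shuffled, "bart_parametric_mpfc", covs)
  expect_equal(f2$beta_age, base$beta_age, tolerance = 1e-10)

  f3 <- fit_specification(co, "bart_parametric_mpfc", rev(covs))
  expect_equal(f3$beta_age, base$beta_age, tolerance = 1e-10)
  expect_equal(f3$p_value, base$p_value, tolerance = 1e-10)

  rescaled <- co
  rescaled$bart_parametric_mpfc <- 1000 * rescaled$bart_parametric_mpfc
  f4 <- fit_specification(rescaled, "bart_parametric_mpfc", covs)
  expect_equal(f4$beta_age, base$beta_age, tolerance = 1e-10)
})

test_that("income specifications use only income-complete rows", {
  co <- tiny_cohort(n = 175, seed = 45)
  with_income <- fit_specification(co, "bart_adjpumps_all", "income")
  without <- fit_specification(co, "bart_adjpumps_all", "gender")
  expect_identical(with_income$n_used, 168L)
  expect_identical(without$n_used, 175L)
})

test_that("degenerate designs are reported as singular or data errors", {
  co <- tiny_cohort(n = 60, seed = 46)
  co$education <- 3L  # constant covariate
  expect_error(fit_specification(co, "bart_adjpumps_all", "education"),
               class = "agespec_singular")
  expect_error(fit_specification(co[1:3, ], "bart_adjpumps_all",
                                 covariate_labels()),
               class = "agespec_data_error")
  expect_error(fit_specification(co, "not_a_column"),
               class = "agespec_data_error")
})

test_that("the curve classification is an exhaustive, exclusive trichotomy", {
  co <- tiny_cohort(n = 140, seed = 47)
  curve <- run_sca(co, outcomes = outcome_labels()[1:4],
                   covariate_pool = c("gender", "income", "numeracy"))
  fits <- tidy(curve)
  expect_identical(nrow(fits), 32L)
  expect_true(all(fits$class %in% c("positive", "negative", "null")))
  expect_identical(curve$n_positive + curve$n_negative + curve$n_null,
                   curve$n_specifications)
  recls <- ifelse(fits$p_value <= curve$alpha & fits$beta_age > 0, "positive",
                  ifelse(fits$p_value <= curve$alpha & fits$beta_age < 0,
                         "negative", "null"))
  expect_identical(fits$class, recls)
  # curve is sorted by effect size and the median re-aggregates
  expect_true(!is.unsorted(fits$beta_age))
  expect_equal(curve$median_beta, median(fits$beta_age))
})

test_that("an outcome that is a copy of age turns all its specifications positive", {
  co <- tiny_cohort(n = 120, seed = 48)
  co$dd_prop_immediate <- co$age + rnorm(120, 0, 1e-8)
  curve <- run_sca(co, outcomes = c("dd_prop_immediate", "bart_adjpumps_all"))
  fits <- tidy(curve)
  on_copy <- fits[fits$outcome == "dd_prop_immediate", ]
  expect_identical(nrow(on_copy), 32L)
  expect_true(all(on_copy$class == "positive"))
})

test_that("false-positive fractions on null cohorts stay in a loose band", {
  # specs on the same outcome are strongly correlated, so per-run fractions
  # are lumpy; only a loose band is asserted for a full-width curve and the
  # mean rate over replicates -- formal calibration is the permutation
  # module's job
  co <- generate_cohort(cohort_config(n = 175, seed = 299))
  full <- run_sca(co)
  expect_lte((full$n_positive + full$n_negative) / full$n_specifications,
             0.15)
  rates <- vapply(1:30, function(i) {
    co <- generate_cohort(cohort_config(n = 175, seed = 300 + i))
    curve <- run_sca(co, outcomes = outcome_labels()[c(1, 4, 9, 17)],
                     covariate_pool = c("gender", "numeracy"))
    (curve$n_positive + curve$n_negative) / curve$n_specifications
  }, numeric(1))
  expect_lt(mean(rates), 0.10)
})

test_that("summary percentages reproduce printed-tally arithmetic", {
  tal <- tally_percentages(58, 86, 624)
  expect_equal(tal$pct, c(7.55, 11.20, 81.25))
  expect_equal(tally_percentages(0, 0, 10)$pct, c(0, 0, 100))
  expect_lt(abs(sum(tal$pct) - 100), 0.02)

  co <- tiny_cohort(n = 100, seed = 49)
  curve <- run_sca(co, outcomes = outcome_labels()[1:2],
                   covariate_pool = c("gender", "income"))
  tal <- sca_summary(curve)
  expect_identical(sum(tal$n), curve$n_specifications)
  expect_equal(attr(tal, "median_beta"), curve$median_beta)
  g <- glance(curve)
  expect_identical(g$n_significant, curve$n_positive + curve$n_negative)
})

test_that("parameter recovery: the median of an outcome's specs tracks the injected slope", {
  for (beta in c(0.2, 0.4)) {
    ae <- setNames(beta, "bart_rewardVsControl_insula")
    co <- generate_cohort(cohort_config(n = 2000, age_effects = ae,
                                        n_income_missing = 80,
                                        seed = round(1000 * beta)))
    curve <- run_sca(co, outcomes = "bart_rewardVsControl_insula")
    expect_lt(abs(median(tidy(curve)$beta_age) - beta), 3 / sqrt(2000))
  }
})

test_that("the specification curve plot is a ggplot with one point per fit", {
  co <- tiny_cohort(n = 80, seed = 50)
  curve <- run_sca(co, outcomes = outcome_labels()[1:2],
                   covariate_pool = c("gender", "numeracy"))
  p <- autoplot(curve)
  expect_s3_class(p, "ggplot")
  expect_identical(nrow(p$data), curve$n_specifications)
})
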