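#' Configuration for synthetic cohort generation
#'
#' Bundles and validates the knobs of the synthetic cohort generator.
#' Ground-truth effects are expressed as standardized slopes: an
#' `age_effects` entry of 0.4 for an outcome means the outcome gains
#' `0.4 * z(age)`; residuals are scaled so every outcome has (approximately)
#' unit marginal variance, so injected slopes are recovered directly as
#' standardized regression coefficients.
#'
#' @param n Number of participants (default 175, the study's effective
#'   sample).
#' @param age_range Numeric length-2, the closed age range sampled uniformly
#'   (default `c(16.15, 81.38)`).
#' @param age_effects Named numeric vector of standardized age slopes, names
#'   among [outcome_labels()]. Unnamed outcomes get slope 0.
#' @param covariate_effects Named list: one element per covariate (names among
#'   [covariate_labels()]), each a named numeric vector of standardized slopes
#'   on outcomes.
#' @param within_block_correlation Equicorrelation in `[0, 1)` applied to
#'   residuals of outcomes sharing a contrast block (see [outcome_blocks()]).
#'   Default 0.6, emulating the strong within-contrast correlation of
#'   neural markers.
#' @param noise_sd Positive multiplier on the residual scale (default 1, which
#'   targets unit outcome variance).
#' @param n_income_missing Number of participants with missing income,
#'   masked completely at random (default 7).
#' @param prop_female Probability that `gender == 1` (default 0.5314).
#' @param seed Integer seed or `NULL`.
#' @return A list of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n = 175L,
                          age_range = c(16.15, 81.38),
                          age_effects = NULL,
                          covariate_effects = NULL,
                          within_block_correlation = 0.6,
                          noise_sd = 1,
                          n_income_missing = 7L,
                          prop_female = 0.5314,
                          seed = NULL) {
  labels <- outcome_labels()
  covs <- covariate_labels()
  stopifnot(
    length(n) == 1L, n >= 1L,
    length(age_range) == 2L, age_range[1] < age_range[2],
    length(noise_sd) == 1L, noise_sd > 0,
    n_income_missing >= 0L, n_income_missing <= n,
    prop_female >= 0, prop_female <= 1
  )
  if (!(length(within_block_correlation) == 1L &&
        within_block_correlation >= 0 && within_block_correlation < 1)) {
    abort("`within_block_correlation` must be a single value in [0, 1)",
          class = "agespec_config_error")
  }
  age_effects <- age_effects %||% stats::setNames(numeric(0), character(0))
  if (length(age_effects) && !all(names(age_effects) %in% labels)) {
    abort("`age_effects` names must be canonical outcome labels",
          class = "agespec_config_error")
  }
  covariate_effects <- covariate_effects %||% list()
  if (length(covariate_effects)) {
    if (!all(names(covariate_effects) %in% covs)) {
      abort("`covariate_effects` names must be covariate labels",
            class = "agespec_config_error")
    }
    ok <- vapply(covariate_effects,
                 function(e) all(names(e) %in% labels), logical(1))
    if (!all(ok)) {
      abort("`covariate_effects` entries must name canonical outcomes",
            class = "agespec_config_error")
    }
  }
  structure(
    list(
      n = as.integer(n), age_range = age_range,
      age_effects = age_effects, covariate_effects = covariate_effects,
      within_block_correlation = within_block_correlation,
      noise_sd = noise_sd, n_income_missing = as.integer(n_income_missing),
      prop_female = prop_female, seed = seed
    ),
    class = "cohort_config"
  )
}

# full 5 x 24 slope matrix from the sparse config representation
effect_matrix <- function(config) {
  labels <- outcome_labels()
  covs <- covariate_labels()
  eff <- matrix(0, nrow = length(covs) + 1L, ncol = length(labels),
                dimnames = list(c("age", covs), labels))
  eff["age", names(config$age_effects)] <- config$age_effects
  for (cv in names(config$covariate_effects)) {
    e <- config$covariate_effects[[cv]]
    eff[cv, names(e)] <- e
  }
  eff
}

# block-equicorrelation residual matrix for the 24 outcomes
residual_correlation <- function(rho) {
  blocks <- outcome_blocks()
  same <- outer(blocks$block, blocks$block, "==")
  r <- ifelse(same, rho, 0)
  diag(r) <- 1
  dimnames(r) <- list(blocks$outcome, blocks$outcome)
  r
}

#' Generate a synthetic study cohort
#'
#' Draws an age-heterogeneous cohort with the study's variable structure:
#' age, five covariates (gender 0/1, ordinal education, monthly income with
#' missingness, numeracy 0--8, working memory 0--75) and the 24 canonical
#' outcomes.  Each outcome is built as
#' `sum(standardized slopes * z(predictor)) + residual`, with residuals
#' equicorrelated within contrast blocks and scaled toward unit marginal
#' outcome variance.  Income values are masked completely at random after
#' outcome generation.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per participant: `participant_id`, `age`,
#'   the five covariates, and the 24 outcome columns.
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 50, seed = 1))
#' dim(cohort)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  labels <- outcome_labels()
  eff <- effect_matrix(config)
  corr <- residual_correlation(config$within_block_correlation)
  ch <- tryCatch(chol(corr),
                 error = function(e) abort(
                   "residual correlation matrix is not positive definite",
                   class = "agespec_config_error"))
  with_seed_or_rng(config$seed, {
    n <- config$n
    age <- runif(n, config$age_range[1], config$age_range[2])
    gender <- rbinom(n, 1L, config$prop_female)
    education <- sample(1:8, n, replace = TRUE,
                        prob = c(2, 6, 14, 22, 22, 18, 11, 5))
    income <- round(rlnorm(n, meanlog = log(5000), sdlog = 0.5) / 50) * 50
    numeracy <- rbinom(n, 8L, 0.6)
    working_memory <- rbinom(n, 75L, 0.65)

    preds <- cbind(
      age = zscore(age),
      gender = if (sd(gender) > 0) zscore(gender) else gender * 0,
      education = zscore(education),
      income = zscore(income),
      numeracy = zscore(numeracy),
      working_memory = zscore(working_memory)
    )
    signal <- preds %*% eff
    # residual scale keeps outcome variance near 1 given injected slopes
    s <- config$noise_sd * sqrt(pmax(0.05, 1 - colSums(eff^2)))
    eps <- (matrix(rnorm(n * length(labels)), n) %*% ch) *
      rep(s, each = n)
    outcomes <- signal + eps
    colnames(outcomes) <- labels

    if (config$n_income_missing > 0L) {
      income[sample.int(n, config$n_income_missing)] <- NA_real_
    }

    dplyr::bind_cols(
      tibble::tibble(
        participant_id = sprintf("P%04d", seq_len(n)),
        age = age, gender = gender, education = education,
        income = income, numeracy = numeracy,
        working_memory = working_memory
      ),
      tibble::as_tibble(outcomes)
    )
  })
}

#' Exclusion bookkeeping for the recruited sample
#'
#' Applies the study's staged exclusions (incomplete imaging, equipment
#' fault, excessive head motion) to the recruited count and reports each
#' stage.
#'
#' @param n_recruited Participants recruited for the imaging session.
#' @param n_incomplete_imaging Excluded for missing or incomplete fMRI data.
#' @param n_equipment_fault Excluded for faulty equipment.
#' @param n_head_motion Excluded for excessive head motion.
#' @return A tibble of class `exclusion_report` with columns `stage`,
#'   `excluded`, `remaining`; the last row's `remaining` is the effective
#'   sample size, also available as `attr(x, "n_effective")`.
#' @examples
#' apply_exclusions(189, 10, 2, 2)
#' @export
apply_exclusions <- function(n_recruited = 189L,
                             n_incomplete_imaging = 10L,
                             n_equipment_fault = 2L,
                             n_head_motion = 2L) {
  counts <- c(n_recruited, n_incomplete_imaging, n_equipment_fault,
              n_head_motion)
  if (any(counts < 0)) {
    abort("exclusion counts must be non-negative", class = "agespec_ledger_error")
  }
  excluded <- c(0L, n_incomplete_imaging, n_equipment_fault, n_head_motion)
  remaining <- n_recruited - cumsum(excluded)
  if (any(remaining < 0)) {
    abort("exclusions exceed the recruited sample", class = "agespec_ledger_error")
  }
  out <- tibble::tibble(
    stage = c("recruited", "incomplete_imaging", "equipment_fault",
              "head_motion"),
    excluded = as.integer(excluded),
    remaining = as.integer(remaining)
  )
  attr(out, "n_effective") <- out$remaining[nrow(out)]
  class(out) <- c("exclusion_report", class(out))
  out
}

#' Analysis sample size for a specification
#'
#' Specifications are fitted on complete cases, so only models that include
#' income (the one covariate with missingness) lose rows.
#'
#' @param data A cohort table.
#' @param uses_income Does the specification include the income covariate?
#' @return Integer count of usable rows.
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 175, seed = 1))
#' analysis_n(cohort, uses_income = TRUE)
#' analysis_n(cohort, uses_income = FALSE)
#' @export
analysis_n <- function(data, uses_income = FALSE) {
  stopifnot(nrow(data) > 0L)
  if (isTRUE(uses_income)) sum(!is.na(data$income)) else nrow(data)
}
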