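#' Canonical outcome labels of the uncertainty study
#'
#' The study measures 24 outcomes per participant: four behavioral indices
#' (adjusted average pumps in the BART across all reward balloons, for linear
#' balloons only, for exponential balloons only, and the proportion of
#' immediate choices in delay discounting) plus 20 neural volume-of-interest
#' (VOI) contrast magnitudes -- three BART contrasts (reward vs. control,
#' parametric pump modulation, linear vs. exponential) and two delay
#' discounting contrasts (immediacy, delay), each extracted from four VOIs
#' (nucleus accumbens, anterior insula, medial prefrontal cortex, thalamus).
#'
#' @return Character vector of 24 labels in a stable canonical order:
#'   behavioral indices first, then BART neural contrasts, then delay
#'   discounting neural contrasts.
#' @examples
#' outcome_labels()
#' @export
outcome_labels <- function() {
  vois <- c("nacc", "insula", "mpfc", "thalamus")
  c(
    "bart_adjpumps_all", "bart_adjpumps_linear", "bart_adjpumps_exponential",
    "dd_prop_immediate",
    paste0("bart_", rep(c("rewardVsControl", "parametric", "linVsExp"),
                        each = 4L), "_", vois),
    paste0("dd_", rep(c("immediacy", "delay"), each = 4L), "_", vois)
  )
}

#' Covariate labels of the uncertainty study
#'
#' The five covariates controlled for in the specification curve: gender
#' (binary), education (ordinal level), monthly income (may be missing),
#' numeracy (0--8), and working memory (operation span, 0--75).
#'
#' @return Character vector of five covariate column names.
#' @export
covariate_labels <- function() {
  c("gender", "education", "income", "numeracy", "working_memory")
}

#' Outcome block structure
#'
#' Groups the 24 outcomes into residual-correlation blocks: each neural
#' contrast (four VOIs) forms one block, mirroring the empirical pattern that
#' VOI markers correlate strongly within contrast; each behavioral index is
#' its own singleton block.
#'
#' @return A tibble with columns `outcome` and `block`.
#' @export
outcome_blocks <- function() {
  labels <- outcome_labels()
  block <- dplyr::case_when(
    grepl("^bart_rewardVsControl_", labels) ~ "bart_rewardVsControl",
    grepl("^bart_parametric_", labels) ~ "bart_parametric",
    grepl("^bart_linVsExp_", labels) ~ "bart_linVsExp",
    grepl("^dd_immediacy_", labels) ~ "dd_immediacy",
    grepl("^dd_delay_", labels) ~ "dd_delay",
    .default = labels
  )
  tibble::tibble(outcome = labels, block = block)
}
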