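dd_pairings <- function() {
  tibble::tibble(
    sooner_delay_wk = c(0, 0, 2, 2, 4),
    later_delay_wk  = c(2, 4, 4, 6, 6)
  )
}

dd_pct_levels <- function() c(1, 3, 5, 10, 15, 25, 35, 50)

# truncated normal on [lo, hi] by rejection; cheap at these sizes
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Build the 80-trial delay discounting design
#'
#' Crosses five delay pairings (today vs. 2 weeks, today vs. 4, 2 vs. 4,
#' 2 vs. 6, 4 vs. 6 weeks) with eight percentage differences between the
#' smaller-sooner and larger-later amount (1, 3, 5, 10, 15, 25, 35, 50
#' percent), two trials per cell: 80 choice sets.  Sooner amounts are drawn
#' from a normal distribution truncated to [5, 40] CHF and rounded to coin
#' resolution (0.05); the later amount applies the cell's percentage
#' difference and is rounded to 0.01.  Trial order is randomized.
#'
#' @param seed Integer seed or `NULL`.
#' @param amount_dist `"truncnorm"` (default) or `"uniform"` for the sooner
#'   amounts on [5, 40].
#' @param amount_mean,amount_sd Parameters of the (pre-truncation) normal.
#' @return A tibble with 80 rows: `trial_id`, `sooner_delay_wk`,
#'   `later_delay_wk`, `pairing`, `pct_diff`, `sooner_amount`,
#'   `later_amount`.
#' @examples
#' design <- dd_design(seed = 1)
#' table(design$pairing)
#' @export
dd_design <- function(seed = NULL, amount_dist = c("truncnorm", "uniform"),
                      amount_mean = 22.5, amount_sd = 8) {
  amount_dist <- match.arg(amount_dist)
  cells <- tidyr::crossing(dd_pairings(), pct_diff = dd_pct_levels(),
                           rep = 1:2)
  with_seed_or_rng(seed, {
    amounts <- switch(amount_dist,
      truncnorm = rtrunc_norm(nrow(cells), amount_mean, amount_sd, 5, 40),
      uniform = runif(nrow(cells), 5, 40)
    )
    cells$sooner_amount <- round(amounts / 0.05) * 0.05
    cells$later_amount <- round(cells$sooner_amount *
                                  (1 + cells$pct_diff / 100), 2)
    cells <- cells[sample.int(nrow(cells)), ]
    cells$trial_id <- sprintf("t%02d", seq_len(nrow(cells)))
    cells$pairing <- paste0(cells$sooner_delay_wk, "v", cells$later_delay_wk)
    dplyr::select(cells, "trial_id", "sooner_delay_wk", "later_delay_wk",
                  "pairing", "pct_diff", "sooner_amount", "later_amount")
  })
}

#' Trial filter for the neural delay discounting contrasts
#'
#' Drops the 4-vs-6-week pairing (to balance trial counts) and labels the
#' rest: trials whose sooner option is paid today form the `immediate`
#' subset; trials whose sooner option is in two weeks form the `delayed`
#' subset.  On the canonical design this yields 32 trials in each subset.
#' Applying the filter to an already-filtered design is a no-op.
#'
#' @param design A design tibble from [dd_design()].
#' @return The design restricted to the retained pairings, with an added
#'   `neural_subset` column (`"immediate"` / `"delayed"`).
#' @export
dd_neural_trials <- function(design) {
  kept <- dplyr::filter(design,
                        !(.data$sooner_delay_wk == 4 & .data$later_delay_wk == 6))
  dplyr::mutate(
    kept,
    neural_subset = dplyr::if_else(.data$sooner_delay_wk == 0,
                                   "immediate", "delayed")
  )
}

#' Simulate inter-temporal choices with a hyperbolic agent
#'
#' Subjective value of an amount `A` at delay `d` weeks is
#' `A / (1 + discount_rate * d)`; the probability of taking the
#' smaller-sooner option is `plogis((SV_sooner - SV_later) / temperature)`.
#' At indifference the probability is exactly 0.5; as `temperature -> 0`
#' choice becomes deterministic.
#'
#' @param design A design tibble from [dd_design()].
#' @param discount_rate Per-week hyperbolic discount rate, `>= 0`.
#' @param temperature Positive softmax temperature; `0` is allowed and makes
#'   the agent deterministic (ties resolved at probability 0.5).
#' @param seed Integer seed or `NULL`.
#' @return A tibble: `trial_id`, `p_sooner`, `choice`
#'   (`"sooner"`/`"later"`).
#' @export
simulate_dd_choices <- function(design, discount_rate = 0.05,
                                temperature = 0.5, seed = NULL) {
  stopifnot(discount_rate >= 0, temperature >= 0)
  sv_sooner <- design$sooner_amount / (1 + discount_rate * design$sooner_delay_wk)
  sv_later <- design$later_amount / (1 + discount_rate * design$later_delay_wk)
  dv <- sv_sooner - sv_later
  p <- if (temperature == 0) (dv > 0) + 0.5 * (dv == 0) else plogis(dv / temperature)
  with_seed_or_rng(seed, {
    sooner <- runif(nrow(design)) < p
    tibble::tibble(
      trial_id = design$trial_id,
      p_sooner = p,
      choice = dplyr::if_else(sooner, "sooner", "later")
    )
  })
}

#' Model-free delay discounting indices
#'
#' Scores a complete choice set against its design: overall proportion of
#' smaller-sooner choices; the primary analysis index, the proportion of
#' immediate choices out of all trials with a today option; and
#' smaller-sooner proportions broken down by delay pairing and by
#' percentage difference (as nested tibbles).  Mean reaction times per
#' grouping are included when the choices carry an `rt` column.
#'
#' @param choices A choice tibble (`trial_id`, `choice`, optional `rt`).
#' @param design The matching [dd_design()] tibble.
#' @return A one-row tibble: `n_trials`, `prop_sooner`, `prop_immediate`,
#'   and list-columns `by_pairing`, `by_pct`.
#' @export
score_dd <- function(choices, design) {
  if (anyDuplicated(choices$trial_id)) {
    abort("duplicate trial responses", class = "agespec_incomplete_session")
  }
  if (!setequal(choices$trial_id, design$trial_id) ||
      nrow(choices) != nrow(design)) {
    abort("choices do not cover the design's trials exactly",
          class = "agespec_incomplete_session")
  }
  d <- dplyr::inner_join(design, choices, by = "trial_id")
  d$sooner_chosen <- d$choice == "sooner"
  has_rt <- "rt" %in% names(d)
  summarise_grp <- function(g) {
    out <- dplyr::summarise(
      g,
      n = dplyr::n(),
      prop_sooner = mean(.data$sooner_chosen),
      .groups = "drop"
    )
    if (has_rt) {
      out$mean_rt <- dplyr::summarise(
        g, mean_rt = mean(.data$rt), .groups = "drop")$mean_rt
    }
    out
  }
  today <- d[d$sooner_delay_wk == 0, ]
  tibble::tibble(
    n_trials = nrow(d),
    prop_sooner = mean(d$sooner_chosen),
    prop_immediate = mean(today$sooner_chosen),
    by_pairing = list(summarise_grp(dplyr::group_by(d, .data$pairing))),
    by_pct = list(summarise_grp(dplyr::group_by(d, .data$pct_diff)))
  )
}
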