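#' BART reward functions
#'
#' Two payoff schedules for reward balloons.  `reward_linear()` pays a fixed
#' amount per successful pump (default 0.05 CHF).  `reward_exponential()`
#' pays `base * growth^(j - 1)` for the j-th pump, so early pumps are worth
#' little but the cumulative payoff overtakes the linear balloon well before
#' the 16-pump capacity under the defaults.  Control balloons pay nothing.
#'
#' @param per_pump Payment per successful pump (linear balloon), in CHF.
#' @param base Payment for the first pump (exponential balloon), in CHF.
#' @param growth Per-pump geometric growth factor, `> 1`.
#' @return An object of class `bart_reward`.
#' @examples
#' cumulative_reward(reward_linear(), 10)       # 0.50
#' cumulative_reward(reward_exponential(), 16)  # exceeds 16 * 0.05
#' @export
reward_linear <- function(per_pump = 0.05) {
  stopifnot(per_pump > 0)
  structure(list(kind = "linear", per_pump = per_pump), class = "bart_reward")
}

#' @rdname reward_linear
#' @export
reward_exponential <- function(base = 0.01, growth = 1.6) {
  stopifnot(base > 0, growth > 1)
  structure(list(kind = "exponential", base = base, growth = growth),
            class = "bart_reward")
}

#' @rdname reward_linear
#' @export
reward_control <- function() {
  structure(list(kind = "control"), class = "bart_reward")
}

#' Cumulative balloon reward after a number of pumps
#'
#' @param fn A `bart_reward` (see [reward_linear()]).
#' @param pumps Non-negative integer vector of pump counts.
#' @return Accumulated earnings in CHF (full precision; rounding to coin
#'   resolution is a reporting concern).
#' @export
cumulative_reward <- function(fn, pumps) {
  stopifnot(inherits(fn, "bart_reward"))
  if (any(pumps < 0)) abort("`pumps` must be non-negative", class = "agespec_domain_error")
  switch(fn$kind,
    linear = fn$per_pump * pumps,
    # geometric series: sum_{j=1..k} base * growth^(j-1)
    exponential = fn$base * (fn$growth^pumps - 1) / (fn$growth - 1),
    control = rep(0, length(pumps))
  )
}

# resolve a pump policy: a fixed integer target or a function of the trial
# history (tibble of completed trials) returning the intended pump count
intended_pumps <- function(policy, history) {
  k <- if (is.function(policy)) policy(history) else policy
  k <- as.integer(k)
  if (is.na(k) || k < 1L) {
    abort("intended pumps must be >= 1", class = "agespec_domain_error")
  }
  k
}

#' Simulate a BART session
#'
#' Each trial draws an explosion point uniformly on `1:16`; the agent pumps
#' toward its intended count and the trial ends at the first of cash-out
#' (intended pumps reached, strictly before the explosion point) or explosion
#' (the pump whose count equals the explosion point).  Explosions and control
#' balloons earn nothing; cash-outs on reward balloons earn
#' [cumulative_reward()] of the pumps administered.
#'
#' @param policy Fixed intended pump count in `1:16`, or a function of the
#'   completed-trial history returning one.  Intending 16 pumps always ends in
#'   an explosion (capacity is 16).
#' @param n_reward_trials_per_type Reward trials per balloon type (default 15,
#'   i.e. 30 reward trials per session).
#' @param n_control_trials Control balloon trials (default 10).
#' @param linear_fn,exponential_fn Reward functions for the two reward
#'   balloon types.
#' @param seed Integer seed or `NULL`.
#' @return A tibble with one row per trial: `trial`, `balloon_type`
#'   (`"linear"`, `"exponential"`, `"control"`), `explosion_point`, `pumps`,
#'   `end_state` (`"cashout"`/`"explosion"`), `trial_earnings`.  Trial order
#'   is randomized.
#' @examples
#' session <- simulate_bart(policy = 8, seed = 1)
#' score_bart(session)
#' @export
simulate_bart <- function(policy,
                          n_reward_trials_per_type = 15L,
                          n_control_trials = 10L,
                          linear_fn = reward_linear(),
                          exponential_fn = reward_exponential(),
                          seed = NULL) {
  stopifnot(n_reward_trials_per_type >= 0L, n_control_trials >= 0L)
  types <- c(rep("linear", n_reward_trials_per_type),
             rep("exponential", n_reward_trials_per_type),
             rep("control", n_control_trials))
  with_seed_or_rng(seed, {
    types <- sample(types)
    n <- length(types)
    explosion_point <- sample.int(16L, n, replace = TRUE)
    rows <- vector("list", n)
    stateful <- is.function(policy)
    history <- tibble::tibble()
    for (i in seq_len(n)) {
      intent <- intended_pumps(policy, history)
      exploded <- explosion_point[i] <= intent
      pumps <- if (exploded) explosion_point[i] else intent
      fn <- switch(types[i],
                   linear = linear_fn,
                   exponential = exponential_fn,
                   control = reward_control())
      earnings <- if (exploded) 0 else cumulative_reward(fn, pumps)
      rows[[i]] <- tibble::tibble(
        trial = i, balloon_type = types[i],
        explosion_point = explosion_point[i], pumps = pumps,
        end_state = if (exploded) "explosion" else "cashout",
        trial_earnings = earnings
      )
      if (stateful) history <- dplyr::bind_rows(history, rows[[i]])
    }
    dplyr::bind_rows(rows)
  })
}

#' Score a BART session
#'
#' Computes the study's behavioral indices on a set of trials: total and
#' average pumps, adjusted average pumps (the primary risk-taking index:
#' mean pumps over cash-out trials only), number of explosions, and total
#' earnings.  Control balloons never contribute earnings.
#'
#' @param session A trial tibble from [simulate_bart()] (or the same dialect).
#' @param balloons Which balloons to score: `"reward"` (both reward types,
#'   the default), `"linear"`, `"exponential"`, or `"control"`.
#' @return A one-row tibble: `balloons`, `n_trials`, `total_pumps`,
#'   `avg_pumps`, `adj_avg_pumps` (`NA` when no trial ended in cash-out),
#'   `n_explosions`, `total_earnings`.
#' @export
score_bart <- function(session, balloons = c("reward", "linear",
                                             "exponential", "control")) {
  balloons <- match.arg(balloons)
  keep <- if (balloons == "reward") {
    session$balloon_type %in% c("linear", "exponential")
  } else {
    session$balloon_type == balloons
  }
  trials <- session[keep, , drop = FALSE]
  if (nrow(trials) == 0L) {
    abort("no trials match the requested balloon filter",
          class = "agespec_no_data")
  }
  cashed <- trials$end_state == "cashout"
  tibble::tibble(
    balloons = balloons,
    n_trials = nrow(trials),
    total_pumps = sum(trials$pumps),
    avg_pumps = mean(trials$pumps),
    adj_avg_pumps = if (any(cashed)) mean(trials$pumps[cashed]) else NA_real_,
    n_explosions = sum(!cashed),
    total_earnings = sum(trials$trial_earnings)
  )
}

#' Paired comparison of balloon-type indices
#'
#' Two-sided paired-samples t-test of a per-participant index between the
#' linear and exponential reward balloons, with the sign convention
#' linear minus exponential.
#'
#' @param data A data frame with one row per participant.
#' @param linear,exponential Column names holding the index for each balloon
#'   type.
#' @return A one-row tibble: `mean_diff`, `t`, `df`, `p_value`, `n`,
#'   `degenerate` (`TRUE` when the differences have zero variance, in which
#'   case `t` and `p_value` are `NA`).
#' @examples
#' d <- data.frame(linear = rnorm(20, 8), exponential = rnorm(20, 7))
#' compare_balloon_types(d)
#' @export
compare_balloon_types <- function(data, linear = "linear",
                                  exponential = "exponential") {
  x <- data[[linear]]
  y <- data[[exponential]]
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  if (sd(d) == 0) {
    return(tibble::tibble(mean_diff = mean(d), t = NA_real_,
                          df = length(d) - 1L, p_value = NA_real_,
                          n = length(d), degenerate = TRUE))
  }
  tt <- t.test(x, y, paired = TRUE, alternative = "two.sided")
  tibble::tibble(
    mean_diff = unname(tt$estimate), t = unname(tt$statistic),
    df = unname(tt$parameter), p_value = tt$p.value,
    n = length(d), degenerate = FALSE
  )
}
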