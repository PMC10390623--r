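test_that("cumulative rewards match closed forms and a brute-force sum", {
  expect_equal(cumulative_reward(reward_linear(0.05), 10), 0.50)
  expect_equal(cumulative_reward(reward_linear(), 0), 0)
  expect_equal(cumulative_reward(reward_exponential(), 0), 0)
  expect_equal(cumulative_reward(reward_control(), 12), 0)
  fn <- reward_exponential(base = 0.01, growth = 1.6)
  brute <- vapply(0:16, function(k) sum(0.01 * 1.6^(seq_len(k) - 1)),
                  numeric(1))
  expect_equal(cumulative_reward(fn, 0:16), brute, tolerance = 1e-12)
  # defaults pay more at capacity than the linear balloon
  expect_gt(cumulative_reward(fn, 16), cumulative_reward(reward_linear(), 16))
  expect_error(cumulative_reward(fn, -1), class = "agespec_domain_error")
})

test_that("exponential cumulative reward is convex in pump count", {
  fn <- reward_exponential(base = 0.02, growth = 1.3)
  cum <- cumulative_reward(fn, 0:16)
  second_diff <- diff(diff(cum))
  expect_true(all(second_diff >= 0))
})

test_that("sessions are deterministic and explosions follow the uniform model", {
  s1 <- simulate_bart(8, seed = 11)
  s2 <- simulate_bart(8, seed = 11)
  expect_identical(s1, s2)
  expect_true(all(s1$explosion_point %in% 1:16))
  # explosion iff the intended pumps reach the explosion point
  exploded <- s1$end_state == "explosion"
  expect_true(all(s1$pumps[exploded] == s1$explosion_point[exploded]))
  expect_true(all(s1$pumps[!exploded] < s1$explosion_point[!exploded]))
  expect_true(all(s1$trial_earnings[exploded] == 0))
  expect_true(all(s1$trial_earnings[s1$balloon_type == "control"] == 0))

  big <- simulate_bart(8, n_reward_trials_per_type = 500,
                       n_control_trials = 0, seed = 12)
  expect_lt(abs(mean(big$end_state == "explosion") - 8 / 16), 0.05)
})

test_that("a pump target of 1 explodes exactly on explosion point 1", {
  s <- simulate_bart(1, n_reward_trials_per_type = 200,
                     n_control_trials = 0, seed = 13)
  hit <- s$explosion_point == 1
  expect_true(all(s$end_state[hit] == "explosion"))
  expect_true(all(s$pumps[hit] == 1))
  expect_true(all(s$trial_earnings[hit] == 0))
  expect_true(all(s$end_state[!hit] == "cashout"))
})

test_that("session scoring matches a brute-force trial-by-trial tally", {
  toy <- tibble::tibble(
    trial = 1:3, balloon_type = "linear",
    explosion_point = c(9, 3, 9), pumps = c(5, 3, 7),
    end_state = c("cashout", "explosion", "cashout"),
    trial_earnings = c(0.25, 0, 0.35)
  )
  sc <- score_bart(toy, "reward")
  expect_equal(sc$adj_avg_pumps, 6.0)
  expect_identical(sc$n_explosions, 1L)

  s <- simulate_bart(9, n_reward_trials_per_type = 250,
                     n_control_trials = 50, seed = 14)
  sc <- score_bart(s, "reward")
  keep <- s[s$balloon_type != "control", ]
  expect_identical(sc$n_trials, nrow(keep))
  expect_equal(sc$total_pumps, sum(keep$pumps))
  expect_equal(sc$avg_pumps, sum(keep$pumps) / nrow(keep))
  expect_equal(sc$adj_avg_pumps,
               mean(keep$pumps[keep$end_state == "cashout"]))
  expect_identical(sc$n_explosions, sum(keep$end_state == "explosion"))
  expect_equal(sc$total_earnings, sum(keep$trial_earnings))
  # earnings identity: cash-out reward trials re-priced from scratch
  lin <- keep[keep$balloon_type == "linear" & keep$end_state == "cashout", ]
  ex <- keep[keep$balloon_type == "exponential" & keep$end_state == "cashout", ]
  expect_equal(sc$total_earnings,
               sum(cumulative_reward(reward_linear(), lin$pumps)) +
                 sum(cumulative_reward(reward_exponential(), ex$pumps)))
})

test_that("adjusted average pumps ignores explosion trials entirely", {
  s <- simulate_bart(7, n_reward_trials_per_type = 100,
                     n_control_trials = 0, seed = 15)
  base <- score_bart(s, "reward")$adj_avg_pumps
  extra <- s[s$end_state == "explosion", ][1, ]
  extra$pumps <- 999L
  expect_equal(score_bart(rbind(s, extra), "reward")$adj_avg_pumps, base)
  all_explode <- s[s$end_state == "explosion", ]
  expect_true(is.na(score_bart(all_explode, "reward")$adj_avg_pumps))
  expect_error(score_bart(s, "control"), class = "agespec_no_data")
})

test_that("paired balloon-type comparison behaves at the degenerate and powered ends", {
  same <- data.frame(linear = c(5, 6, 7), exponential = c(5, 6, 7))
  out <- compare_balloon_types(same)
  expect_equal(out$mean_diff, 0)
  expect_true(out$degenerate)
  expect_true(is.na(out$t))

  set.seed(31)
  shifted <- data.frame(exponential = rnorm(50, 5, 1))
  shifted$linear <- shifted$exponential + 1 + rnorm(50, 0, 0.1)
  out <- compare_balloon_types(shifted)
  expect_lt(out$p_value, 0.001)
  expect_gt(out$mean_diff, 0.9)
})

test_that("the paired t-test is calibrated under identical pumping policies", {
  set.seed(32)
  p <- vapply(1:1000, function(i) {
    x <- rnorm(40, 8, 2)
    y <- rnorm(40, 8, 2)
    compare_balloon_types(data.frame(linear = x, exponential = y))$p_value
  }, numeric(1))
  expect_lt(abs(mean(p <= 0.05) - 0.05), 0.02)
})

test_that("stateful pump policies see the trial history", {
  policy <- function(history) if (nrow(history) == 0) 4L else
    max(1L, 4L + sum(history$end_state == "cashout") -
          2L * sum(history$end_state == "explosion"))
  s <- simulate_bart(policy, n_reward_trials_per_type = 20, seed = 16)
  expect_identical(s, simulate_bart(policy, n_reward_trials_per_type = 20,
                                    seed = 16))
  expect_true(all(s$pumps >= 1))
})
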