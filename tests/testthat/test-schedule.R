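test_that("the titration rule moves the requirement by one step or not at all", {
  expect_equal(apply_ae_adjustment(c("AE", "AE"), 0.030), 0.031)
  expect_equal(apply_ae_adjustment(c("FR", "FR"), 0.030), 0.029)
  expect_equal(apply_ae_adjustment(c("AE", "FR"), 0.030), 0.030)
  expect_equal(apply_ae_adjustment(c("FR", "AE"), 0.030), 0.030)
  # clipped at the floor
  expect_equal(apply_ae_adjustment(c("FR", "FR"), 0.001), 0.001)
  expect_error(apply_ae_adjustment("AE", 0.03), class = "aeforage_error_state")
  expect_error(apply_ae_adjustment(c("AE", "left"), 0.03),
               class = "aeforage_error_state")
})

test_that("schedule configuration validates its invariants", {
  expect_error(schedule_config(block_size = 3),
               class = "aeforage_error_invalid_argument")
  expect_error(schedule_config(trials_per_session = 61),
               class = "aeforage_error_invalid_argument")
  expect_error(schedule_config(fr_requirement = 0),
               class = "aeforage_error_invalid_argument")
  expect_error(schedule_config(ae_step = -0.001),
               class = "aeforage_error_invalid_argument")
})

test_that("FR trials reinforce after exactly the required pecks", {
  set.seed(61)
  tr <- run_trial(agent_always_fr(), "free", 0.05,
                  schedule_config(fr_requirement = 15))
  expect_true(tr$reinforced)
  expect_equal(tr$corrections_used, 0L)
  expect_equal(sum(tr$events[[1]]$event_kind == "peck"), 15)
  expect_equal(nrow(tr$ire_attempts[[1]]), 0)
})

test_that("forced AE failures re-run the schedule phase up to five corrections", {
  set.seed(62)
  tr <- run_trial(failing_agent(), "forced-left", 0.01)
  expect_false(tr$reinforced)
  expect_equal(tr$corrections_used, 5L)
  expect_equal(nrow(tr$ire_attempts[[1]]), 6L) # initial attempt + 5 corrections
  # free-choice failures get no correction
  set.seed(63)
  fr <- run_trial(failing_agent(), "free", 0.01,
                  config = schedule_config(fr_requirement = 1))
  if (fr$chosen_schedule == "AE") {
    expect_false(fr$reinforced)
    expect_equal(fr$corrections_used, 0L)
    expect_equal(nrow(fr$ire_attempts[[1]]), 1L)
  }
  # a zero requirement is beaten by any movement under strict >
  set.seed(64)
  cfg0 <- schedule_config(ae_floor = 0)
  zz <- run_trial(agent_always_ae(), "free", 0, config = cfg0)
  expect_true(zz$reinforced)
})

test_that("an agent pecking outside the response area is rejected", {
  bad <- agent_custom(
    choose_fun = function(agent, a, fr, i) "AE",
    pair_fun = function(agent, clock, geometry, a) {
      data.frame(x = c(0, 0.5), y = c(0, 0), t = clock + c(0.1, 0.3))
    }
  )
  expect_error(run_trial(bad, "forced-left", 0.01),
               class = "aeforage_error_invalid_behavior")
})

test_that("a default session is 15 blocks of 2 forced + 2 free trials", {
  s <- run_session(agent_alternating(), schedule_config(), seed = 5)
  expect_equal(nrow(s$trials), 60)
  expect_equal(s$blocks_completed, 15)
  expect_equal(sum(s$trials$trial_type == "free"), 30)
  expect_equal(sum(s$trials$trial_type != "free"), 30)
  # each block holds exactly one forced-left and one forced-right trial
  per_block <- dplyr::count(s$trials, block, trial_type) |>
    tidyr::pivot_wider(names_from = trial_type, values_from = n)
  expect_true(all(per_block$`forced-left` == 1))
  expect_true(all(per_block$`forced-right` == 1))
  # session-mean convention
  expect_equal(s$mean_ae_requirement, mean(s$trials$ae_requirement))
  # at most one reinforcer per trial, corrections never add more
  expect_lte(sum(s$trials$reinforced), nrow(s$trials))
})

test_that("an always-AE session titrates up by one step per block", {
  s <- run_session(agent_always_ae(), schedule_config(), ae_start = 0.010,
                   seed = 2)
  per_block <- vapply(split(s$trials$ae_requirement, s$trials$block),
                      unique, numeric(1))
  expect_equal(unname(per_block), 0.010 + 0.001 * (0:14))
  expect_equal(s$final_block_requirement, 0.024)
  expect_equal(s$next_start, 0.025)
  # requirement never changes mid-block and moves by 0 or +-step between blocks
  steps <- abs(diff(per_block))
  expect_true(all(pmin(steps, abs(steps - 0.001)) < 1e-12))
})

test_that("an always-FR session titrates down to the floor and stays there", {
  s <- run_session(agent_always_fr(),
                   schedule_config(fr_requirement = 2),
                   ae_start = 0.005, seed = 3)
  per_block <- vapply(split(s$trials$ae_requirement, s$trials$block),
                      unique, numeric(1))
  expect_equal(unname(per_block),
               pmax(0.005 - 0.001 * (0:14), 0.001))
  expect_equal(s$next_start, 0.001)
})

test_that("the session time cap truncates the session", {
  # cap below one trial's duration: no trials at all
  cfg <- schedule_config(session_time_cap = 0)
  s0 <- run_session(agent_alternating(), cfg, seed = 4)
  expect_equal(nrow(s0$trials), 0)
  expect_equal(s0$blocks_completed, 0)
  expect_equal(s0$next_start, 0.010) # no completed block, no adjustment
  # a tight cap stops mid-session; completed trials are retained
  cfg2 <- schedule_config(session_time_cap = 120)
  s1 <- run_session(agent_always_ae(), cfg2, seed = 4)
  expect_lt(nrow(s1$trials), 60)
  expect_gt(nrow(s1$trials), 0)
  expect_lte(s1$blocks_completed, max(s1$trials$block))
})

test_that("sessions and conditions are deterministic under a fixed seed", {
  a <- run_session(agent_stationary(a_star = 0.02), schedule_config(), seed = 99)
  b <- run_session(agent_stationary(a_star = 0.02), schedule_config(), seed = 99)
  expect_identical(a$trials, b$trials)
  expect_identical(a$events, b$events)
  c1 <- run_condition(agent_alternating(), schedule_config(), seed = 7,
                      n_sessions = 3)
  c2 <- run_condition(agent_alternating(), schedule_config(), seed = 7,
                      n_sessions = 3)
  expect_identical(c1$session_means, c2$session_means)
})

test_that("the requirement carries over from the final block of each session", {
  cond <- run_condition(agent_stationary(a_star = 0.02, tau = 0.01),
                        schedule_config(), ae_start = 0.010, seed = 13,
                        n_sessions = 5)
  for (k in 1:4) {
    expect_equal(cond$sessions[[k + 1]]$ae_start,
                 cond$sessions[[k]]$next_start)
  }
})

test_that("conditions terminate at the stability rule or the hard cap", {
  cfg <- schedule_config(fr_requirement = 3)
  stable <- run_condition(agent_alternating(), cfg, seed = 8)
  expect_equal(stable$n_sessions, 18)
  expect_true(stable$stable)
  # a drifting agent never stabilises and hits the hard cap
  err <- tryCatch(
    run_condition(agent_always_ae(), cfg, seed = 8, max_sessions = 14L),
    aeforage_error_condition_not_stable = function(e) e
  )
  expect_s3_class(err, "aeforage_error_condition_not_stable")
  expect_length(err$logs, 14)
})

test_that("titrated requirements recover a logistic agent's indifference point", {
  # smooth decreasing choice rule equal to 1/2 at a*: the long-run mean
  # requirement converges to a*
  ag <- agent_stationary(a_star = 0.025, tau = 0.004)
  ips <- vapply(1:6, function(r) {
    cond <- run_condition(ag, schedule_config(fr_requirement = 2),
                          ae_start = 0.010, seed = 100 + r, n_sessions = 30)
    indifference_point(cond$session_means$mean_ae_requirement)
  }, numeric(1))
  se <- stats::sd(ips) / sqrt(length(ips))
  expect_lt(abs(mean(ips) - 0.025), 3 * se + 1e-4)
})

test_that("experiments run the configured condition series with carryover", {
  cfg <- experiment_config(
    seed = 21, conditions = c(2, 4),
    agent = agent_alternating(),
    schedule = schedule_config(trials_per_session = 16,
                               min_sessions_per_condition = 12)
  )
  exp <- run_experiment(cfg)
  expect_length(exp$conditions, 2)
  expect_equal(vapply(exp$conditions, function(cc) cc$fr_requirement,
                      integer(1)), c(2L, 4L))
  expect_equal(exp$conditions[[2]]$ae_start, exp$conditions[[1]]$next_start)
  g <- glance(exp)
  expect_equal(nrow(g), 2)
  expect_true(all(g$stable))
})
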