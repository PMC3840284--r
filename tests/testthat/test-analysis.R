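test_that("stability criteria behave at their defining boundaries", {
  # exactly constant series: flat-series carve-out passes everything
  flat <- stability_check(rep(0.02, 20))
  expect_true(flat$criterion1_pass)
  expect_true(flat$criterion2_pass)
  expect_true(flat$criterion3_pass)
  expect_true(flat$pass)

  # an extreme inside the last six fails criterion 1
  x <- rep(0.02, 20); x[18] <- 0.03
  expect_false(stability_check(x)$criterion1_pass)
  # ties toward failure: the condition-wide max repeated in the last six
  y <- c(rep(0.03, 3), rep(0.02, 11), 0.03, rep(0.02, 5))
  expect_false(stability_check(y)$criterion1_pass)
  # extremes strictly before the last six pass
  z <- c(0.05, 0.001, rep(0.02, 16))
  expect_true(stability_check(z)$criterion1_pass)

  # last six 10% above the preceding six: criterion 3 fails
  w <- c(rep(0.02, 8), rep(0.02, 6), rep(0.022, 6))
  rep3 <- stability_check(w)
  expect_false(rep3$criterion3_pass)
  expect_equal(rep3$percent_diff, 10)

  # the 7.5% window-mean boundary itself still passes; just above fails
  at <- c(rep(0.02, 6), rep(0.02 * 1.075, 6))
  expect_true(stability_check(at)$criterion3_pass)
  expect_equal(stability_check(at)$percent_diff, 7.5)
  above <- c(rep(0.02, 6), rep(0.02 * 1.0751, 6))
  expect_false(stability_check(above)$criterion3_pass)

  expect_error(stability_check(rep(0.02, 11)),
               class = "aeforage_error_insufficient_data")
})

test_that("a significant slope over the last six sessions fails criterion 2", {
  # construct a series whose last-six least-squares slope is significant:
  # verify significance with R's lm as the independent check
  x <- c(rep(0.02, 6), 0.020, 0.022, 0.024, 0.0262, 0.028, 0.0301)
  last6 <- utils::tail(x, 6)
  p_lm <- summary(stats::lm(last6 ~ seq_len(6)))$coefficients[2, 4]
  expect_lt(p_lm, 0.05)
  rep2 <- stability_check(x)
  expect_false(rep2$criterion2_pass)
  expect_equal(rep2$trend_p, p_lm, tolerance = 1e-10)
  expect_gt(rep2$trend_slope, 0)

  # a perfectly linear run is an unambiguous trend
  lin <- c(rep(0.02, 6), 0.02 + 0.001 * (1:6))
  expect_false(stability_check(lin)$criterion2_pass)
  # the monotone-run alternative flags the same series
  expect_false(stability_check(lin, trend_method = "monotone")$criterion2_pass)
  jag <- c(rep(0.02, 6), 0.02, 0.021, 0.0205, 0.021, 0.0207, 0.021)
  expect_true(stability_check(jag, trend_method = "monotone")$criterion2_pass)
})

test_that("the indifference point is the mean of the last six session means", {
  expect_equal(indifference_point(rep(0.02, 6)), 0.02)
  expect_equal(indifference_point(c(0.01, 0.02, 0.03, 0.03, 0.02, 0.01)), 0.02)
  # prefix-invariant: only the last six matter
  expect_equal(indifference_point(c(rep(9, 10), 0.01, 0.02, 0.03, 0.03, 0.02, 0.01)),
               0.02)
  expect_error(indifference_point(rep(0.02, 5)),
               class = "aeforage_error_insufficient_data")
})

test_that("E/RFT sums every attempt's energy within a reinforcement run", {
  tr <- tibble::tibble(
    session_index = 1L,
    reinforced = c(FALSE, FALSE, TRUE),
    ire_attempts = lapply(c(0.01, 0.02, 0.05),
                          function(e) tibble::tibble(ire = e))
  )
  out <- e_per_rft(tr)
  expect_equal(out$e_per_rft, 0.08)
  expect_equal(out$n_reinforcers, 1L)

  # all successes: runs of length one, E/RFT is the mean reinforced IRE
  ok <- tibble::tibble(
    session_index = 1L, reinforced = TRUE,
    ire_attempts = lapply(c(0.03, 0.05, 0.07),
                          function(e) tibble::tibble(ire = e))
  )
  expect_equal(e_per_rft(ok)$e_per_rft, 0.05)
  expect_equal(e_per_rft(ok)$n_reinforcers, 3L)

  # zero reinforcements: the carve-out reports the total IRE
  none <- tibble::tibble(
    session_index = 1L, reinforced = FALSE,
    ire_attempts = lapply(c(0.01, 0.01), function(e) tibble::tibble(ire = e))
  )
  out0 <- e_per_rft(none)
  expect_equal(out0$e_per_rft, 0.02)
  expect_equal(out0$n_reinforcers, 0L)

  expect_error(e_per_rft(none[0, ]),
               class = "aeforage_error_undefined_statistic")
})

test_that("E/RFT matches a brute-force per-run summation oracle", {
  set.seed(71)
  for (i in 1:100) {
    log <- random_ae_log()
    got <- e_per_rft(log)
    want <- oracle_e_per_rft(log)
    expect_identical(got$n_reinforcers, want$n)
    expect_equal(got$e_per_rft, want$e)
  }
})

test_that("runs never span session boundaries", {
  tr <- tibble::tibble(
    session_index = c(1L, 1L, 2L, 2L),
    reinforced = c(FALSE, TRUE, FALSE, TRUE),
    ire_attempts = lapply(c(0.01, 0.02, 0.04, 0.08),
                          function(e) tibble::tibble(ire = e))
  )
  out <- e_per_rft(tr)
  expect_equal(sort(out$run_totals[[1]]), c(0.03, 0.12))
  # a trailing failure belongs to no completed reinforcement
  tr2 <- tibble::tibble(
    session_index = 1L,
    reinforced = c(TRUE, FALSE),
    ire_attempts = lapply(c(0.02, 0.09), function(e) tibble::tibble(ire = e))
  )
  expect_equal(e_per_rft(tr2)$e_per_rft, 0.02)
})

test_that("condition summaries reproduce the expected cross-condition patterns", {
  # stationary always-AE agent at pinned requirements (zero titration step):
  # E/RFT rises with the requirement while the mean IRE stays flat
  mk <- function(a, seed) {
    run_condition(agent_always_ae(), schedule_config(fr_requirement = 2,
                                                     ae_step = 0),
                  ae_start = a, seed = seed, n_sessions = 6)
  }
  conds <- list(mk(0.01, 1), mk(0.05, 2), mk(0.10, 3))
  # fake distinct FR labels so each pinned requirement is one condition
  for (i in 1:3) conds[[i]]$fr_requirement <- c(15L, 30L, 60L)[i]
  summ <- condition_summaries(conds, last_n = 3)
  s <- summ$summaries
  expect_equal(nrow(s), 3)
  expect_true(all(diff(s$e_per_rft) > 0))
  # mean IRE flat across requirements (stationary kinematics)
  pooled_sd <- stats::sd(unlist(s$ire_samples))
  expect_lt(max(abs(diff(s$mean_ire))), 3 * pooled_sd / sqrt(min(s$n_ire)) + 0.02)
  expect_false(is.null(summ$correlation))
  expect_gt(summ$correlation$r, 0)

  # determinism: identical seeds give identical summaries
  again <- condition_summaries({
    cc <- list(mk(0.01, 1), mk(0.05, 2), mk(0.10, 3))
    for (i in 1:3) cc[[i]]$fr_requirement <- c(15L, 30L, 60L)[i]
    cc
  }, last_n = 3)
  expect_equal(tidy(again), tidy(summ))

  # single condition: correlation reported as absent
  one <- condition_summaries(conds[1], last_n = 3)
  expect_null(one$correlation)
  expect_null(one$friedman)
})

test_that("the Friedman test appears only with enough replicated FR levels", {
  mk <- function(fr, ip) {
    structure(list(
      sessions = list(),
      session_means = tibble::tibble(session_index = 1:6,
                                     mean_ae_requirement = rep(ip, 6)),
      stability = NULL, stable = TRUE, fr_requirement = fr,
      condition_label = paste0("FR", fr), condition_index = 1L,
      ae_start = 0.01, next_start = ip, n_sessions = 6L, seed = 1L,
      config = NULL), class = "ae_condition")
  }
  # ascending 15,30,60 then descending 60,30,15 visits: 3 levels x 2 series
  conds <- list(mk(15, 0.02), mk(30, 0.04), mk(60, 0.08),
                mk(60, 0.075), mk(30, 0.045), mk(15, 0.022))
  summ <- condition_summaries(conds)
  expect_false(is.null(summ$friedman))
  expect_s3_class(summ$friedman, "htest")
  # the standard 15,30,60,30,15 order leaves FR 60 unreplicated
  summ5 <- condition_summaries(conds[1:5])
  expect_null(summ5$friedman)
})

test_that("series labels split at the first visit to the highest FR", {
  expect_equal(aeforage:::series_labels(c(15, 30, 60, 30, 15)),
               c("ascending", "ascending", "ascending",
                 "descending", "descending"))
})
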