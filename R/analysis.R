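#' Assess stability of a condition's session means
#'
#' A condition is stable when three criteria hold over the series of
#' per-session mean AE requirements:
#'
#' 1. Neither the highest nor the lowest session mean of the condition
#'    occurs in the last six sessions (ties count against stability). An
#'    exactly constant series — where every session is both the maximum and
#'    the minimum — passes, since the criterion's intent is to exclude
#'    extremes, not to penalise flatness.
#' 2. No systematic upward or downward trend over the last six sessions. By
#'    default this is operationalised as a two-sided t-test on the
#'    least-squares slope being non-significant at `alpha`; set
#'    `trend_method = "monotone"` to instead fail only a strictly monotone
#'    run of six.
#' 3. The mean over the last six sessions differs from the mean over the
#'    preceding six by no more than `max_percent_diff` per cent (of the
#'    preceding-six mean).
#'
#' @param session_means Ordered numeric vector of per-session mean AE
#'   requirements, J.
#' @param min_sessions Minimum series length required (never below 12, since
#'   criterion 3 needs two six-session windows).
#' @param trend_method `"ttest"` (default) or `"monotone"`.
#' @param alpha Significance level for the slope test.
#' @param max_percent_diff Criterion-3 threshold, per cent.
#'
#' @return A one-row tibble: `criterion1_pass`, `criterion2_pass`,
#'   `criterion3_pass`, `pass`, `last6_mean`, `prev6_mean`, `percent_diff`,
#'   `trend_slope` (J per session), `trend_p`.
#' @examples
#' stability_check(rep(0.02, 20))$pass
#' @export
stability_check <- function(session_means, min_sessions = 12L,
                            trend_method = c("ttest", "monotone"),
                            alpha = 0.05, max_percent_diff = 7.5) {
  trend_method <- arg_match(trend_method)
  n <- length(session_means)
  if (n < max(min_sessions, 12L)) {
    ae_abort(paste0("Stability needs at least ", max(min_sessions, 12L),
                    " sessions; got ", n, "."),
             "aeforage_error_insufficient_data")
  }
  last6 <- session_means[(n - 5):n]
  prev6 <- session_means[(n - 11):(n - 6)]

  mx <- max(session_means)
  mn <- min(session_means)
  c1 <- if (mx == mn) TRUE else !any(last6 == mx) && !any(last6 == mn)

  xx <- seq_len(6)
  slope <- stats::cov(xx, last6) / stats::var(xx)
  fitted <- mean(last6) + slope * (xx - mean(xx))
  rss <- sum((last6 - fitted)^2)
  se <- sqrt(rss / 4 / (stats::var(xx) * 5))
  if (se == 0) {
    trend_p <- if (slope == 0) 1 else 0
  } else {
    trend_p <- 2 * stats::pt(-abs(slope / se), df = 4)
  }
  c2 <- if (trend_method == "ttest") {
    trend_p >= alpha
  } else {
    d <- diff(last6)
    !(all(d > 0) || all(d < 0))
  }

  l6 <- mean(last6)
  p6 <- mean(prev6)
  pd <- 100 * abs(l6 - p6) / p6
  # a series sitting exactly on the threshold passes; guard the comparison
  # against floating-point representation of the window means
  c3 <- pd <= max_percent_diff || isTRUE(all.equal(pd, max_percent_diff))

  tibble(criterion1_pass = c1, criterion2_pass = c2, criterion3_pass = c3,
         pass = c1 && c2 && c3, last6_mean = l6, prev6_mean = p6,
         percent_diff = pd, trend_slope = slope, trend_p = trend_p)
}

#' Indifference point of a condition
#'
#' The titrated AE requirement at which the subject is equally likely to
#' choose the AE and FR alternatives, estimated as the arithmetic mean of
#' the per-session mean AE requirements over the condition's last six
#' sessions.
#'
#' @param session_means Ordered numeric vector of per-session mean AE
#'   requirements, J (length >= 6).
#' @return The indifference point, J.
#' @examples
#' indifference_point(c(0.01, 0.02, 0.03, 0.03, 0.02, 0.01)) # 0.02
#' @export
indifference_point <- function(session_means) {
  if (length(session_means) < 6) {
    ae_abort("Need at least 6 session means.",
             "aeforage_error_insufficient_data")
  }
  mean(session_means[(length(session_means) - 5):length(session_means)])
}

# NA-returning variant for summaries over conditions too short to define an
# indifference point (e.g. re-analysed fixture logs).
ip_or_na <- function(session_means) {
  if (length(session_means) >= 6) indifference_point(session_means)
  else NA_real_
}

#' Free-choice AE trials from the last sessions of a condition
#'
#' Extracts the trials on which the AE-schedule analytics (mean IRE, E/RFT)
#' are based: free-choice trials where the AE key was chosen, from the last
#' `last_n` sessions.
#'
#' @param x An `"ae_condition"`, a single `"ae_session"`, or a list of
#'   `"ae_session"` objects in session order.
#' @param last_n Number of final sessions to keep (default 6); `Inf` keeps
#'   all.
#' @return A tibble of trial rows (with the `ire_attempts` list-column).
#' @export
free_ae_trials <- function(x, last_n = 6) {
  sessions <- if (inherits(x, "ae_condition")) x$sessions
              else if (inherits(x, "ae_session")) list(x)
              else x
  keep <- seq_along(sessions)
  if (is.finite(last_n)) keep <- utils::tail(keep, last_n)
  out <- dplyr::bind_rows(lapply(sessions[keep], function(s) s$trials))
  if (nrow(out) == 0) {
    return(tibble(session_index = integer(), block = integer(),
                  trial = integer(), trial_type = character(),
                  chosen_schedule = character(), reinforced = logical(),
                  corrections_used = integer(), ae_requirement = numeric(),
                  ire_attempts = list()))
  }
  dplyr::filter(out, .data$trial_type == "free", .data$chosen_schedule == "AE")
}

#' Total energy per reinforcement (E/RFT)
#'
#' Partitions consecutive free-choice AE trials into runs terminated by a
#' reinforcer and sums the interresponse energies of *all* responses in each
#' run — failed attempts included — giving the total energy the subject
#' spent to earn one reinforcer. `e_per_rft` is the mean of these
#' per-reinforcement totals. Runs never span session boundaries, and
#' attempts after a session's last reinforcer belong to no completed
#' reinforcement and are dropped. If the input contains no reinforced trial
#' at all, `e_per_rft` is the total IRE of every attempt and
#' `n_reinforcers` is 0.
#'
#' @param trials A tibble of free-choice AE trials in trial order (see
#'   [free_ae_trials()]): columns `session_index`, `reinforced` and the
#'   `ire_attempts` list-column.
#' @return A one-row tibble: `e_per_rft` (J), `n_reinforcers`, and the
#'   list-column `run_totals` (per-reinforcement energy totals, J).
#' @examples
#' tr <- tibble::tibble(
#'   session_index = 1L, reinforced = c(FALSE, FALSE, TRUE),
#'   ire_attempts = lapply(c(0.01, 0.02, 0.05),
#'                         function(e) tibble::tibble(ire = e))
#' )
#' e_per_rft(tr) # 0.08 J over 1 reinforcer
#' @export
e_per_rft <- function(trials) {
  if (nrow(trials) == 0) {
    ae_abort("No AE trials: E/RFT is undefined.",
             "aeforage_error_undefined_statistic")
  }
  totals <- numeric(0)
  all_ire <- 0
  for (sess in unique(trials$session_index)) {
    rows <- trials[trials$session_index == sess, ]
    acc <- 0
    for (i in seq_len(nrow(rows))) {
      e <- sum(rows$ire_attempts[[i]]$ire)
      acc <- acc + e
      all_ire <- all_ire + e
      if (rows$reinforced[i]) {
        totals <- c(totals, acc)
        acc <- 0
      }
    }
  }
  if (length(totals) == 0) {
    tibble(e_per_rft = all_ire, n_reinforcers = 0L,
           run_totals = list(numeric(0)))
  } else {
    tibble(e_per_rft = mean(totals), n_reinforcers = length(totals),
           run_totals = list(totals))
  }
}

# All schedule-phase IREs of a set of AE trials, as one numeric vector.
ire_samples <- function(trials) {
  unlist(lapply(trials$ire_attempts, function(a) a$ire), use.names = FALSE)
}

# Series labels for an ordered vector of FR requirements: ascending up to
# and including the first occurrence of the maximum, descending after.
series_labels <- function(fr) {
  peak <- which.max(fr)
  ifelse(seq_along(fr) <= peak, "ascending", "descending")
}

#' Summarise the conditions of an experiment
#'
#' For each condition: the indifference point (mean AE requirement over the
#' last six sessions), the mean IRE and IRE samples of the last six
#' sessions' free-choice AE trials, and the total energy per reinforcement
#' ([e_per_rft()]). Across conditions it reports the Pearson correlation
#' between E/RFT and the AE requirement (the indifference point), and — when
#' at least three FR levels each have at least two replicates (an ascending
#' and a descending visit) — a Friedman test of the FR effect on the
#' indifference points with series as blocks.
#'
#' @param x An `"ae_experiment"` or a list of `"ae_condition"` objects in
#'   condition order.
#' @param last_n Number of final sessions per condition the trial-level
#'   statistics use.
#' @return An object of class `"ae_summaries"`: `summaries` (tibble, one row
#'   per condition with `fr_requirement`, `series`, `indifference_point`,
#'   `mean_ire`, `n_ire`, `e_per_rft`, `n_reinforcers`, `n_sessions` and the
#'   list-column `ire_samples`), `correlation` (list with `r`, `p`, or
#'   `NULL` when fewer than three conditions exist), `friedman` (an
#'   `htest`, or `NULL`).
#' @export
condition_summaries <- function(x, last_n = 6) {
  conds <- if (inherits(x, "ae_experiment")) x$conditions else x
  if (length(conds) < 1) {
    ae_abort("Need at least one condition.", "aeforage_error_invalid_argument")
  }
  fr <- vapply(conds, function(cc) cc$fr_requirement, numeric(1))
  series <- series_labels(fr)
  rows <- purrr::imap(conds, function(cc, i) {
    tr <- free_ae_trials(cc, last_n = last_n)
    ires <- ire_samples(tr)
    ert <- if (nrow(tr)) e_per_rft(tr) else
      tibble(e_per_rft = NA_real_, n_reinforcers = 0L,
             run_totals = list(numeric(0)))
    tibble(
      condition_index = i,
      condition_label = cc$condition_label,
      fr_requirement = cc$fr_requirement,
      series = series[i],
      n_sessions = cc$n_sessions,
      indifference_point =
        if (nrow(cc$session_means) >= 6)
          indifference_point(cc$session_means$mean_ae_requirement)
        else NA_real_,
      mean_ire = if (length(ires)) mean(ires) else NA_real_,
      n_ire = length(ires),
      e_per_rft = ert$e_per_rft,
      n_reinforcers = ert$n_reinforcers,
      ire_samples = list(ires)
    )
  })
  summaries <- dplyr::bind_rows(rows)

  correlation <- NULL
  ok <- stats::complete.cases(summaries[, c("e_per_rft", "indifference_point")])
  if (sum(ok) >= 3) {
    ct <- stats::cor.test(summaries$indifference_point[ok],
                          summaries$e_per_rft[ok], method = "pearson")
    correlation <- list(r = unname(ct$estimate), p = ct$p.value,
                        n = sum(ok))
  }

  friedman <- NULL
  reps <- table(summaries$fr_requirement)
  if (length(reps) >= 3 && all(reps >= 2)) {
    wide <- summaries |>
      dplyr::group_by(.data$fr_requirement, .data$series) |>
      dplyr::summarise(ip = mean(.data$indifference_point), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "fr_requirement", values_from = "ip")
    m <- as.matrix(wide[, -1])
    if (!anyNA(m) && nrow(m) >= 2) {
      friedman <- stats::friedman.test(m)
    }
  }

  structure(list(summaries = summaries, correlation = correlation,
                 friedman = friedman),
            class = "ae_summaries")
}

#' @export
print.ae_summaries <- function(x, ...) {
  cat("<ae_summaries> ", nrow(x$summaries), " conditions\n", sep = "")
  print(dplyr::select(x$summaries, -"ire_samples"))
  if (!is.null(x$correlation)) {
    cat(sprintf("E/RFT vs AE requirement: Pearson r = %.3f (p = %.3g, n = %d)\n",
                x$correlation$r, x$correlation$p, x$correlation$n))
  } else {
    cat("E/RFT vs AE requirement correlation: not defined (< 3 conditions)\n")
  }
  if (!is.null(x$friedman)) {
    cat(sprintf("Friedman test of FR effect: chi^2 = %.3f, df = %d, p = %.3g\n",
                unname(x$friedman$statistic), unname(x$friedman$parameter),
                x$friedman$p.value))
  }
  invisible(x)
}

#' @export
tidy.ae_summaries <- function(x, ...) {
  dplyr::select(x$summaries, -"ire_samples")
}

#' @export
glance.ae_summaries <- function(x, ...) {
  tibble(
    n_conditions = nrow(x$summaries),
    e_rft_requirement_r = if (is.null(x$correlation)) NA_real_
                          else x$correlation$r,
    e_rft_requirement_p = if (is.null(x$correlation)) NA_real_
                          else x$correlation$p,
    friedman_chisq = if (is.null(x$friedman)) NA_real_
                     else unname(x$friedman$statistic),
    friedman_p = if (is.null(x$friedman)) NA_real_ else x$friedman$p.value
  )
}
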