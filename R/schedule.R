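#' Schedule configuration
#'
#' Parameters of the adjusting-energy (AE) vs fixed-ratio (FR) titration
#' procedure. Defaults reproduce the standard session: 60 trials (or a 90-min
#' cap, whichever comes first) divided into 15 blocks of four trials — two
#' forced-choice trials covering the left (AE) and right (FR) keys in
#' pseudorandom order, then two free-choice trials. After each completed
#' block the AE requirement moves by `ae_step` (up if both free choices were
#' AE, down if both were FR, unchanged on a split), never below `ae_floor`.
#' Forced AE trials that fail the requirement re-run the AE schedule phase as
#' correction trials after the intertrial interval, at most
#' `max_correction_trials` times. Conditions run for at least
#' `min_sessions_per_condition` sessions and then until the stability
#' criteria pass (see [stability_check()]).
#'
#' @param fr_requirement FR response count, positive integer.
#' @param ae_step Titration step, J.
#' @param ae_floor Lower bound on the AE requirement, J; the requirement is
#'   clipped here so the schedule never becomes vacuous.
#' @param iti Intertrial interval, s.
#' @param max_correction_trials Maximum correction trials on a forced AE
#'   trial.
#' @param trials_per_session Trials per session; must be divisible by
#'   `block_size`.
#' @param session_time_cap Session duration cap, s.
#' @param block_size Trials per block (even; half forced, half free).
#' @param reinforcer_duration Hopper access per reinforcer, s.
#' @param min_sessions_per_condition Minimum sessions before stability is
#'   assessed.
#'
#' @return A list of class `"ae_schedule_config"`.
#' @examples
#' schedule_config(fr_requirement = 30)
#' @export
schedule_config <- function(fr_requirement = 15,
                            ae_step = 0.001,
                            ae_floor = 0.001,
                            iti = 3,
                            max_correction_trials = 5,
                            trials_per_session = 60,
                            session_time_cap = 5400,
                            block_size = 4,
                            reinforcer_duration = 4,
                            min_sessions_per_condition = 18) {
  counts <- c(fr_requirement = fr_requirement,
              max_correction_trials = max_correction_trials,
              trials_per_session = trials_per_session,
              block_size = block_size,
              min_sessions_per_condition = min_sessions_per_condition)
  if (any(counts <= 0) || any(counts != round(counts))) {
    ae_abort("All count parameters must be positive integers.",
             "aeforage_error_invalid_argument")
  }
  if (ae_step < 0) {
    ae_abort("`ae_step` must be non-negative.", "aeforage_error_invalid_argument")
  }
  if (ae_floor < 0) {
    ae_abort("`ae_floor` must be non-negative.", "aeforage_error_invalid_argument")
  }
  if (block_size %% 2 != 0) {
    ae_abort("`block_size` must be even (half forced, half free).",
             "aeforage_error_invalid_argument")
  }
  if (trials_per_session %% block_size != 0) {
    ae_abort("`trials_per_session` must be divisible by `block_size`.",
             "aeforage_error_invalid_argument")
  }
  if (iti < 0 || reinforcer_duration < 0 || session_time_cap < 0) {
    ae_abort("Durations must be non-negative.", "aeforage_error_invalid_argument")
  }
  structure(
    list(fr_requirement = as.integer(fr_requirement), ae_step = ae_step,
         ae_floor = ae_floor, iti = iti,
         max_correction_trials = as.integer(max_correction_trials),
         trials_per_session = as.integer(trials_per_session),
         session_time_cap = session_time_cap,
         block_size = as.integer(block_size),
         reinforcer_duration = reinforcer_duration,
         min_sessions_per_condition = as.integer(min_sessions_per_condition)),
    class = "ae_schedule_config"
  )
}

#' Apply the block-wise AE titration rule
#'
#' Given the two free-choice outcomes of one completed block, returns the AE
#' requirement for the next block: both AE raises it by `ae_step`, both FR
#' lowers it by `ae_step` (clipped at `ae_floor`), a split leaves it
#' unchanged. Adjustments only happen between blocks, never mid-block, and
#' the rule also carries from the final block of one session into the first
#' block of the next.
#'
#' @param free_choices Character vector of exactly two elements, each `"AE"`
#'   or `"FR"`, in trial order.
#' @param ae_requirement Requirement in effect during the block, J.
#' @param ae_step Titration step, J.
#' @param ae_floor Lower clip, J.
#' @return The new requirement, J.
#' @examples
#' apply_ae_adjustment(c("AE", "AE"), 0.030) # 0.031
#' apply_ae_adjustment(c("FR", "FR"), 0.030) # 0.029
#' apply_ae_adjustment(c("AE", "FR"), 0.030) # 0.030
#' @export
apply_ae_adjustment <- function(free_choices, ae_requirement,
                                ae_step = 0.001, ae_floor = 0.001) {
  if (length(free_choices) != 2 || !all(free_choices %in% c("AE", "FR"))) {
    ae_abort("`free_choices` must be exactly two outcomes, each \"AE\" or \"FR\" (one completed block).",
             "aeforage_error_state")
  }
  n_ae <- sum(free_choices == "AE")
  if (n_ae == 2) ae_requirement + ae_step
  else if (n_ae == 0) max(ae_requirement - ae_step, ae_floor)
  else ae_requirement
}

# --- internal trial simulation -------------------------------------------

# Raw peck pair as plain vectors (hot path; the exported draw_peck_pair
# wraps this in a tibble).
draw_pair_raw <- function(agent, clock, geometry, ae_requirement) {
  if (!is.null(agent$pair_fun)) {
    d <- agent$pair_fun(agent, clock, geometry, ae_requirement)
    return(list(x = as.numeric(d$x), y = as.numeric(d$y), t = as.numeric(d$t)))
  }
  gaps <- rlnorm(2, agent$irt_meanlog, agent$irt_sdlog)
  pts <- sample_points(agent, 2, geometry, ae_requirement)
  list(x = unname(pts[, "x"]), y = unname(pts[, "y"]), t = clock + cumsum(gaps))
}

check_inside <- function(x, y, geometry) {
  r <- geometry$response_area_diameter / 2
  if (any(x^2 + y^2 > r^2 + 1e-12)) {
    ae_abort("Agent produced a peck outside the response area.",
             "aeforage_error_invalid_behavior")
  }
}

# One trial of the discrete-event machine. Returns plain lists for speed;
# run_session() assembles tibbles once per session.
sim_trial <- function(agent, trial_type, ae_requirement, config, geometry,
                      clock, free_index = 1L) {
  chosen <- switch(trial_type,
    "forced-left"  = "AE",
    "forced-right" = "FR",
    "free" = choose_schedule(agent, ae_requirement, config$fr_requirement,
                             free_index),
    ae_abort(paste0("Unknown trial type: '", trial_type, "'."),
             "aeforage_error_invalid_argument")
  )
  t_start <- clock
  clock <- clock + agent$choice_latency
  kc <- key_center(geometry, if (chosen == "AE") "left" else "right")

  ev_kind <- "choice"; ev_x <- unname(kc["x"]); ev_y <- unname(kc["y"])
  ev_t <- clock; ev_attempt <- NA_integer_

  reinforced <- FALSE
  attempts <- NULL # rows: ird, irt, ire

  if (chosen == "FR") {
    n <- config$fr_requirement
    gaps <- rlnorm(n, agent$irt_meanlog, agent$irt_sdlog)
    pts <- sample_points(agent, n, geometry)
    check_inside(pts[, "x"], pts[, "y"], geometry)
    ts <- clock + cumsum(gaps)
    ev_kind <- c(ev_kind, rep("peck", n))
    ev_x <- c(ev_x, pts[, "x"]); ev_y <- c(ev_y, pts[, "y"])
    ev_t <- c(ev_t, ts); ev_attempt <- c(ev_attempt, rep(NA_integer_, n))
    clock <- ts[n]
    reinforced <- TRUE
  } else {
    # AE schedule phase: one peck pair per attempt; forced trials get up to
    # max_correction_trials re-runs after the ITI.
    max_attempts <- if (trial_type == "free") 1L else
      1L + config$max_correction_trials
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      pr <- draw_pair_raw(agent, clock, geometry, ae_requirement)
      check_inside(pr$x, pr$y, geometry)
      irt <- pr$t[2] - pr$t[1]
      if (!is.finite(irt) || irt <= 0) {
        ae_abort("Agent produced a non-increasing peck pair.",
                 "aeforage_error_invalid_behavior")
      }
      ird <- sqrt((pr$x[2] - pr$x[1])^2 + (pr$y[2] - pr$y[1])^2)
      ire <- ird^2 / irt^2
      attempts <- rbind(attempts, c(ird = ird, irt = irt, ire = ire))
      ev_kind <- c(ev_kind, "peck", "peck")
      ev_x <- c(ev_x, pr$x); ev_y <- c(ev_y, pr$y); ev_t <- c(ev_t, pr$t)
      ev_attempt <- c(ev_attempt, attempt, attempt)
      clock <- pr$t[2]
      if (ire > ae_requirement) {
        reinforced <- TRUE
        break
      }
      if (attempt >= max_attempts) break
      # failed forced attempt: ITI, then the schedule phase re-runs
      ev_kind <- c(ev_kind, "iti"); ev_x <- c(ev_x, NA_real_)
      ev_y <- c(ev_y, NA_real_); ev_t <- c(ev_t, clock)
      ev_attempt <- c(ev_attempt, NA_integer_)
      clock <- clock + config$iti
    }
  }
  corrections <- if (chosen == "AE") nrow(attempts) - 1L else 0L

  if (reinforced) {
    ev_kind <- c(ev_kind, "reinforcer"); ev_x <- c(ev_x, NA_real_)
    ev_y <- c(ev_y, NA_real_); ev_t <- c(ev_t, clock)
    ev_attempt <- c(ev_attempt, NA_integer_)
    clock <- clock + config$reinforcer_duration
  }
  ev_kind <- c(ev_kind, "iti"); ev_x <- c(ev_x, NA_real_)
  ev_y <- c(ev_y, NA_real_); ev_t <- c(ev_t, clock)
  ev_attempt <- c(ev_attempt, NA_integer_)
  clock <- clock + config$iti

  list(trial_type = trial_type, chosen = chosen, reinforced = reinforced,
       corrections = corrections, ae_requirement = ae_requirement,
       attempts = attempts, t_start = t_start, t_end = clock,
       ev = list(kind = ev_kind, x = ev_x, y = ev_y, t = ev_t,
                 attempt = ev_attempt))
}

attempts_tibble <- function(m) {
  if (is.null(m)) {
    tibble(ird = numeric(), irt = numeric(), ire = numeric())
  } else {
    tibble(ird = m[, "ird"], irt = m[, "irt"], ire = m[, "ire"])
  }
}

#' Run a single trial
#'
#' Runs one trial of the adjusting procedure — choice phase, then the FR or
#' AE schedule phase (with correction trials on forced AE failures), the
#' reinforcer, and the intertrial interval — using the current RNG stream.
#'
#' @param agent An [ae_agent].
#' @param trial_type `"forced-left"` (AE key only), `"forced-right"` (FR key
#'   only) or `"free"` (both keys; the agent chooses).
#' @param ae_requirement AE requirement in effect, J.
#' @param config A [schedule_config()].
#' @param geometry A [chamber_geometry()].
#' @param clock Simulated time at trial onset, s.
#' @param free_index Index of this free-choice trial within the session.
#'
#' @return A one-row tibble: `trial_type`, `chosen_schedule`, `reinforced`,
#'   `corrections_used`, `ae_requirement`, `n_attempts`, `t_start`, `t_end`,
#'   and list-columns `ire_attempts` (one row per AE schedule-phase attempt:
#'   `ird`, `irt`, `ire`) and `events` (per-event rows).
#' @export
run_trial <- function(agent, trial_type, ae_requirement,
                      config = schedule_config(),
                      geometry = chamber_geometry(), clock = 0,
                      free_index = 1L) {
  if (clock >= config$session_time_cap) {
    ae_abort("`clock` is already past the session time cap.",
             "aeforage_error_invalid_argument")
  }
  tr <- sim_trial(agent, trial_type, ae_requirement, config, geometry,
                  clock, free_index)
  tibble(
    trial_type = tr$trial_type, chosen_schedule = tr$chosen,
    reinforced = tr$reinforced, corrections_used = tr$corrections,
    ae_requirement = tr$ae_requirement,
    n_attempts = if (is.null(tr$attempts)) 0L else nrow(tr$attempts),
    t_start = tr$t_start, t_end = tr$t_end,
    ire_attempts = list(attempts_tibble(tr$attempts)),
    events = list(tibble(event_kind = tr$ev$kind, x = tr$ev$x, y = tr$ev$y,
                         t = tr$ev$t, attempt = tr$ev$attempt))
  )
}

# Deterministic per-session RNG stream derived from (master seed, condition
# index, session index); all factors stay below 2^31 so the arithmetic is
# exact in doubles.
derive_seed <- function(seed, condition_index, session_index) {
  s <- as.numeric(seed) %% 2147483629
  as.integer((s * 69069 + condition_index * 30011 + session_index * 2971) %%
               2147483629) + 1L
}

#' Run one session of the adjusting procedure
#'
#' Runs blocks of (forced, forced, free, free, ...) trials until the trial
#' count or the session time cap is reached. The two forced trials of each
#' block cover the left and right keys in pseudorandom order. After each
#' completed block the AE requirement is adjusted from the block's two
#' free-choice outcomes ([apply_ae_adjustment()]); an incomplete final block
#' (time cap) produces no adjustment. The requirement that would govern the
#' next block is recorded as `next_start` for cross-session carryover.
#'
#' @inheritParams run_trial
#' @param ae_start Requirement in effect for the first block, J (>=
#'   `ae_floor`).
#' @param seed Integer seed for this session's RNG stream.
#' @param session_index,condition_label Bookkeeping stored in the log.
#'
#' @return An object of class `"ae_session"`: a list with `trials` (tibble,
#'   one row per trial), `events` (flat tibble, one row per event),
#'   `mean_ae_requirement` (mean of the per-trial requirement),
#'   `final_block_requirement`, `next_start`, and indices/seed.
#' @examples
#' s <- run_session(agent_alternating(), schedule_config(), ae_start = 0.01,
#'                  seed = 1)
#' s$mean_ae_requirement
#' @export
run_session <- function(agent, config = schedule_config(), ae_start = 0.010,
                        seed = 1L, geometry = chamber_geometry(),
                        session_index = 1L, condition_label = "") {
  if (ae_start < config$ae_floor) {
    ae_abort("`ae_start` must be at least `ae_floor`.",
             "aeforage_error_invalid_argument")
  }
  set.seed(seed)
  req <- ae_start
  n_blocks <- config$trials_per_session %/% config$block_size
  n_forced <- config$block_size %/% 2L
  clock <- 0
  trial_idx <- 0L
  free_count <- 0L
  trials <- vector("list", config$trials_per_session)
  blocks_completed <- 0L
  final_block_req <- NA_real_
  next_start <- ae_start
  history <- list()

  for (b in seq_len(n_blocks)) {
    if (clock >= config$session_time_cap) break
    sides <- rep_len(sample(c("forced-left", "forced-right")), n_forced)
    types <- c(sides, rep("free", config$block_size - n_forced))
    block_choices <- character(0)
    block_complete <- TRUE
    for (ty in types) {
      if (clock >= config$session_time_cap) {
        block_complete <- FALSE
        break
      }
      if (ty == "free") free_count <- free_count + 1L
      tr <- sim_trial(agent, ty, req, config, geometry, clock, free_count)
      clock <- tr$t_end
      trial_idx <- trial_idx + 1L
      tr$block <- b
      tr$trial <- trial_idx
      trials[[trial_idx]] <- tr
      if (ty == "free") block_choices <- c(block_choices, tr$chosen)
    }
    if (block_complete) {
      blocks_completed <- b
      final_block_req <- req
      req <- apply_ae_adjustment(block_choices, req, config$ae_step,
                                 config$ae_floor)
      history[[length(history) + 1L]] <- c(block = b, requirement = req)
      next_start <- req
    } else {
      break
    }
  }

  trials <- trials[seq_len(trial_idx)]
  trials_tb <- tibble(
    session_index = session_index,
    block = vapply(trials, `[[`, integer(1), "block"),
    trial = vapply(trials, `[[`, integer(1), "trial"),
    trial_type = vapply(trials, `[[`, character(1), "trial_type"),
    chosen_schedule = vapply(trials, `[[`, character(1), "chosen"),
    reinforced = vapply(trials, `[[`, logical(1), "reinforced"),
    corrections_used = vapply(trials, `[[`, integer(1), "corrections"),
    ae_requirement = vapply(trials, `[[`, numeric(1), "ae_requirement"),
    t_start = vapply(trials, `[[`, numeric(1), "t_start"),
    t_end = vapply(trials, `[[`, numeric(1), "t_end"),
    ire_attempts = lapply(trials, function(tr) attempts_tibble(tr$attempts))
  )
  ev_n <- vapply(trials, function(tr) length(tr$ev$kind), integer(1))
  events_tb <- tibble(
    session_index = session_index,
    block = rep(trials_tb$block, ev_n),
    trial = rep(trials_tb$trial, ev_n),
    trial_type = rep(trials_tb$trial_type, ev_n),
    chosen_schedule = rep(trials_tb$chosen_schedule, ev_n),
    event_kind = unlist(lapply(trials, function(tr) tr$ev$kind)) %||%
      character(0),
    attempt = unlist(lapply(trials, function(tr) tr$ev$attempt)) %||%
      integer(0),
    x = unlist(lapply(trials, function(tr) tr$ev$x)) %||% numeric(0),
    y = unlist(lapply(trials, function(tr) tr$ev$y)) %||% numeric(0),
    t = unlist(lapply(trials, function(tr) tr$ev$t)) %||% numeric(0),
    ae_requirement = rep(trials_tb$ae_requirement, ev_n),
    reinforced = rep(trials_tb$reinforced, ev_n),
    corrections_used = rep(trials_tb$corrections_used, ev_n)
  )

  structure(
    list(
      trials = trials_tb,
      events = events_tb,
      session_index = as.integer(session_index),
      condition_label = condition_label,
      fr_requirement = config$fr_requirement,
      ae_start = ae_start,
      mean_ae_requirement = if (trial_idx) mean(trials_tb$ae_requirement)
                            else NA_real_,
      final_block_requirement = final_block_req,
      next_start = next_start,
      blocks_completed = blocks_completed,
      adjustment_history = history,
      rng_seed = as.integer(seed)
    ),
    class = "ae_session"
  )
}

#' @export
print.ae_session <- function(x, ...) {
  cat("<ae_session> ", x$condition_label,
      " session ", x$session_index, ": ", nrow(x$trials), " trials, ",
      x$blocks_completed, " blocks; mean AE requirement ",
      signif(x$mean_ae_requirement, 4), " J\n", sep = "")
  invisible(x)
}

#' @export
tidy.ae_session <- function(x, ...) x$trials

#' @export
glance.ae_session <- function(x, ...) {
  tibble(session_index = x$session_index,
         condition_label = x$condition_label,
         fr_requirement = x$fr_requirement,
         n_trials = nrow(x$trials),
         blocks_completed = x$blocks_completed,
         n_reinforcers = sum(x$trials$reinforced),
         ae_start = x$ae_start,
         mean_ae_requirement = x$mean_ae_requirement,
         final_block_requirement = x$final_block_requirement,
         next_start = x$next_start)
}

#' Run a condition (a chained series of sessions)
#'
#' Chains sessions, carrying each session's post-adjustment final-block
#' requirement into the next session's start. After
#' `min_sessions_per_condition` sessions the condition terminates at the
#' first session where [stability_check()] passes on the per-session mean AE
#' requirements. A hard session cap guards against non-termination: reaching
#' it raises a condition-not-stable error that carries the partial logs in
#' its `logs` field.
#'
#' @inheritParams run_session
#' @param n_sessions If given, run exactly this many sessions and skip the
#'   stability rule (useful for fixed-length simulations).
#' @param max_sessions Hard cap on sessions per condition.
#' @param condition_index Position of this condition in the experiment
#'   (seeds each session's RNG stream together with `seed`).
#' @param trend_method Passed to [stability_check()].
#'
#' @return An object of class `"ae_condition"`: `sessions` (list of
#'   `"ae_session"`), `session_means` (tibble), `stability` (the passing
#'   report, or the last one computed), `stable`, `fr_requirement`,
#'   `condition_label`, `next_start` for cross-condition carryover.
#' @export
run_condition <- function(agent, config = schedule_config(),
                          ae_start = 0.010, seed = 1L,
                          geometry = chamber_geometry(),
                          condition_label = paste0("FR", config$fr_requirement),
                          condition_index = 1L,
                          n_sessions = NULL, max_sessions = 200L,
                          trend_method = c("ttest", "monotone")) {
  trend_method <- arg_match(trend_method)
  sessions <- list()
  means <- numeric(0)
  start <- ae_start
  stable <- FALSE
  report <- NULL
  s <- 0L
  repeat {
    s <- s + 1L
    ses <- run_session(agent, config, ae_start = start,
                       seed = derive_seed(seed, condition_index, s),
                       geometry = geometry, session_index = s,
                       condition_label = condition_label)
    sessions[[s]] <- ses
    means[s] <- ses$mean_ae_requirement
    start <- ses$next_start
    if (!is.null(n_sessions)) {
      if (s >= n_sessions) break
    } else {
      if (s >= max(config$min_sessions_per_condition, 12L)) {
        report <- stability_check(means, trend_method = trend_method)
        if (report$pass) {
          stable <- TRUE
          break
        }
      }
      if (s >= max_sessions) {
        cnd <- rlang::error_cnd(
          class = c("aeforage_error_condition_not_stable", "aeforage_error"),
          message = paste0("Condition did not stabilise within ",
                           max_sessions, " sessions."),
          logs = sessions
        )
        rlang::cnd_signal(cnd)
      }
    }
  }
  structure(
    list(
      sessions = sessions,
      session_means = tibble(session_index = seq_along(means),
                             mean_ae_requirement = means),
      stability = report,
      stable = stable,
      fr_requirement = config$fr_requirement,
      condition_label = condition_label,
      condition_index = as.integer(condition_index),
      ae_start = ae_start,
      next_start = start,
      n_sessions = s,
      seed = as.integer(seed),
      config = config
    ),
    class = "ae_condition"
  )
}

#' @export
print.ae_condition <- function(x, ...) {
  cat("<ae_condition> ", x$condition_label, ": ", x$n_sessions, " sessions",
      if (x$stable) " (stable)" else "", "; indifference point ",
      signif(ip_or_na(x$session_means$mean_ae_requirement), 4),
      " J\n", sep = "")
  invisible(x)
}

#' @export
tidy.ae_condition <- function(x, ...) {
  dplyr::mutate(x$session_means,
                condition_label = x$condition_label,
                fr_requirement = x$fr_requirement,
                .before = 1)
}

#' @export
glance.ae_condition <- function(x, ...) {
  tibble(condition_label = x$condition_label,
         fr_requirement = x$fr_requirement,
         n_sessions = x$n_sessions,
         stable = x$stable,
         ae_start = x$ae_start,
         indifference_point = ip_or_na(x$session_means$mean_ae_requirement))
}

#' Run a full experiment from a configuration
#'
#' Runs the configured sequence of FR conditions (by default the ascending
#' then descending series 15, 30, 60, 30, 15), each to stability. When
#' `carryover_conditions` is set, each condition starts at the previous
#' condition's carried requirement; otherwise every condition starts at
#' `ae_start`.
#'
#' @param config An `"ae_config"` from [load_config()] or
#'   [experiment_config()].
#'
#' @return An object of class `"ae_experiment"`: a list with `conditions`
#'   (list of `"ae_condition"`) and the config.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "ae_config"))
  conds <- vector("list", length(config$conditions))
  start <- config$ae_start
  for (i in seq_along(config$conditions)) {
    fr <- config$conditions[i]
    sc <- config$schedule
    sc$fr_requirement <- as.integer(fr)
    conds[[i]] <- run_condition(
      config$agent, sc, ae_start = start, seed = config$seed,
      geometry = config$geometry,
      condition_label = paste0("FR", fr, "#", i),
      condition_index = i, max_sessions = config$max_sessions
    )
    if (config$carryover_conditions) start <- conds[[i]]$next_start
  }
  structure(list(conditions = conds, config = config),
            class = "ae_experiment")
}

#' @export
print.ae_experiment <- function(x, ...) {
  cat("<ae_experiment> ", length(x$conditions), " conditions (FR ",
      paste(x$config$conditions, collapse = ", "), ")\n", sep = "")
  for (cond in x$conditions) print(cond)
  invisible(x)
}

#' @export
tidy.ae_experiment <- function(x, ...) {
  dplyr::bind_rows(lapply(x$conditions, tidy))
}

#' @export
glance.ae_experiment <- function(x, ...) {
  dplyr::bind_rows(lapply(x$conditions, glance))
}
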