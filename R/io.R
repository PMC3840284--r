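LOG_VERSION <- "# aeforage-log v1"

log_col_types <- readr::cols(
  condition_label = readr::col_character(),
  fr_requirement = readr::col_integer(),
  session_index = readr::col_integer(),
  rng_seed = readr::col_integer(),
  ae_start = readr::col_double(),
  next_start = readr::col_double(),
  final_block_requirement = readr::col_double(),
  blocks_completed = readr::col_integer(),
  block = readr::col_integer(),
  trial = readr::col_integer(),
  trial_type = readr::col_character(),
  chosen_schedule = readr::col_character(),
  event_kind = readr::col_character(),
  attempt = readr::col_integer(),
  x = readr::col_double(),
  y = readr::col_double(),
  t = readr::col_double(),
  ae_requirement = readr::col_double(),
  reinforced = readr::col_logical(),
  corrections_used = readr::col_integer()
)

#' Programmatic experiment configuration
#'
#' Builds the same configuration object as [load_config()], from R. The
#' default condition order is the ascending-then-descending FR series 15,
#' 30, 60, 30, 15.
#'
#' @param seed Master seed; every RNG stream in the experiment derives from
#'   it.
#' @param conditions Ordered vector of FR requirements, one per condition.
#' @param ae_start Starting AE requirement of the first session, J. The
#'   published procedure does not state it; 0.010 J sits inside the band
#'   titrations typically traverse.
#' @param schedule A [schedule_config()].
#' @param geometry A [chamber_geometry()].
#' @param agent An [ae_agent].
#' @param carryover_conditions Carry the titrated requirement from each
#'   condition into the next (otherwise every condition restarts at
#'   `ae_start`).
#' @param max_sessions Hard per-condition session cap.
#' @param output_dir Where the CLI writes logs.
#' @return A list of class `"ae_config"`.
#' @export
experiment_config <- function(seed = 1L,
                              conditions = c(15, 30, 60, 30, 15),
                              ae_start = 0.010,
                              schedule = schedule_config(),
                              geometry = chamber_geometry(),
                              agent = agent_stationary(),
                              carryover_conditions = TRUE,
                              max_sessions = 200L,
                              output_dir = "logs") {
  if (length(conditions) < 1) {
    ae_abort("`conditions` must be non-empty.", "aeforage_error_config")
  }
  if (any(conditions <= 0) || any(conditions != round(conditions))) {
    ae_abort("`conditions` must be positive integer FR requirements.",
             "aeforage_error_config")
  }
  structure(
    list(seed = as.integer(seed), conditions = as.integer(conditions),
         ae_start = ae_start, schedule = schedule, geometry = geometry,
         agent = agent, carryover_conditions = isTRUE(carryover_conditions),
         max_sessions = as.integer(max_sessions), output_dir = output_dir),
    class = "ae_config"
  )
}

check_known_keys <- function(x, known, where) {
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    ae_abort(paste0("Unknown configuration key", if (length(extra) > 1) "s",
                    " in ", where, ": ",
                    paste0("'", extra, "'", collapse = ", "), "."),
             "aeforage_error_config")
  }
}

#' Load an experiment configuration from a YAML file
#'
#' Reads a human-readable configuration with the sections `schedule`,
#' `geometry` and `agent` plus the top-level keys `seed`, `conditions`,
#' `ae_start`, `carryover_conditions`, `max_sessions` and `output_dir`.
#' Every omitted key takes its documented default (see [schedule_config()],
#' [chamber_geometry()], [ae_agent]); unknown keys are rejected by name. The
#' agent section selects a preset via `preset:` (default `"stationary"`)
#' and may override its parameters; `a_star` may be a single number or a
#' map from FR requirement to indifference requirement.
#'
#' @param path Path to the YAML file.
#' @return A list of class `"ae_config"`.
#' @examples
#' cfg <- load_config(system.file("extdata", "example-config.yml",
#'                                package = "aeforage"))
#' cfg$conditions
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    ae_abort(paste0("Config file not found: ", path), "aeforage_error_config")
  }
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) {
    ae_abort("Config file must be a YAML mapping.", "aeforage_error_config")
  }
  check_known_keys(raw, c("seed", "conditions", "ae_start", "output_dir",
                          "carryover_conditions", "max_sessions", "schedule",
                          "geometry", "agent"), "top level")
  sched_args <- raw$schedule %||% list()
  check_known_keys(sched_args, names(formals(schedule_config)), "`schedule`")
  geom_args <- raw$geometry %||% list()
  check_known_keys(geom_args, names(formals(chamber_geometry)), "`geometry`")
  ag <- raw$agent %||% list()
  check_known_keys(ag, c("preset", "a_star", "tau", "irt_meanlog",
                         "irt_sdlog", "scatter", "scatter_sd",
                         "choice_latency", "adapt_reference"), "`agent`")
  preset <- ag$preset %||% "stationary"
  ag$preset <- NULL
  if (!is.null(ag$a_star) && is.list(ag$a_star)) {
    ag$a_star <- unlist(ag$a_star)
  }
  agent <- tryCatch(
    do.call(agent_preset, c(list(preset = preset), ag)),
    error = function(e) {
      if (inherits(e, "aeforage_error")) stop(e)
      ae_abort(paste0("Invalid `agent` section: ", conditionMessage(e)),
               "aeforage_error_config")
    }
  )
  wrap <- function(expr, where) {
    tryCatch(expr, aeforage_error = function(e) {
      ae_abort(paste0("Invalid `", where, "` section: ", conditionMessage(e)),
               "aeforage_error_config")
    })
  }
  experiment_config(
    seed = raw$seed %||% 1L,
    conditions = raw$conditions %||% c(15, 30, 60, 30, 15),
    ae_start = raw$ae_start %||% 0.010,
    schedule = wrap(do.call(schedule_config, sched_args), "schedule"),
    geometry = wrap(do.call(chamber_geometry, geom_args), "geometry"),
    agent = agent,
    carryover_conditions = raw$carryover_conditions %||% TRUE,
    max_sessions = raw$max_sessions %||% 200L,
    output_dir = raw$output_dir %||% "logs"
  )
}

collect_sessions <- function(x) {
  if (inherits(x, "ae_session")) return(list(x))
  if (inherits(x, "ae_condition")) return(x$sessions)
  if (inherits(x, "ae_experiment")) {
    return(unlist(lapply(x$conditions, function(cc) cc$sessions),
                  recursive = FALSE))
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "ae_session"))) {
    return(x)
  }
  ae_abort("Cannot extract sessions from this object.",
           "aeforage_error_invalid_argument")
}

session_event_rows <- function(s) {
  ev <- s$events
  tibble(
    condition_label = s$condition_label,
    fr_requirement = as.integer(s$fr_requirement),
    session_index = s$session_index,
    rng_seed = s$rng_seed,
    ae_start = s$ae_start,
    next_start = s$next_start,
    final_block_requirement = s$final_block_requirement,
    blocks_completed = s$blocks_completed,
    block = ev$block, trial = ev$trial, trial_type = ev$trial_type,
    chosen_schedule = ev$chosen_schedule, event_kind = ev$event_kind,
    attempt = ev$attempt, x = ev$x, y = ev$y, t = ev$t,
    ae_requirement = ev$ae_requirement, reinforced = ev$reinforced,
    corrections_used = ev$corrections_used
  )
}

#' Write and read session event logs
#'
#' Session logs are serialised as flat, versioned CSV: one row per event
#' (choice peck, schedule-phase peck, reinforcer, ITI onset) with the
#' session- and trial-level fields repeated on each row, so any trial can be
#' reconstructed from its rows alone. The first line stamps the schema
#' version; the reader rejects files with an unknown stamp. Doubles are
#' written at round-trip precision.
#'
#' `read_session_logs()` rebuilds the `"ae_session"` objects: per-trial
#' records (type, choice, reinforced flag, corrections, requirement), the
#' schedule-phase IRE attempts recomputed from the logged peck coordinates
#' and times, and the per-session summaries.
#'
#' @param x An `"ae_session"`, `"ae_condition"`, `"ae_experiment"`, or list
#'   of sessions.
#' @param path File path.
#' @return `write_session_logs()` returns `path` invisibly;
#'   `read_session_logs()` returns a list of `"ae_session"` objects in file
#'   order.
#' @export
write_session_logs <- function(x, path) {
  sessions <- collect_sessions(x)
  rows <- dplyr::bind_rows(lapply(sessions, session_event_rows))
  writeLines(LOG_VERSION, path)
  readr::write_csv(rows, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_session_logs
#' @export
read_session_logs <- function(path) {
  if (!file.exists(path)) {
    ae_abort(paste0("Log file not found: ", path), "aeforage_error_parse")
  }
  first <- readLines(path, n = 1)
  if (!identical(first, LOG_VERSION)) {
    ae_abort(paste0("Unknown log schema version: '", first, "'."),
             "aeforage_error_parse")
  }
  rows <- suppressWarnings(
    readr::read_csv(path, skip = 1, col_types = log_col_types,
                    progress = FALSE)
  )
  pr <- readr::problems(rows)
  if (nrow(pr) > 0) {
    ae_abort(paste0("Malformed log row at line ", pr$row[1] + 2, ": ",
                    pr$expected[1], " expected."),
             "aeforage_error_parse")
  }
  if (nrow(rows) == 0) return(list())
  miss <- setdiff(names(log_col_types$cols), names(rows))
  if (length(miss)) {
    ae_abort(paste0("Log file lacks column(s): ",
                    paste(miss, collapse = ", "), "."),
             "aeforage_error_parse")
  }
  key <- paste(rows$condition_label, rows$session_index, sep = "\r")
  lapply(split(rows, factor(key, levels = unique(key))), rebuild_session) |>
    unname()
}

rebuild_trial_attempts <- function(ev) {
  pk <- ev[ev$event_kind == "peck" & !is.na(ev$attempt), ]
  if (nrow(pk) == 0) {
    return(tibble(ird = numeric(), irt = numeric(), ire = numeric()))
  }
  pk <- pk[order(pk$attempt, pk$t), ]
  dplyr::bind_rows(lapply(split(pk, pk$attempt), function(a) {
    compute_ire(list(x = a$x[1], y = a$y[1], t = a$t[1]),
                list(x = a$x[2], y = a$y[2], t = a$t[2]))[, c("ird", "irt", "ire")]
  }))
}

rebuild_session <- function(rows) {
  per_trial <- rows |>
    dplyr::group_by(.data$trial) |>
    dplyr::summarise(
      session_index = .data$session_index[1],
      block = .data$block[1],
      trial_type = .data$trial_type[1],
      chosen_schedule = .data$chosen_schedule[1],
      reinforced = .data$reinforced[1],
      corrections_used = .data$corrections_used[1],
      ae_requirement = .data$ae_requirement[1],
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$trial)
  per_trial$ire_attempts <- lapply(
    per_trial$trial,
    function(tr) rebuild_trial_attempts(rows[rows$trial == tr, ])
  )
  per_trial <- dplyr::relocate(per_trial, "session_index", .before = "trial") |>
    dplyr::relocate("block", .after = "session_index")
  events <- rows[, c("session_index", "block", "trial", "trial_type",
                     "chosen_schedule", "event_kind", "attempt", "x", "y",
                     "t", "ae_requirement", "reinforced",
                     "corrections_used")]
  structure(
    list(
      trials = per_trial,
      events = events,
      session_index = rows$session_index[1],
      condition_label = rows$condition_label[1],
      fr_requirement = rows$fr_requirement[1],
      ae_start = rows$ae_start[1],
      mean_ae_requirement = mean(per_trial$ae_requirement),
      final_block_requirement = rows$final_block_requirement[1],
      next_start = rows$next_start[1],
      blocks_completed = rows$blocks_completed[1],
      adjustment_history = list(),
      rng_seed = rows$rng_seed[1]
    ),
    class = "ae_session"
  )
}

#' Group read-back sessions into condition objects
#'
#' Rebuilds minimal `"ae_condition"` objects (sessions, session means,
#' labels) from a flat list of sessions, grouping by condition label in
#' order of appearance. Useful after [read_session_logs()].
#'
#' @param sessions List of `"ae_session"` objects.
#' @return List of `"ae_condition"` objects.
#' @export
sessions_to_conditions <- function(sessions) {
  labs <- vapply(sessions, function(s) s$condition_label, character(1))
  lapply(unique(labs), function(lb) {
    ss <- sessions[labs == lb]
    means <- vapply(ss, function(s) s$mean_ae_requirement, numeric(1))
    structure(
      list(sessions = ss,
           session_means = tibble(session_index = seq_along(means),
                                  mean_ae_requirement = means),
           stability = NULL, stable = NA,
           fr_requirement = ss[[1]]$fr_requirement,
           condition_label = lb, condition_index = NA_integer_,
           ae_start = ss[[1]]$ae_start,
           next_start = ss[[length(ss)]]$next_start,
           n_sessions = length(ss), seed = NA_integer_, config = NULL),
      class = "ae_condition"
    )
  })
}

#' Deterministic fixture sessions for tests and demos
#'
#' Small, seeded single-session logs with hand-checkable structure: a
#' shortened session (five blocks of four trials, FR 5) driven by one of the
#' deterministic or stationary agent presets.
#'
#' @param preset `"always-ae"`, `"always-fr"`, `"alternating"` or
#'   `"stationary"`.
#' @param seed Session seed.
#' @param ae_start Starting requirement, J.
#' @return An `"ae_session"`.
#' @export
fixture_session <- function(preset = c("always-ae", "always-fr",
                                       "alternating", "stationary"),
                            seed = 1L, ae_start = 0.010) {
  preset <- arg_match(preset)
  cfg <- schedule_config(fr_requirement = 5, trials_per_session = 20)
  run_session(agent_preset(preset), cfg, ae_start = ae_start, seed = seed,
              condition_label = paste0("fixture-", preset))
}
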