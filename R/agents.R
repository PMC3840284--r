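#' Synthetic subjects for the adjusting-energy schedule
#'
#' Agents stand in for live subjects: they supply key choices at the choice
#' phase and peck kinematics (coordinates and interresponse times) at the
#' schedule phase. The stock agent chooses the AE key with logistic
#' probability `1 / (1 + exp((a - a_star) / tau))`, where `a` is the current
#' AE requirement, `a_star` the agent's indifference requirement and `tau` a
#' temperature; its interresponse times are lognormal and its peck locations
#' are scattered over the response area independently of the requirement
#' (a *stationary* agent, whose IRE distribution does not move as the
#' requirement is titrated).
#'
#' `a_star` may be a single value or a named numeric vector keyed by FR
#' requirement (e.g. `c("15" = 0.02, "30" = 0.04, "60" = 0.08)`); unlisted FR
#' levels are linearly interpolated. The default map is `a_star = N / 750`,
#' chosen so indifference points rise monotonically with the FR requirement
#' through the 0.01-0.1 J band that typical titrations occupy.
#'
#' Presets:
#' * `agent_stationary()` — logistic chooser, requirement-independent pecks.
#' * `agent_adaptive()` — logistic chooser whose peck scatter scales with the
#'   current requirement (IRE conditioned on requirement), for probing how
#'   weakly the schedule controls per-response energy.
#' * `agent_always_ae()`, `agent_always_fr()` — deterministic choosers.
#' * `agent_alternating()` — alternates AE and FR across free-choice trials,
#'   so the titrated requirement never moves: an immediately stable subject.
#' * `agent_custom()` — user-supplied choice and/or peck-pair functions, for
#'   deterministic tests.
#'
#' @param a_star Indifference requirement(s), J (>= 0): the AE requirement at
#'   which AE and FR are subjectively equal. Scalar, or named vector by FR.
#' @param tau Choice temperature, J (> 0); smaller is closer to a step rule.
#' @param irt_meanlog,irt_sdlog Lognormal parameters of the interresponse
#'   time, log-seconds and dimensionless.
#' @param scatter Peck-location rule: `"uniform"` (uniform over the response
#'   area) or `"gaussian"` (isotropic about the centre, truncated to the
#'   area).
#' @param scatter_sd Standard deviation of the gaussian scatter, m.
#' @param choice_latency Time from key onset to the choice peck, s.
#' @param adapt_reference For adaptive agents: the requirement, J, at which
#'   the scatter equals its nominal scale; scatter is multiplied by
#'   `sqrt(a / adapt_reference)` at requirement `a`.
#' @param choose_fun For `agent_custom()`: `function(agent, ae_requirement,
#'   fr_requirement, free_index)` returning `"AE"` or `"FR"`.
#' @param pair_fun For `agent_custom()`: `function(agent, clock, geometry,
#'   ae_requirement)` returning a two-row data frame with columns `x`, `y`,
#'   `t`.
#' @param ... Passed on to the shared constructor.
#'
#' @return An object of class `"ae_agent"`.
#' @examples
#' ag <- agent_stationary(a_star = 0.03, tau = 0.005)
#' choose_schedule(ag, ae_requirement = 0.03, fr_requirement = 30) # fair coin
#' @name ae_agent
NULL

new_agent <- function(choice_rule, a_star = NULL, tau = 0.005,
                      irt_meanlog = log(0.35), irt_sdlog = 0.4,
                      scatter = c("uniform", "gaussian"), scatter_sd = 0.03,
                      choice_latency = 0.5, adaptive = FALSE,
                      adapt_reference = 0.05,
                      choose_fun = NULL, pair_fun = NULL) {
  scatter <- arg_match(scatter)
  a_star <- a_star %||% (c(15, 30, 60) / 750)
  if (is.null(names(a_star)) && length(a_star) == 3 &&
      identical(a_star, c(15, 30, 60) / 750)) {
    names(a_star) <- c("15", "30", "60")
  }
  if (any(a_star < 0)) {
    ae_abort("`a_star` must be non-negative.", "aeforage_error_invalid_argument")
  }
  if (!is.numeric(tau) || tau <= 0) {
    ae_abort("`tau` must be positive.", "aeforage_error_invalid_argument")
  }
  if (irt_sdlog < 0) {
    ae_abort("`irt_sdlog` must be non-negative.", "aeforage_error_invalid_argument")
  }
  structure(
    list(
      choice_rule = choice_rule, a_star = a_star, tau = tau,
      irt_meanlog = irt_meanlog, irt_sdlog = irt_sdlog,
      scatter = scatter, scatter_sd = scatter_sd,
      choice_latency = choice_latency,
      adaptive = adaptive, adapt_reference = adapt_reference,
      choose_fun = choose_fun, pair_fun = pair_fun
    ),
    class = "ae_agent"
  )
}

#' @rdname ae_agent
#' @export
agent_stationary <- function(a_star = NULL, tau = 0.005, ...) {
  new_agent("logistic", a_star = a_star, tau = tau, ...)
}

#' @rdname ae_agent
#' @export
agent_adaptive <- function(a_star = NULL, tau = 0.005,
                           adapt_reference = 0.05, ...) {
  new_agent("logistic", a_star = a_star, tau = tau, adaptive = TRUE,
            adapt_reference = adapt_reference, ...)
}

#' @rdname ae_agent
#' @export
agent_always_ae <- function(...) new_agent("always_ae", ...)

#' @rdname ae_agent
#' @export
agent_always_fr <- function(...) new_agent("always_fr", ...)

#' @rdname ae_agent
#' @export
agent_alternating <- function(...) new_agent("alternating", ...)

#' @rdname ae_agent
#' @export
agent_custom <- function(choose_fun = NULL, pair_fun = NULL, ...) {
  new_agent("custom", choose_fun = choose_fun, pair_fun = pair_fun, ...)
}

#' Resolve an agent preset name
#'
#' Maps the preset names accepted in configuration files to agent
#' constructors.
#'
#' @param preset One of `"stationary"`, `"adaptive"`, `"always-ae"`,
#'   `"always-fr"`, `"alternating"`.
#' @param ... Passed to the matching constructor.
#' @return An `"ae_agent"`.
#' @export
agent_preset <- function(preset, ...) {
  switch(preset,
    "stationary"  = agent_stationary(...),
    "adaptive"    = agent_adaptive(...),
    "always-ae"   = agent_always_ae(...),
    "always-fr"   = agent_always_fr(...),
    "alternating" = agent_alternating(...),
    ae_abort(paste0("Unknown agent preset: '", preset, "'."),
             "aeforage_error_config")
  )
}

#' @export
print.ae_agent <- function(x, ...) {
  cat("<ae_agent> choice rule:", x$choice_rule,
      if (x$adaptive) "(adaptive kinematics)" else "", "\n")
  if (x$choice_rule == "logistic") {
    cat("  a* =", paste(signif(x$a_star, 4), collapse = "/"),
        "J, tau =", x$tau, "J\n")
  }
  cat("  IRT ~ lognormal(", signif(x$irt_meanlog, 4), ",", x$irt_sdlog,
      "); scatter:", x$scatter, "\n")
  invisible(x)
}

# a_star for a given FR requirement: scalar, exact lookup, or linear
# interpolation over the named map (constant beyond the ends).
resolve_a_star <- function(agent, fr_requirement) {
  a <- agent$a_star
  if (length(a) == 1 && is.null(names(a))) return(unname(a))
  nm <- suppressWarnings(as.numeric(names(a)))
  hit <- match(fr_requirement, nm)
  if (!is.na(hit)) return(unname(a[[hit]]))
  if (length(a) == 1) return(unname(a))
  unname(stats::approx(nm, a, xout = fr_requirement, rule = 2)$y)
}

#' Probability that a logistic agent chooses the AE key
#'
#' `1 / (1 + exp((ae_requirement - a_star) / tau))`: decreasing in the
#' requirement, 1/2 at the indifference requirement.
#'
#' @param ae_requirement Current AE requirement, J.
#' @param a_star Indifference requirement, J.
#' @param tau Choice temperature, J.
#' @return Probability of choosing AE. Vectorised.
#' @export
prob_choose_ae <- function(ae_requirement, a_star, tau) {
  stats::plogis((a_star - ae_requirement) / tau)
}

#' Draw a choice between the AE and FR schedules
#'
#' Queries the agent's choice rule at a free-choice trial. Logistic agents
#' draw from [prob_choose_ae()] using the current RNG stream; deterministic
#' agents ignore the requirement.
#'
#' @param agent An [ae_agent].
#' @param ae_requirement Current AE requirement, J.
#' @param fr_requirement FR requirement (response count) of the condition.
#' @param free_index 1-based index of the free-choice trial within the
#'   session (used by the alternating agent).
#' @return `"AE"` or `"FR"`.
#' @export
choose_schedule <- function(agent, ae_requirement, fr_requirement,
                            free_index = 1L) {
  switch(agent$choice_rule,
    always_ae = "AE",
    always_fr = "FR",
    alternating = if (free_index %% 2 == 1) "AE" else "FR",
    custom = {
      if (is.null(agent$choose_fun)) {
        ae_abort("Custom agent lacks `choose_fun`.", "aeforage_error_invalid_argument")
      }
      agent$choose_fun(agent, ae_requirement, fr_requirement, free_index)
    },
    logistic = {
      p <- prob_choose_ae(ae_requirement,
                          resolve_a_star(agent, fr_requirement), agent$tau)
      if (runif(1) < p) "AE" else "FR"
    }
  )
}

# Vectorised peck locations under the agent's scatter rule. Gaussian scatter
# is truncated to the response area by rejection; sigma = 0 degenerates to
# the centre point.
sample_points <- function(agent, n, geometry, ae_requirement = NULL) {
  r <- geometry$response_area_diameter / 2
  sd <- agent$scatter_sd
  scale <- 1
  if (agent$adaptive && !is.null(ae_requirement)) {
    scale <- sqrt(max(ae_requirement, 0) / agent$adapt_reference)
  }
  if (agent$scatter == "uniform") {
    # uniform over the disc, shrunk for adaptive agents (capped at the rim)
    rad <- min(r * scale, r)
    rr <- rad * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    return(cbind(x = rr * cos(th), y = rr * sin(th)))
  }
  sd <- sd * scale
  if (sd == 0) return(cbind(x = numeric(n), y = numeric(n)))
  x <- y <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    cx <- stats::rnorm(length(need), 0, sd)
    cy <- stats::rnorm(length(need), 0, sd)
    ok <- cx^2 + cy^2 <= r^2
    x[need[ok]] <- cx[ok]
    y[need[ok]] <- cy[ok]
    need <- need[!ok]
  }
  cbind(x = x, y = y)
}

#' Draw one peck pair at the schedule phase of an AE trial
#'
#' Samples an interresponse time from the agent's lognormal distribution and
#' two peck locations from its scatter rule. The first peck lands one
#' lognormal latency after `clock`. For stationary agents both draws are
#' independent of the current requirement; adaptive agents rescale their
#' scatter with the requirement.
#'
#' @param agent An [ae_agent].
#' @param clock Simulated time at which the schedule phase starts, s.
#' @param geometry A [chamber_geometry()].
#' @param ae_requirement Current AE requirement, J (used by adaptive agents).
#' @return A two-row tibble with columns `x`, `y`, `t`.
#' @export
draw_peck_pair <- function(agent, clock = 0, geometry = chamber_geometry(),
                           ae_requirement = NULL) {
  if (!is.null(agent$pair_fun)) {
    out <- agent$pair_fun(agent, clock, geometry, ae_requirement)
    return(as_tibble(out))
  }
  gaps <- rlnorm(2, agent$irt_meanlog, agent$irt_sdlog)
  pts <- sample_points(agent, 2, geometry, ae_requirement)
  tibble(x = pts[, "x"], y = pts[, "y"], t = clock + cumsum(gaps))
}

#' Simulate interresponse energies
#'
#' Draws `n` independent peck pairs from the agent's kinematics and returns
#' their interresponse energies, J. This is the IRE distribution the AE
#' schedule samples from at the given requirement (stationary agents ignore
#' the requirement).
#'
#' @param agent An [ae_agent].
#' @param n Number of peck pairs.
#' @param geometry A [chamber_geometry()].
#' @param ae_requirement Current AE requirement, J (used by adaptive
#'   agents).
#' @return Numeric vector of `n` IRE values, J.
#' @export
simulate_ires <- function(agent, n, geometry = chamber_geometry(),
                          ae_requirement = NULL) {
  sample_ire(agent, n, geometry, ae_requirement)
}

# Vectorised IRE sample for Monte-Carlo work: n independent peck pairs.
sample_ire <- function(agent, n, geometry = chamber_geometry(),
                       ae_requirement = NULL) {
  irt <- rlnorm(n, agent$irt_meanlog, agent$irt_sdlog)
  p1 <- sample_points(agent, n, geometry, ae_requirement)
  p2 <- sample_points(agent, n, geometry, ae_requirement)
  ird2 <- (p2[, "x"] - p1[, "x"])^2 + (p2[, "y"] - p1[, "y"])^2
  ird2 / irt^2
}

#' Monte-Carlo probability that an agent's peck pair meets a requirement
#'
#' Estimates `P(IRE > ae_requirement)` under the agent's kinematics by
#' simulating `n_mc` independent peck pairs. Monotone non-increasing in the
#' requirement up to sampling error.
#'
#' @param agent An [ae_agent].
#' @param ae_requirement AE requirement, J.
#' @param n_mc Number of simulated pairs (>= 1).
#' @param geometry A [chamber_geometry()].
#' @return Estimated success probability.
#' @export
success_probability <- function(agent, ae_requirement, n_mc = 10000,
                                geometry = chamber_geometry()) {
  if (n_mc < 1) {
    ae_abort("`n_mc` must be at least 1.", "aeforage_error_invalid_argument")
  }
  mean(sample_ire(agent, n_mc, geometry, ae_requirement) > ae_requirement)
}
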