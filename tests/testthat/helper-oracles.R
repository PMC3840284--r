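# Independent oracles and deterministic test agents shared across tests.

# Brute-force E/RFT oracle: walk the trial sequence session by session,
# accumulate every attempt's IRE, close a run at each reinforcer, drop any
# trailing unreinforced tail; with zero reinforcers overall, E/RFT is the
# grand total IRE. Written independently of the package implementation.
oracle_e_per_rft <- function(trials) {
  totals <- c()
  grand <- 0
  for (sess in unique(trials$session_index)) {
    acc <- 0
    for (i in which(trials$session_index == sess)) {
      e <- sum(trials$ire_attempts[[i]]$ire)
      acc <- acc + e
      grand <- grand + e
      if (trials$reinforced[i]) {
        totals <- c(totals, acc)
        acc <- 0
      }
    }
  }
  if (length(totals) == 0) list(e = grand, n = 0L)
  else list(e = mean(totals), n = length(totals))
}

# Random small free-choice AE trial logs for oracle comparison.
random_ae_log <- function(n_max = 50) {
  n <- sample(1:n_max, 1)
  tibble::tibble(
    session_index = sort(sample(1:3, n, replace = TRUE)),
    trial_type = "free",
    chosen_schedule = "AE",
    reinforced = runif(n) < 0.4,
    ire_attempts = lapply(seq_len(n), function(i) {
      k <- sample(1:3, 1)
      tibble::tibble(ire = round(runif(k, 0, 0.2), 4))
    })
  )
}

# Agent whose AE peck pairs are scripted: the k-th attempt uses ird_seq[k]
# (recycled) at a fixed 1-s IRT, so its IREs are ird_seq^2 in order.
scripted_agent <- function(ird_seq) {
  idx <- new.env()
  idx$i <- 0L
  agent_custom(
    choose_fun = function(agent, a, fr, free_index) "AE",
    pair_fun = function(agent, clock, geometry, a) {
      idx$i <- idx$i + 1L
      d <- ird_seq[(idx$i - 1L) %% length(ird_seq) + 1L]
      data.frame(x = c(0, d), y = c(0, 0), t = clock + c(0.1, 1.1))
    }
  )
}

# An agent that can never meet any positive requirement (zero movement).
failing_agent <- function() agent_stationary(scatter = "gaussian", scatter_sd = 0)

# Closed form: mean distance between two independent uniform points in a
# disc of radius r.
mean_disc_distance <- function(r) 128 * r / (45 * pi)
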