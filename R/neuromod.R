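#' Create a dopamine state
#'
#' @param cfg a `polywave_config`.
#' @param novelty initial novelty in `[0, 1]` (1 = maximally novel task).
#' @return list with phasic level `D_p`, tonic level `D_t`, `novelty` and the
#'   queue of pending delayed phasic jumps.
#' @export
dopamine_state <- function(cfg = pw_config(), novelty = 1) {
  list(D_p = 0, D_t = cfg$d_t * novelty, novelty = novelty,
       pending_time = numeric(0), pending_amount = numeric(0))
}

#' Raw task reward from per-trial spike counts
#'
#' Task 1: `R = (-0.5 + 1.5 * I(n_true > max(n_false))) *
#' I(n_true + sum(n_false) > 5)` — a reward of 1 when the target leads and a
#' punishment of -0.5 when it does not, gated by a strict total-count
#' threshold of 5. Task 2: `R = I(n_true > 0)`; no punishment. Task 3:
#' `R = I(n_true >= n_false + 5) - I(n_false >= n_true + 5)` — a 5-spike
#' margin between the two output neurons.
#'
#' @param task task id (1, 2 or 3).
#' @param n_true spike count of the target neuron this trial.
#' @param n_false vector of per-false-target spike counts (may be empty).
#' @return scalar reward R.
#' @export
compute_reward <- function(task, n_true, n_false = integer(0)) {
  stopifnot(n_true >= 0, all(n_false >= 0))
  maxf <- if (length(n_false)) max(n_false) else 0
  sumf <- sum(n_false)
  switch(as.character(task),
    "1" = (-0.5 + 1.5 * (n_true > maxf)) * (n_true + sumf > 5),
    "2" = as.numeric(n_true > 0),
    "3" = as.numeric(n_true >= maxf + 5) - as.numeric(maxf >= n_true + 5),
    stop("unknown task id: ", task, call. = FALSE)
  )
}

#' Reward amplitude envelope
#'
#' The phasic jump amplitude is 0 until the stimulus onset, `d_p` from onset
#' to offset, and decays exponentially with `tau_d` afterwards:
#' `Gamma_R(t) = d_p * I(t > t_on) * exp(-max(t - t_off, 0)/tau_d)`.
#'
#' @param t trial time (ms).
#' @param cfg a `polywave_config` (keys `t_on`, `t_off`, `d_p`, `tau_d`).
#' @param d_p override of the amplitude (e.g. under the end-of-run decline).
#' @return scalar amplitude.
#' @export
reward_amplitude <- function(t, cfg = pw_config(), d_p = cfg$d_p) {
  if (t <= cfg$t_on) return(0)
  if (t <= cfg$t_off) d_p else d_p * exp(-(t - cfg$t_off) / cfg$tau_d)
}

#' Queue a delayed phasic dopamine jump for a target/false-target spike
#'
#' When a target or false-target neuron spikes at time t, the phasic level
#' receives `R(t) * Gamma_R(t) * Novelty` after the transmission delay `t_p`,
#' with the reward evaluated on the counts including the triggering spike.
#'
#' @param dopa a [dopamine_state()].
#' @param R reward at the spike time (counts including this spike).
#' @param t spike time (ms).
#' @param cfg a `polywave_config`.
#' @param d_p amplitude override (end-of-run decline).
#' @return the dopamine state with the jump enqueued for `t + t_p`.
#' @export
on_target_spike <- function(dopa, R, t, cfg = pw_config(), d_p = cfg$d_p) {
  inc <- R * reward_amplitude(t, cfg, d_p) * dopa$novelty
  dopa$pending_time <- c(dopa$pending_time, t + cfg$t_p)
  dopa$pending_amount <- c(dopa$pending_amount, inc)
  dopa
}

#' Advance the dopamine state by one step
#'
#' `D_p` decays exponentially with `tau_p`, due queued jumps are applied, and
#' the result is clipped to `[-dp_bound, dp_bound]`. The tonic level is
#' `D_t = d_t * Novelty` (0 when tonic signalling is disabled).
#'
#' @param dopa a [dopamine_state()].
#' @param t current trial time (ms); queued jumps with arrival <= t fire.
#' @param cfg a `polywave_config`.
#' @param tonic_enabled whether the tonic component is active.
#' @param d_t tonic constant override (end-of-run decline).
#' @return updated dopamine state.
#' @export
update_dopamine <- function(dopa, t, cfg = pw_config(), tonic_enabled = TRUE,
                            d_t = cfg$d_t) {
  dopa$D_p <- dopa$D_p * exp(-cfg$dt / cfg$tau_p)
  due <- dopa$pending_time <= t
  if (any(due)) {
    dopa$D_p <- dopa$D_p + sum(dopa$pending_amount[due])
    dopa$D_p <- min(max(dopa$D_p, -cfg$dp_bound), cfg$dp_bound)
    dopa$pending_time <- dopa$pending_time[!due]
    dopa$pending_amount <- dopa$pending_amount[!due]
  }
  dopa$D_t <- if (tonic_enabled) d_t * dopa$novelty else 0
  dopa
}

#' Update the novelty after a trial
#'
#' Novelty decreases by `novelty_step` after a correct trial and increases by
#' the same amount after a wrong one, clipped to `[0, 1]`. Correctness is the
#' task criterion: R > 0 at trial end for Tasks 1 and 3, first-target-spike
#' latency below 100 ms for Task 2.
#'
#' @param novelty current novelty.
#' @param trial_correct logical.
#' @param cfg a `polywave_config`.
#' @return updated novelty.
#' @export
update_novelty <- function(novelty, trial_correct, cfg = pw_config()) {
  step <- if (trial_correct) -cfg$novelty_step else cfg$novelty_step
  min(max(novelty + step, 0), 1)
}
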