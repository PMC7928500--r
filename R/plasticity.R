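#' Create an eligibility-trace state
#'
#' @param n number of neurons.
#' @param m number of edges.
#' @return list with per-edge eligibility `c` and per-neuron spike trace
#'   `fbar`, both zero.
#' @export
trace_state <- function(n, m) {
  list(c = rep(0, m), fbar = rep(0, n))
}

#' Decay and accumulate the running-average spike traces
#'
#' The trace `fbar_i` is the exponential running average of neuron i's spike
#' train: it decays with `tau_stdp` and gains 1 at each spike. For an isolated
#' spike the trace peaks at 1, so the STDP window amplitude at zero lag is
#' exactly `gamma`; at sustained rate r it fluctuates around
#' `r * tau_stdp`.
#'
#' @param fbar per-neuron trace vector.
#' @param spikes indices of neurons spiking this step.
#' @param cfg a `polywave_config`.
#' @param decay whether to apply the per-step decay (set `FALSE` when the
#'   decay to the current time was already applied).
#' @return updated `fbar`.
#' @export
update_spike_traces <- function(fbar, spikes, cfg = pw_config(), decay = TRUE) {
  if (decay) fbar <- fbar * exp(-cfg$dt / cfg$tau_stdp)
  fbar[spikes] <- fbar[spikes] + 1
  fbar
}

#' Apply STDP events to the eligibility traces
#'
#' For each spike of postsynaptic neuron i on edge j -> i the eligibility
#' gains `gamma * fbar_j` (pre-before-post potentiation); for each spike of
#' presynaptic neuron j it loses `ltd_factor * gamma * fbar_i`
#' (post-before-pre depression). All increments of one step are evaluated with
#' the traces as they stand before any of this step's jumps, so coincident
#' pre/post spikes contribute `gamma * (fbar_j - ltd_factor * fbar_i)`
#' independent of processing order. The result is clipped to
#' `[-S_max/2, S_max/2]`.
#'
#' @param trace a [trace_state()] list; `fbar` must already be decayed to the
#'   current time.
#' @param edges data.frame with `pre`, `post`.
#' @param spikes indices of neurons spiking this step.
#' @param cfg a `polywave_config`.
#' @return the trace state with updated `c` and `fbar` (post-jump).
#' @export
apply_stdp_events <- function(trace, edges, spikes, cfg = pw_config()) {
  if (length(spikes)) {
    as_post <- edges$post %in% spikes
    trace$c[as_post] <- trace$c[as_post] +
      cfg$gamma * trace$fbar[edges$pre[as_post]]
    as_pre <- edges$pre %in% spikes
    trace$c[as_pre] <- trace$c[as_pre] -
      cfg$ltd_factor * cfg$gamma * trace$fbar[edges$post[as_pre]]
    bound <- cfg$S_max / 2
    trace$c <- pmin(pmax(trace$c, -bound), bound)
    trace$fbar[spikes] <- trace$fbar[spikes] + 1
  }
  trace
}

#' Decay the eligibility traces
#'
#' @param c_vec per-edge eligibility vector.
#' @param cfg a `polywave_config` (key `tau_c`).
#' @param dt step length (ms), default `cfg$dt`.
#' @return decayed eligibility.
#' @export
decay_eligibility <- function(c_vec, cfg = pw_config(), dt = cfg$dt) {
  c_vec * exp(-dt / cfg$tau_c)
}

#' Dopamine-gated weight update
#'
#' Applies `dS = c * (D_t + D_p) * dt / tau_s` to every edge except those
#' with `c < 0` and `D_p < 0`, which are left untouched (punishment does not
#' deepen depression). Weights are clipped to `[0, S_max]`.
#'
#' @param S per-edge weight vector.
#' @param c_vec per-edge eligibility vector.
#' @param D_t,D_p tonic and phasic dopamine levels.
#' @param cfg a `polywave_config`.
#' @param dt step length (ms), default `cfg$dt`.
#' @return updated weights.
#' @export
update_weights <- function(S, c_vec, D_t, D_p, cfg = pw_config(),
                           dt = cfg$dt) {
  active <- !(c_vec < 0 & D_p < 0)
  S[active] <- S[active] + c_vec[active] * (D_t + D_p) * dt / cfg$tau_s
  pmin(pmax(S, 0), cfg$S_max)
}
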