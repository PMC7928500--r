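#' Create a neuron state for step-wise integration
#'
#' @param n number of neurons.
#' @param cfg a `polywave_config`.
#' @return list with membrane potentials `v` (at rest), recurrent drive `h`,
#'   external drive `h_ext`, inhibitory drive `h_inh` and noise levels `sigma`.
#' @export
neuron_state <- function(n, cfg = pw_config()) {
  list(v = rep(cfg$v0, n), h = rep(0, n), h_ext = rep(0, n),
       h_inh = 0, sigma = rep(0, n))
}

#' One Euler-Maruyama membrane step with spike-and-reset
#'
#' Advances `dv/dt = (v0 - v + h + h_ext - h_inh)/tau_m + noise` by one step
#' `dt`, with per-step noise `noise_gain * sigma * sqrt(dt) * N(0,1)`. Neurons
#' reaching the threshold `v_th` are reset to `v_reset` and reported as spikes.
#'
#' @param state a [neuron_state()] list (fields `v`, `h`, `h_ext`, `h_inh`,
#'   `sigma`).
#' @param cfg a `polywave_config`.
#' @param xi optional vector of standard-normal draws (one per neuron); drawn
#'   from the session RNG when `NULL`.
#' @return `state` with updated `v` and an integer vector `spikes` of the
#'   indices that fired this step.
#' @export
integrate_membrane <- function(state, cfg = pw_config(), xi = NULL) {
  n <- length(state$v)
  if (is.null(xi)) xi <- stats::rnorm(n)
  v <- state$v + cfg$dt * (cfg$v0 - state$v + state$h + state$h_ext -
                             state$h_inh) / cfg$tau_m +
    cfg$noise_gain * state$sigma * sqrt(cfg$dt) * xi
  if (any(!is.finite(v)))
    stop("non-finite membrane potential at neuron(s) ",
         paste(which(!is.finite(v)), collapse = ", "))
  spikes <- which(v >= cfg$v_th)
  v[spikes] <- cfg$v_reset
  state$v <- v
  state$spikes <- spikes
  state
}

#' Update recurrent synaptic drives from delayed presynaptic spikes
#'
#' `h` decays with time constant `tau_h`; every presynaptic spike of neuron j
#' that occurred `t_d` ago adds `h0 * S_ij` to each postsynaptic neuron i. The
#' decay uses the exact per-step factor `exp(-dt/tau_h)`.
#'
#' @param h numeric vector of drives (mV).
#' @param edges data.frame with `pre`, `post`, `weight`.
#' @param delayed_spikes integer vector of neurons that spiked `t_d` ago.
#' @param cfg a `polywave_config`.
#' @return updated `h`.
#' @export
update_synaptic_drive <- function(h, edges, delayed_spikes, cfg = pw_config()) {
  h <- h * exp(-cfg$dt / cfg$tau_h)
  if (length(delayed_spikes)) {
    hit <- edges$pre %in% delayed_spikes
    if (any(hit)) {
      add <- tapply(cfg$h0 * edges$weight[hit], edges$post[hit], sum)
      idx <- as.integer(names(add))
      h[idx] <- h[idx] + as.numeric(add)
    }
  }
  h
}

#' Update the global inhibitory feedback drive
#'
#' `h_inh` decays with `tau_inh` and increases by `beta` for every spike in
#' the population `t_h` ago.
#'
#' @param h_inh current inhibitory drive (mV).
#' @param n_delayed_spikes population spike count `t_h` ago.
#' @param cfg a `polywave_config`.
#' @return updated `h_inh`.
#' @export
update_inhibition <- function(h_inh, n_delayed_spikes, cfg = pw_config()) {
  h_inh * exp(-cfg$dt / cfg$tau_inh) + cfg$beta * n_delayed_spikes
}

#' External stimulation pulses
#'
#' Stimulated neurons receive an impulse of `pulse_amplitude` mV at every
#' multiple of `pulse_period` within the stimulation window `[t_on, t_off)`
#' (5 ms period = 200 Hz); all other neurons, and all times outside the
#' window, receive 0. The returned impulses are added to the external drive
#' `h_ext`, which then decays with `tau_h` like the recurrent drive, so that
#' the pulse train holds stimulated neurons above threshold.
#'
#' @param t time within the trial (ms).
#' @param n number of neurons.
#' @param stim_ids indices of stimulated neurons.
#' @param cfg a `polywave_config` (keys `t_on`, `t_off`, `pulse_period`,
#'   `pulse_amplitude`).
#' @return numeric vector of per-neuron impulse amplitudes (mV).
#' @export
external_stimulus <- function(t, n, stim_ids, cfg = pw_config()) {
  out <- rep(0, n)
  if (t >= cfg$t_on && t < cfg$t_off) {
    phase <- (t - cfg$t_on) / cfg$pulse_period
    if (abs(phase - round(phase)) < 1e-9)
      out[stim_ids] <- cfg$pulse_amplitude
  }
  out
}
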