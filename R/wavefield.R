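#' Create a wavefield state
#'
#' @param n number of neurons.
#' @param cfg a `polywave_config`.
#' @return list with local fields `psi` (0 = downstate), drives `g`, per-edge
#'   crossing flags and per-neuron crossing counts.
#' @export
wave_state <- function(n, cfg = pw_config()) {
  list(psi = rep(0, n), g = rep(0, n))
}

#' One Euler step of the local fields
#'
#' `dpsi_i/dt = (g_i - psi_i)/tau_w + kappa_in * sum_(j->i) [psi_j(t - delta_t)
#' - psi_i(t) - theta]_+ - kappa_out * sum_(i->j) [psi_i(t - delta_t) -
#' psi_j(t) - theta]_+`, clipped to `[psi_min, psi_max]`. The rectified
#' coupling runs over the synaptic adjacency (waves spread along anatomical
#' connections, not spatial distance), with a propagation delay `delta_t` and
#' threshold `theta`; sheet boundaries receive no influx from outside because
#' no edges exist there (waves collapse at the edges).
#'
#' @param psi current local fields (mV).
#' @param psi_delayed local fields `delta_t` ago (mV).
#' @param g per-neuron drives (mV).
#' @param edges data.frame with `pre`, `post`.
#' @param cfg a `polywave_config`.
#' @return updated `psi`.
#' @export
update_local_field <- function(psi, psi_delayed, g, edges, cfg = pw_config()) {
  dpsi <- (g - psi) / cfg$tau_w
  if (nrow(edges)) {
    # the rectified gap of edge j -> i feeds psi_i (inflow) and drains psi_j
    # (outflow): both sums of the field equation evaluate the same bracket
    w <- pmax(psi_delayed[edges$pre] - psi[edges$post] - cfg$theta, 0)
    dpsi <- dpsi +
      cfg$kappa_in * as.numeric(rowsum_vec(w, edges$post, length(psi))) -
      cfg$kappa_out * as.numeric(rowsum_vec(w, edges$pre, length(psi)))
  }
  pmin(pmax(psi + cfg$dt * dpsi, cfg$psi_min), cfg$psi_max)
}

rowsum_vec <- function(x, group, n) {
  out <- rep(0, n)
  if (length(x)) {
    s <- tapply(x, group, sum)
    out[as.integer(names(s))] <- as.numeric(s)
  }
  out
}

#' External drive of the local field under stimulation
#'
#' For stimulated neurons the drive is a staircase accumulating `eta` every
#' `pulse_period` from the stimulus onset (steps at 0, 5, 10, ... ms after
#' onset), then drops to `g_post` (-5 mV) after the stimulation interval.
#' Non-stimulated neurons always have drive 0.
#'
#' @param t trial time (ms).
#' @param n number of neurons.
#' @param stim_ids indices of stimulated neurons.
#' @param cfg a `polywave_config` (keys `eta`, `g_post`, `t_on`, `t_off`,
#'   `pulse_period`).
#' @return per-neuron drive vector (mV).
#' @export
external_field_drive <- function(t, n, stim_ids, cfg = pw_config()) {
  g <- rep(0, n)
  if (t >= cfg$t_off) {
    g[stim_ids] <- cfg$g_post
  } else if (t >= cfg$t_on) {
    nsteps <- floor((t - cfg$t_on) / cfg$pulse_period + 1e-9) + 1
    g[stim_ids] <- cfg$eta * nsteps
  }
  g
}

#' Update the influx crossing counts and coefficients
#'
#' For each incoming edge j -> i, the first step of a trial at which
#' `psi_j(t - delta_t) - psi_i(t) - theta` becomes positive counts as one
#' crossing (each neighbour at most once per trial). The influx coefficient is
#' the saturating `alpha_i = 5 * tanh(counts_i)`, which maps the local field
#' to the noise level.
#'
#' @param influx list with logical per-edge `crossed` and integer per-neuron
#'   `counts` (create with `influx_state(n, m)`).
#' @param psi current local fields.
#' @param psi_delayed fields `delta_t` ago.
#' @param edges data.frame with `pre`, `post`.
#' @param cfg a `polywave_config`.
#' @return updated influx list (fields `crossed`, `counts`, `alpha`).
#' @export
update_influx <- function(influx, psi, psi_delayed, edges, cfg = pw_config()) {
  val <- psi_delayed[edges$pre] - psi[edges$post] - cfg$theta
  new <- !influx$crossed & val > 0
  if (any(new)) {
    influx$crossed[new] <- TRUE
    add <- tabulate(edges$post[new], nbins = length(psi))
    influx$counts <- influx$counts + add
  }
  influx$alpha <- 5 * tanh(influx$counts)
  influx
}

#' @rdname update_influx
#' @param n number of neurons.
#' @param m number of edges.
#' @export
influx_state <- function(n, m) {
  list(crossed = rep(FALSE, m), counts = rep(0L, n), alpha = rep(0, n))
}

#' Per-neuron noise level
#'
#' Wave condition: `sigma_i = clip(alpha_i * psi_i + sigma_base,
#' sigma_min, sigma_max)` — the traveling upstate raises the membrane noise
#' from the 3 mV downstate toward the 6 mV upstate. No-wave condition: the
#' constant `sigma_const` for every neuron.
#'
#' @param alpha per-neuron influx coefficients.
#' @param psi per-neuron local fields.
#' @param cfg a `polywave_config`.
#' @param wave_enabled logical.
#' @param sigma_const constant level for the no-wave condition (mV).
#' @return per-neuron noise levels (mV).
#' @export
noise_level <- function(alpha, psi, cfg = pw_config(), wave_enabled = TRUE,
                        sigma_const = cfg$sigma_const) {
  if (!wave_enabled) return(rep(sigma_const, length(psi)))
  pmin(pmax(alpha * psi + cfg$sigma_base, cfg$sigma_min), cfg$sigma_max)
}
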