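# Pure-R reference stepper mirroring the compiled trial integrator step by
# step (same update order, same integer-step delay handling, same RNG draw
# order: one N(0,1) per neuron per step). Used by the test suite to validate
# the compiled core on short trials; far too slow for production runs.
run_trial_reference <- function(net, cfg, condition, state = NULL,
                                pattern = 1L, plastic = TRUE,
                                d_t_scale = 1, d_p_scale = 1,
                                duration = 500) {
  if (is.character(condition)) condition <- pw_condition(condition)
  if (is.null(state)) state <- learning_state(net)
  n <- net$n; e <- net$edges
  edges <- data.frame(pre = e$pre, post = e$post, weight = state$S)
  stim <- net$stim_patterns[[pattern]]
  targ <- net$pattern_targets[[pattern]]
  fals <- net$pattern_false[[pattern]]

  dt <- cfg$dt
  nsteps <- round(duration / dt)
  td_steps <- round(cfg$t_d / dt); th_steps <- round(cfg$t_h / dt)
  tp_steps <- round(cfg$t_p / dt); dl_steps <- round(cfg$delta_t / dt)
  per_steps <- round(cfg$pulse_period / dt)
  on_step <- round(cfg$t_on / dt); off_step <- round(cfg$t_off / dt)
  d_t_eff <- cfg$d_t * d_t_scale; d_p_eff <- cfg$d_p * d_p_scale

  ns <- neuron_state(n, cfg)
  ns$sigma <- rep(if (condition$wave) cfg$sigma_base else cfg$sigma_const, n)
  ws <- wave_state(n, cfg)
  influx <- influx_state(n, nrow(edges))
  psi_hist <- matrix(0, n, dl_steps)
  fbar <- state$fbar; cc <- state$c; S <- state$S
  Dp <- 0
  Dt <- if (condition$tonic) d_t_eff * state$novelty else 0
  pend_step <- integer(0); pend_amt <- numeric(0)
  ntrue <- 0L; nfalse <- rep(0L, length(fals))
  spike_step <- integer(0); spike_id <- integer(0)
  R_now <- 0; latency <- NA_real_

  spikes_at <- function(k) spike_id[spike_step == k]

  for (k in 0:(nsteps - 1)) {
    t <- k * dt
    if (condition$wave) {
      col <- (k %% dl_steps) + 1
      delayed <- if (k >= dl_steps) psi_hist[, col] else rep(0, n)
      if (k >= on_step && k < off_step) {
        if ((k - on_step) %% per_steps == 0) ws$g[stim] <- ws$g[stim] + cfg$eta
      } else if (k == off_step) ws$g[stim] <- cfg$g_post
      influx <- update_influx(influx, ws$psi, delayed, edges, cfg)
      psi_hist[, col] <- ws$psi
      ws$psi <- update_local_field(ws$psi, delayed, ws$g, edges, cfg)
      ns$sigma <- noise_level(influx$alpha, ws$psi, cfg, wave_enabled = TRUE)
    }
    ns$h_inh <- update_inhibition(ns$h_inh, length(spikes_at(k - th_steps)), cfg)
    edges$weight <- S
    ns$h <- update_synaptic_drive(ns$h, edges, spikes_at(k - td_steps), cfg)
    ns$h_ext <- ns$h_ext * exp(-dt / cfg$tau_h)
    if (k >= on_step && k < off_step && (k - on_step) %% per_steps == 0)
      ns$h_ext[stim] <- ns$h_ext[stim] + cfg$pulse_amplitude
    ns <- integrate_membrane(ns, cfg)
    spk <- ns$spikes
    if (length(spk)) {
      spike_step <- c(spike_step, rep(k, length(spk)))
      spike_id <- c(spike_id, spk)
    }
    if (plastic) {
      fbar <- fbar * exp(-dt / cfg$tau_stdp)
      cc <- decay_eligibility(cc, cfg)
      tr <- apply_stdp_events(list(c = cc, fbar = fbar), edges, spk, cfg)
      cc <- tr$c; fbar <- tr$fbar
    }
    Dp <- Dp * exp(-dt / cfg$tau_p)
    due <- pend_step <= k
    if (any(due)) {
      Dp <- min(max(Dp + sum(pend_amt[due]), -cfg$dp_bound), cfg$dp_bound)
      pend_step <- pend_step[!due]; pend_amt <- pend_amt[!due]
    }
    for (i in spk) {
      hit_t <- i %in% targ; hit_f <- i %in% fals
      if (!hit_t && !hit_f) next
      if (hit_t) {
        ntrue <- ntrue + 1L
        if (is.na(latency)) latency <- t - cfg$t_on
      } else nfalse[match(i, fals)] <- nfalse[match(i, fals)] + 1L
      R_now <- compute_reward(net$task, ntrue, nfalse)
      if (condition$phasic) {
        inc <- R_now * reward_amplitude(t, cfg, d_p_eff) * state$novelty
        if (inc != 0) {
          pend_step <- c(pend_step, k + tp_steps)
          pend_amt <- c(pend_amt, inc)
        }
      }
    }
    if (plastic && (Dt != 0 || Dp != 0))
      S <- update_weights(S, cc, Dt, Dp, cfg)
  }
  list(spike_step = spike_step, spike_id = spike_id - 1L,
       S = S, c = cc, fbar = fbar,
       n_true = ntrue, n_false = nfalse, R_end = R_now, Dp_end = Dp,
       latency_ms = latency, v = ns$v, sigma = ns$sigma)
}
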