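test_that("resting potential is a fixed point and drift follows the leak", {
  cfg <- pw_config()
  st <- neuron_state(2, cfg)
  st$v <- c(-70, -60)
  out <- integrate_membrane(st, cfg, xi = c(0, 0))
  expect_identical(out$v[1], -70)
  # drift (v0 - v)/tau = -1 mV/ms at v = -60, so one 0.1 ms step gives -60.1
  expect_equal(out$v[2], -60.1)
  expect_length(out$spikes, 0)
})

test_that("membrane converges monotonically to rest without noise or input", {
  cfg <- pw_config()
  st <- neuron_state(1, cfg)
  st$v <- -55
  gap <- abs(st$v - cfg$v0)
  for (i in 1:200) {
    st <- integrate_membrane(st, cfg, xi = 0)
    g <- abs(st$v - cfg$v0)
    expect_lt(g, gap)
    gap <- g
  }
})

test_that("threshold crossing emits a spike and resets to -60 mV", {
  cfg <- pw_config()
  st <- neuron_state(3, cfg)
  st$v <- c(-55, -55, -70)
  st$sigma <- c(10, 10, 0)
  out <- integrate_membrane(st, cfg, xi = c(10, 10, 0))
  expect_setequal(out$spikes, c(1, 2))
  expect_equal(out$v[1:2], c(-60, -60))
  # after any step no membrane exceeds the threshold
  expect_true(all(out$v <= cfg$v_th))
})

test_that("non-finite membrane state raises an error naming the neuron", {
  cfg <- pw_config()
  st <- neuron_state(2, cfg)
  st$h <- c(0, Inf)
  expect_error(integrate_membrane(st, cfg, xi = c(0, 0)), "neuron")
})

test_that("synaptic and inhibitory decay match the closed-form exponential", {
  cfg <- pw_config()
  edges <- data.frame(pre = 1L, post = 2L, weight = 0)
  h <- c(10, 10); h_inh <- 4
  for (k in 1:500) { # 50 ms
    h <- update_synaptic_drive(h, edges, integer(0), cfg)
    h_inh <- update_inhibition(h_inh, 0, cfg)
  }
  expect_equal(h, c(10, 10) * exp(-50 / cfg$tau_h), tolerance = 1e-2)
  expect_equal(h_inh, 4 * exp(-50 / cfg$tau_inh), tolerance = 1e-2)
})

test_that("a delayed presynaptic spike adds h0 * S_ij to the drive", {
  cfg <- pw_config()
  edges <- data.frame(pre = c(1L, 1L), post = c(2L, 3L),
                      weight = c(0.24, 0))
  h <- update_synaptic_drive(c(0, 0, 0), edges, delayed_spikes = 1L, cfg)
  expect_equal(h[2], 60 * 0.24) # 14.4 mV
  expect_identical(h[3], 0)     # zero weight leaves the drive untouched
  expect_identical(h[1], 0)
})

test_that("inhibitory feedback superposes delayed spikes linearly", {
  cfg <- pw_config()
  expect_equal(update_inhibition(0, 5, cfg), cfg$beta * 5)
  cfg0 <- pw_config(beta = 0)
  h <- update_inhibition(2, 1000, cfg0)
  expect_equal(h, 2 * exp(-cfg0$dt / cfg0$tau_inh)) # beta = 0: decay only
})

test_that("stimulation pulses recur at 200 Hz inside the window only", {
  cfg <- pw_config()
  # pulse instants: multiples of 5 ms within [0, 250)
  expect_equal(external_stimulus(10, 3, 2L, cfg)[2], cfg$pulse_amplitude)
  expect_equal(external_stimulus(10, 3, 2L, cfg)[c(1, 3)], c(0, 0))
  expect_equal(external_stimulus(12, 3, 2L, cfg)[2], 0)   # between pulses
  expect_equal(external_stimulus(300, 3, 2L, cfg)[2], 0)  # after t_off
  expect_equal(external_stimulus(250, 3, 2L, cfg)[2], 0)  # t_off excluded
  n_pulses <- sum(vapply(seq(0, 2999) * 0.1,
                         function(t) external_stimulus(t, 1, 1L, cfg)[1] > 0,
                         logical(1)))
  expect_equal(n_pulses, 50) # 250 ms at 200 Hz
})

test_that("a stimulated neuron fires throughout every stimulation window", {
  cfg <- pw_config()
  for (seed in 1:3) {
    set.seed(seed)
    res <- polywave:::sim_trial_cpp(
      n = 1L, pre = integer(0), post = integer(0), S_in = numeric(0),
      c_in = numeric(0), fbar_in = 0, par = unclass(cfg),
      stim_ids = 0L, target_ids = integer(0), false_ids = integer(0),
      task = 1L, wave = FALSE, tonic = FALSE, phasic = FALSE,
      plastic = FALSE, sigma_const = 0, d_t_eff = 0, d_p_eff = 0,
      novelty = 0, duration_ms = 400)
    tms <- res$spike_step * cfg$dt
    expect_gt(sum(tms < 250), 25)     # sustained firing during the window
    expect_equal(sum(tms > 260), 0)   # silent once the pulses stop
  }
})
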