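test_that("compiled trial integrator matches the pure-R reference stepper", {
  cfg <- pw_config(task = 2, d_p = 0.2)
  set.seed(5)
  net <- build_task2(cfg)
  st <- learning_state(net)
  set.seed(42)
  a <- run_trial(net, cfg, "full", st, duration = 300)
  set.seed(42)
  b <- polywave:::run_trial_reference(net, cfg, pw_condition("full"), st,
                                      duration = 300)
  expect_identical(as.integer(a$spikes$neuron), as.integer(b$spike_id))
  expect_equal(a$spikes$time_ms, b$spike_step * cfg$dt, tolerance = 1e-12)
  expect_equal(a$state$S, b$S, tolerance = 1e-12)
  expect_equal(a$state$c, b$c, tolerance = 1e-12)
  expect_equal(a$state$fbar, b$fbar, tolerance = 1e-12)
  expect_equal(a$Dp_end, b$Dp_end, tolerance = 1e-12)
})

test_that("identical seed and config give bit-identical trials", {
  cfg <- pw_config(task = 2)
  set.seed(6)
  net <- build_task2(cfg)
  run_once <- function() {
    set.seed(99)
    run_trial(net, cfg, "full")
  }
  a <- run_once(); b <- run_once()
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$state$S, b$state$S)
  expect_identical(a$R_end, b$R_end)
})

test_that("a silent network produces no spikes and no reward", {
  cfg <- pw_config(task = 2, sigma_const = 0)
  set.seed(7)
  net <- build_task2(cfg)
  net$stim_patterns <- list(integer(0)) # no stimulation
  set.seed(1)
  tr <- run_trial(net, cfg, "conventional", plastic = FALSE)
  expect_equal(nrow(tr$spikes), 0)
  expect_equal(tr$R_end, 0)
  expect_true(is.na(tr$latency_ms))
})

test_that("spike counters start from zero in every trial", {
  cfg <- pw_config(task = 2)
  set.seed(8)
  net <- build_task2(cfg)
  st <- learning_state(net)
  set.seed(2)
  t1 <- run_trial(net, cfg, "full", st, plastic = FALSE)
  t2 <- run_trial(net, cfg, "full", t1$state, plastic = FALSE)
  # counts are per-trial tallies, not cumulative across trials
  n2 <- sum(t2$spikes$neuron == net$pattern_targets[[1]] - 1L)
  expect_equal(t2$n_true, n2)
})

test_that("weights and eligibility stay inside their bounds over a full run", {
  cfg <- pw_config(task = 2, d_p = 0.3)
  set.seed(9)
  net <- build_task2(cfg)
  st <- learning_state(net)
  set.seed(3)
  for (i in 1:8) {
    tr <- run_trial(net, cfg, "full", st)
    st <- tr$state
    expect_true(all(st$S >= 0 & st$S <= cfg$S_max))
    expect_true(all(abs(st$c) <= cfg$S_max / 2 + 1e-15))
    expect_true(abs(tr$Dp_end) <= cfg$dp_bound)
  }
})

test_that("experiment log tracks novelty, decline schedule and patterns", {
  cfg <- pw_config(task = 3, n_trials = 8, decline_fraction = 0.25)
  set.seed(10)
  net <- build_task3(cfg)
  set.seed(4)
  ex <- run_experiment(net, cfg, "full")
  expect_equal(nrow(ex$log), 8)
  # task 3 cycles its four stimulus patterns in order
  expect_equal(ex$log$pattern, rep(1:4, 2))
  expect_true(all(ex$log$novelty >= 0 & ex$log$novelty <= 1))
  # the final trial sits at the end of the dopamine decline ramp
  expect_equal(ex$log$D_t[8], 0)
})

test_that("replicated experiments aggregate per-trial success with SEM", {
  cfg <- pw_config(task = 2)
  rep <- run_replicates(task = 2, cfg = cfg, condition = "full",
                        n_trials = 3, replicates = 2, seed = 5)
  expect_equal(dim(rep$success), c(3, 2))
  expect_equal(nrow(rep$curve), 3)
  expect_true(all(rep$curve$success_rate >= 0 & rep$curve$success_rate <= 1))
  expect_true(all(rep$curve$sem >= 0))
})

test_that("latency index caps at 300 ms and handles missing spikes", {
  expect_equal(latency_index(80), 80)
  expect_equal(latency_index(450), 300)
  expect_equal(latency_index(NA_real_), 300)
  expect_equal(latency_index(c(10, NA, 301)), c(10, 300, 300))
})

test_that("path strength is the product of stage means", {
  set.seed(11)
  net <- build_task3()
  ps <- path_strength_task3(net)
  # initial strong path: 0.2 * 0.2
  expect_true(any(abs(ps$strength - 0.04) < 1e-12))
  # zeroed weights annihilate every path
  ps0 <- path_strength_task3(net, S = rep(0, nrow(net$edges)))
  expect_true(all(ps0$strength == 0))
  # bilinearity: doubling all weights quadruples all strengths
  ps2 <- path_strength_task3(net, S = 2 * net$edges$weight)
  expect_equal(ps2$strength, 4 * ps$strength)
})

test_that("weight-difference map is signed by edge direction", {
  net <- chain_network(3)
  S0 <- net$edges$weight
  # unchanged weights: zero field
  m0 <- mean_weight_difference_map(net, S0)
  expect_true(all(m0$dx == 0 & m0$dy == 0))
  # strengthen edge 1 -> 2 (pointing +x): both endpoints gain +x components
  S1 <- S0; S1[1] <- S0[1] + 0.1
  m1 <- mean_weight_difference_map(net, S1)
  expect_gt(m1$dx[1], 0)
  expect_equal(m1$dy[1], 0)
  # reversing the edge flips the sign of its contribution
  net_rev <- net
  net_rev$edges$pre <- net$edges$post
  net_rev$edges$post <- net$edges$pre
  m2 <- mean_weight_difference_map(net_rev, S1)
  expect_equal(m2$dx[1], -m1$dx[1])
})

test_that("latency declines under the full model but not conventionally", {
  cfg <- pw_config(task = 2)
  lat <- list()
  for (cond in c("full", "conventional")) {
    li <- sapply(1:3, function(s) {
      set.seed(s)
      net <- build_task2(cfg)
      ex <- run_experiment(net, cfg, cond, n_trials = 40)
      idx <- latency_index(ex$log$latency_ms)
      c(head = mean(idx[1:10]), tail = mean(utils::tail(idx, 10)))
    })
    lat[[cond]] <- rowMeans(li)
  }
  expect_lt(lat$full["tail"], lat$full["head"])         # learning shortens it
  expect_lt(lat$full["tail"], lat$conventional["tail"]) # waves + D_t win
})
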