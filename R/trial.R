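#' Simulation condition (ablation flags)
#'
#' The four headline conditions toggle the traveling wave and the tonic
#' dopamine component; `"no-dp"` additionally silences the phasic component
#' to isolate reward-independent learning. The conventional model is the
#' baseline reward-modulated STDP: no waves, no tonic dopamine, phasic only.
#'
#' @param name one of `"full"` (waves + tonic + phasic), `"wave-only"`,
#'   `"dt-only"`, `"conventional"`, `"no-dp"` (waves + tonic, no phasic).
#' @return list of logical flags `wave`, `tonic`, `phasic` with class
#'   `polywave_condition`.
#' @export
pw_condition <- function(name = c("full", "wave-only", "dt-only",
                                  "conventional", "no-dp")) {
  name <- match.arg(name)
  flags <- switch(name,
    "full"         = list(wave = TRUE,  tonic = TRUE,  phasic = TRUE),
    "wave-only"    = list(wave = TRUE,  tonic = FALSE, phasic = TRUE),
    "dt-only"      = list(wave = FALSE, tonic = TRUE,  phasic = TRUE),
    "conventional" = list(wave = FALSE, tonic = FALSE, phasic = TRUE),
    "no-dp"        = list(wave = TRUE,  tonic = TRUE,  phasic = FALSE))
  flags$name <- name
  class(flags) <- "polywave_condition"
  flags
}

#' Initial persistent learning state for an experiment
#'
#' Weights, eligibility traces and novelty persist across trials; membrane,
#' field and dopamine states are reset at every trial start.
#'
#' @param net a `polywave_network`.
#' @param novelty initial novelty (default 1, a new task).
#' @return list with `S`, `c`, `fbar`, `novelty`.
#' @export
learning_state <- function(net, novelty = 1) {
  list(S = net$edges$weight, c = rep(0, nrow(net$edges)),
       fbar = rep(0, net$n), novelty = novelty)
}

#' Run one trial through the compiled integrator
#'
#' Executes the full coupled update loop (membranes, synaptic and inhibitory
#' drives, wavefield, eligibility traces, dopamine, weight updates) for one
#' trial. Membrane, field and dopamine states start fresh; the learning state
#' (`S`, `c`, `fbar`, novelty) is carried in and returned updated. Gaussian
#' noise is drawn from the session RNG, so `set.seed()` makes trials
#' bit-reproducible.
#'
#' @param net a `polywave_network`.
#' @param cfg a `polywave_config`.
#' @param condition a [pw_condition()] (or its name).
#' @param state a [learning_state()]; created from the network when `NULL`.
#' @param pattern stimulus pattern index (Task 3 cycles 4 patterns).
#' @param plastic whether plasticity (traces and weight updates) runs.
#' @param d_t_scale,d_p_scale multipliers on the dopamine constants (used by
#'   the end-of-run decline schedule).
#' @param duration trial duration in ms (default `cfg$trial_duration`).
#' @param record_every record `psi`, `sigma` and `D_p` every this many steps
#'   (0 = off).
#' @return list with the spike raster (`spikes`: data.frame `neuron`, `time_ms`,
#'   0-based ids), counters, `R_end`, `latency_ms`, `success`, and the updated
#'   learning `state`.
#' @export
run_trial <- function(net, cfg = pw_config(task = net$task),
                      condition = pw_condition("full"), state = NULL,
                      pattern = 1L, plastic = TRUE,
                      d_t_scale = 1, d_p_scale = 1,
                      duration = cfg$trial_duration, record_every = 0L) {
  if (is.character(condition)) condition <- pw_condition(condition)
  if (is.null(state)) state <- learning_state(net)
  stim <- net$stim_patterns[[pattern]]
  targ <- net$pattern_targets[[pattern]]
  fals <- net$pattern_false[[pattern]]
  res <- sim_trial_cpp(
    n = net$n,
    pre = as.integer(net$edges$pre) - 1L,
    post = as.integer(net$edges$post) - 1L,
    S_in = state$S, c_in = state$c, fbar_in = state$fbar,
    par = unclass(cfg),
    stim_ids = as.integer(stim) - 1L,
    target_ids = as.integer(targ) - 1L,
    false_ids = as.integer(fals) - 1L,
    task = as.integer(net$task),
    wave = condition$wave, tonic = condition$tonic,
    phasic = condition$phasic, plastic = plastic,
    sigma_const = cfg$sigma_const,
    d_t_eff = cfg$d_t * d_t_scale,
    d_p_eff = cfg$d_p * d_p_scale,
    novelty = state$novelty,
    duration_ms = duration,
    record_every = as.integer(record_every))
  state$S <- res$S; state$c <- res$c; state$fbar <- res$fbar
  latency <- res$latency_ms
  success <- if (net$task == 2) {
    !is.na(latency) && latency < 100
  } else {
    res$R_end > 0
  }
  out <- list(
    spikes = data.frame(neuron = res$spike_id,
                        time_ms = res$spike_step * cfg$dt),
    n_true = res$n_true, n_false = res$n_false,
    R_end = res$R_end, Dp_end = res$Dp_end,
    latency_ms = latency, success = success,
    state = state)
  for (k in c("rec_t", "rec_sigma", "rec_Dp", "rec_psi"))
    if (!is.null(res[[k]])) out[[k]] <- res[[k]]
  out
}

#' Run a full learning experiment
#'
#' Runs `n_trials` sequential trials with persistent weights, eligibility
#' traces and novelty. Novelty moves by `novelty_step` after each trial
#' according to the task's success criterion, and both dopamine constants ramp
#' linearly to zero over the final `decline_fraction` of trials so that
#' learning self-terminates and the network is fixed. Task 3 cycles the four
#' stimulus patterns 0a0b, 0a1b, 1a0b, 1a1b (rewarded outputs F, T, T, F).
#'
#' @inheritParams run_trial
#' @param n_trials number of trials (default `cfg$n_trials`).
#' @param snapshot_trials trial indices at which to keep a copy of the weight
#'   vector (list entry names are the trial numbers).
#' @param verbose print a one-line per-trial summary to stderr.
#' @return list of class `polywave_experiment` with `log` (one row per trial:
#'   trial, task, condition, pattern, R_end, novelty, D_t, latency_ms,
#'   success), the final learning `state`, `snapshots`, and the network.
#' @export
run_experiment <- function(net, cfg = pw_config(task = net$task),
                           condition = pw_condition("full"),
                           n_trials = cfg$n_trials, state = NULL,
                           snapshot_trials = integer(0), verbose = FALSE) {
  if (is.character(condition)) condition <- pw_condition(condition)
  if (is.null(state)) state <- learning_state(net)
  n_trials <- as.integer(n_trials)
  n_pat <- length(net$stim_patterns)
  i0 <- floor((1 - cfg$decline_fraction) * n_trials)
  log <- vector("list", n_trials)
  snapshots <- list()
  for (i in seq_len(n_trials)) {
    scale <- if (i <= i0 || i0 >= n_trials) 1 else (n_trials - i) / (n_trials - i0)
    pattern <- ((i - 1L) %% n_pat) + 1L
    tr <- run_trial(net, cfg, condition, state, pattern = pattern,
                    d_t_scale = scale, d_p_scale = scale)
    state <- tr$state
    state$novelty <- update_novelty(state$novelty, tr$success, cfg)
    log[[i]] <- data.frame(
      trial = i, task = net$task, condition = condition$name,
      pattern = pattern, R_end = tr$R_end, novelty = state$novelty,
      D_t = if (condition$tonic) cfg$d_t * scale * state$novelty else 0,
      latency_ms = ifelse(is.na(tr$latency_ms), NA_real_, tr$latency_ms),
      success = tr$success)
    if (i %in% snapshot_trials) snapshots[[as.character(i)]] <- state$S
    if (verbose)
      message(sprintf("trial %3d [%s] R=%5.2f novelty=%.1f latency=%s success=%s",
                      i, condition$name, tr$R_end, state$novelty,
                      ifelse(is.na(tr$latency_ms), "-",
                             sprintf("%.0f", tr$latency_ms)), tr$success))
  }
  out <- list(log = do.call(rbind, log), state = state,
              snapshots = snapshots, network = net, condition = condition)
  class(out) <- "polywave_experiment"
  out
}

#' @export
print.polywave_experiment <- function(x, ...) {
  cat("<polywave_experiment> task ", x$network$task, ", condition ",
      x$condition$name, ", ", nrow(x$log), " trials\n", sep = "")
  cat(sprintf("  success rate: %.2f (last quarter: %.2f)\n",
              mean(x$log$success),
              mean(utils::tail(x$log$success, ceiling(nrow(x$log) / 4)))))
  invisible(x)
}

#' Replicate an experiment across seeds and aggregate success
#'
#' Runs the same experiment under `replicates` different seeds and returns the
#' per-trial success fraction with its standard error (the success-rate curve
#' of the aggregate figures).
#'
#' @inheritParams run_experiment
#' @param replicates number of independent runs.
#' @param seed base seed; replicate r uses `seed + r` for both network
#'   construction and simulation.
#' @param rebuild_network build a fresh random network per replicate (TRUE for
#'   tasks with random topology).
#' @return list with `curve` (data.frame trial, success_rate, sem), the
#'   per-replicate success matrix, and the per-replicate final latencies.
#' @export
run_replicates <- function(net = NULL, task = NULL,
                           cfg = pw_config(task = task),
                           condition = pw_condition("full"),
                           n_trials = cfg$n_trials, replicates = 10,
                           seed = 1, rebuild_network = is.null(net)) {
  if (is.null(net) && is.null(task)) stop("give a network or a task id")
  if (is.null(task)) task <- net$task
  succ <- matrix(NA, nrow = n_trials, ncol = replicates)
  lat <- matrix(NA_real_, nrow = n_trials, ncol = replicates)
  for (r in seq_len(replicates)) {
    set.seed(seed + r)
    net_r <- if (rebuild_network) build_task_network(task, cfg) else net
    ex <- run_experiment(net_r, cfg, condition, n_trials = n_trials)
    succ[, r] <- ex$log$success
    lat[, r] <- ex$log$latency_ms
  }
  curve <- data.frame(
    trial = seq_len(n_trials),
    success_rate = rowMeans(succ),
    sem = apply(succ, 1, stats::sd) / sqrt(replicates))
  list(curve = curve, success = succ, latency = lat)
}

#' Capped first-spike latency index
#'
#' The latency of the first target spike after the stimulus onset, capped at
#' 300 ms; trials with no target spike (or latency above the cap) take
#' 300 ms, making the index insensitive to outliers.
#'
#' @param latency_ms first-spike latency (ms), `NA` when the target never
#'   fired. Vectorized.
#' @param cap cap in ms.
#' @return latency index in ms.
#' @export
latency_index <- function(latency_ms, cap = 300) {
  pmin(ifelse(is.na(latency_ms), cap, latency_ms), cap)
}

#' Path strengths of the XOR network
#'
#' For every (input, output) pair, the product of the mean input-to-middle
#' weight and the mean middle-to-output weight, taken over the middle group of
#' that input (the middles whose nearest — hence strongly wired — input it is)
#' restricted to those projecting to that output. The strong initial path has
#' strength 0.2 * 0.2 = 0.04. Percentage change is relative to the initial
#' weights.
#'
#' @param net a Task 3 `polywave_network`.
#' @param S current weight vector (defaults to the network's initial weights).
#' @param S_init initial weight vector for the percentage change.
#' @return data.frame with `input`, `output`, `strength`, `initial`,
#'   `pct_change`.
#' @export
path_strength_task3 <- function(net, S = net$edges$weight,
                                S_init = net$edges$weight) {
  stopifnot(net$task == 3)
  e <- net$edges
  inputs <- which(net$roles == "stimulated")
  outputs <- which(net$roles %in% c("target", "false_target"))
  in_names <- c("0a", "1a", "0b", "1b")[seq_along(inputs)]
  out_names <- ifelse(net$roles[outputs] == "target", "T", "F")
  mids <- which(net$roles == "middle")
  nearest <- inputs[vapply(mids, function(m)
    which.min(abs(net$coords[inputs, 1] - net$coords[m, 1])), integer(1))]
  strength_of <- function(S, a, o) {
    grp <- mids[nearest == a]
    grp <- grp[grp %in% e$pre[e$post == o]]
    if (!length(grp)) return(0)
    w_in <- mean(S[e$pre == a & e$post %in% grp])
    w_out <- mean(S[e$post == o & e$pre %in% grp])
    w_in * w_out
  }
  grid <- expand.grid(ai = seq_along(inputs), oi = seq_along(outputs))
  out <- data.frame(
    input = in_names[grid$ai], output = out_names[grid$oi],
    strength = mapply(function(a, o) strength_of(S, inputs[a], outputs[o]),
                      grid$ai, grid$oi),
    initial = mapply(function(a, o) strength_of(S_init, inputs[a], outputs[o]),
                     grid$ai, grid$oi))
  out$pct_change <- ifelse(out$initial > 0,
                           100 * (out$strength / out$initial - 1), NA_real_)
  out
}

#' Directional mean weight-change map
#'
#' For each neuron, the average over its incident edges of the weight change
#' times the unit displacement vector of the edge (presynaptic to
#' postsynaptic), so that strengthened outbound paths show as arrows along
#' them and an edge traversed in the opposite direction contributes with a
#' minus sign.
#'
#' @param net a `polywave_network`.
#' @param S_now,S_init weight vectors on the same topology.
#' @return data.frame with `neuron`, `x`, `y`, `dx`, `dy`.
#' @export
mean_weight_difference_map <- function(net, S_now, S_init = net$edges$weight) {
  e <- net$edges
  disp <- net$coords[e$post, , drop = FALSE] - net$coords[e$pre, , drop = FALSE]
  len <- sqrt(rowSums(disp^2))
  unit <- disp / len
  dS <- S_now - S_init
  vx <- dS * unit[, 1]; vy <- dS * unit[, 2]
  out <- data.frame(neuron = seq_len(net$n), x = net$coords[, 1],
                    y = net$coords[, 2], dx = 0, dy = 0)
  inc <- c(e$pre, e$post)
  cx <- c(vx, vx); cy <- c(vy, vy)
  sx <- tapply(cx, inc, mean); sy <- tapply(cy, inc, mean)
  out$dx[as.integer(names(sx))] <- as.numeric(sx)
  out$dy[as.integer(names(sy))] <- as.numeric(sy)
  out
}

#' Firing rate of an isolated neuron at fixed noise
#'
#' Simulates a single unconnected, unstimulated leaky integrate-and-fire
#' neuron at a constant noise level and reports its mean firing rate — the
#' up/downstate calibration anchor (about 5 Hz at sigma = 6 mV, about 0 Hz at
#' sigma = 3 mV).
#'
#' @param sigma noise level (mV).
#' @param duration_ms simulated time per seed (ms).
#' @param seeds integer vector of seeds (one simulation each).
#' @param cfg a `polywave_config`.
#' @return mean firing rate across seeds (Hz).
#' @export
isolated_neuron_rate <- function(sigma, duration_ms = 10000, seeds = 1:5,
                                 cfg = pw_config()) {
  rates <- vapply(seeds, function(s) {
    set.seed(s)
    res <- sim_trial_cpp(
      n = 1L, pre = integer(0), post = integer(0),
      S_in = numeric(0), c_in = numeric(0), fbar_in = 0,
      par = unclass(cfg), stim_ids = integer(0),
      target_ids = integer(0), false_ids = integer(0),
      task = 1L, wave = FALSE, tonic = FALSE, phasic = FALSE,
      plastic = FALSE, sigma_const = sigma, d_t_eff = 0, d_p_eff = 0,
      novelty = 0, duration_ms = duration_ms)
    length(res$spike_id) / (duration_ms / 1000)
  }, numeric(1))
  mean(rates)
}

#' Calibrate the no-wave constant noise level
#'
#' The no-wave conditions use a constant noise level chosen so that the mean
#' population firing rate matches the wave condition. This routine measures
#' the wave condition's rate over a few non-plastic stimulated trials and
#' bisects `sigma_const` in `[sigma_min, sigma_max]` until the no-wave rate
#' matches within `tol` (relative).
#'
#' @param net a `polywave_network`.
#' @param cfg a `polywave_config`.
#' @param n_trials trials per rate measurement.
#' @param tol relative rate tolerance.
#' @param seed RNG seed for the measurement trials.
#' @param max_iter bisection iterations.
#' @return list with `sigma_const`, `wave_rate`, `nowave_rate` (Hz per
#'   neuron).
#' @export
calibrate_sigma <- function(net, cfg = pw_config(task = net$task),
                            n_trials = 5, tol = 0.1, seed = 1,
                            max_iter = 20) {
  pop_rate <- function(condition, sigma_const) {
    cfg$sigma_const <- sigma_const
    set.seed(seed)
    tot <- 0
    for (i in seq_len(n_trials)) {
      tr <- run_trial(net, cfg, condition, plastic = FALSE,
                      pattern = ((i - 1L) %% length(net$stim_patterns)) + 1L)
      tot <- tot + nrow(tr$spikes)
    }
    tot / n_trials / net$n / (cfg$trial_duration / 1000)
  }
  target <- pop_rate(pw_condition("full"), cfg$sigma_const)
  lo <- cfg$sigma_min; hi <- cfg$sigma_max
  mid <- (lo + hi) / 2; rate <- NA
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    rate <- pop_rate(pw_condition("conventional"), mid)
    if (abs(rate - target) <= tol * target) break
    if (rate > target) hi <- mid else lo <- mid
  }
  list(sigma_const = mid, wave_rate = target, nowave_rate = rate)
}
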