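#' Model configuration with calibrated defaults
#'
#' Builds the flat list of model parameters used by every simulation function.
#' Most values are fixed constants of the model (membrane, synaptic, plasticity
#' and wavefield time constants); three parameters are task-dependent knobs
#' (`beta`, the global inhibitory feedback strength; `d_p`, the phasic dopamine
#' amplitude; `eta`, the wavefield drive gain) and are filled in per task by
#' [task_defaults()] when a `task` is given.
#'
#' Units: potentials and drives in mV, times and time constants in ms, weights
#' and dopamine variables dimensionless. The membrane noise term adds
#' `noise_gain * sigma * sqrt(dt) * N(0,1)` per step; `noise_gain = 0.5` is
#' calibrated so that an isolated neuron fires at roughly 5 Hz at the upstate
#' noise level (sigma = 6 mV) and is essentially silent at the downstate level
#' (sigma = 3 mV).
#'
#' @param task optional task id (1, 2 or 3); merges task-dependent defaults.
#' @param ... named overrides of individual keys; unknown keys are an error.
#' @return a named list of class `polywave_config`.
#' @seealso [load_config()], [write_config()], [task_defaults()]
#' @export
#' @examples
#' cfg <- pw_config(task = 1)
#' cfg$S_max
pw_config <- function(task = NULL, ...) {
  cfg <- list(
    # integration
    dt = 0.1,                # ms, forward Euler(-Maruyama) step
    # membrane (leaky integrate-and-fire)
    v0 = -70, v_th = -54, v_reset = -60, tau_m = 10,
    # recurrent synapses
    tau_h = 5, h0 = 60, t_d = 2,
    # global inhibitory feedback
    tau_inh = 5, t_h = 1, beta = 1,
    # external stimulation (200 Hz pulse train during the first 250 ms);
    # 25 mV pulses make a resting neuron spike once per pulse, so stimulated
    # neurons fire at the pulse rate
    t_on = 0, t_off = 250, pulse_period = 5, pulse_amplitude = 25,
    # plasticity
    S_max = 0.24, gamma = 9e-4, ltd_factor = 1.05,
    tau_stdp = 30, tau_c = 1000, tau_s = 1,
    # dopamine
    d_t = 0.003, d_p = 0.05, tau_p = 200, t_p = 100, tau_d = 200,
    dp_bound = 0.3, novelty_step = 0.2, decline_fraction = 0.2,
    # wavefield
    tau_w = 200, delta_t = 20, theta = 0.001, eta = 1,
    kappa_in = 0.01, kappa_out = 0.005,
    psi_min = -1, psi_max = 100, g_post = -5,
    sigma_base = 3, sigma_min = 3, sigma_max = 6,
    sigma_const = 4,         # no-wave noise level, calibrated per task
    noise_gain = 0.5,
    # networks
    task1_weight_init = 0.12,
    task2_base_weight = 0.04, task2_detour_factor = 3, task2_grid_n = 5,
    pair_connect_rule = "unordered",
    # experiment
    trial_duration = 3000, n_trials = 80
  )
  if (!is.null(task)) cfg <- utils::modifyList(cfg, task_defaults(task))
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop(config_key_error(bad, names(cfg)), call. = FALSE)
    cfg <- utils::modifyList(cfg, dots)
  }
  class(cfg) <- "polywave_config"
  validate_config(cfg)
  cfg
}

#' Task-dependent parameter defaults
#'
#' The inhibitory feedback strength `beta`, the phasic dopamine amplitude
#' `d_p` and the wavefield drive gain `eta` depend on the task's network size
#' and architecture. The values here are package calibrations chosen so that
#' the full model (waves + tonic dopamine) reaches each task's qualitative
#' outcome; `sigma_const` is the no-wave noise level matched to the wave
#' condition's population firing rate (see [calibrate_sigma()]), and
#' `n_trials` is the task's standard trial count.
#'
#' @param task task id: 1 (path reinforcement), 2 (shortcut), 3 (XOR).
#' @return named list of overrides for [pw_config()].
#' @export
task_defaults <- function(task) {
  switch(as.character(task),
    "1" = list(beta = 1, d_p = 0.3, eta = 8, sigma_const = 4.875,
               n_trials = 80),
    "2" = list(beta = 0.3, d_p = 0.2, eta = 6, sigma_const = 5.0625,
               n_trials = 60),
    "3" = list(beta = 1.5, d_p = 0.04, eta = 0.8, sigma_const = 4.125,
               n_trials = 100),
    stop("unknown task id: ", task, " (must be 1, 2 or 3)", call. = FALSE)
  )
}

config_key_error <- function(bad, known) {
  hints <- vapply(bad, function(k) {
    d <- utils::adist(k, known)
    near <- known[which.min(d)]
    if (min(d) <= 2) sprintf("'%s' (did you mean '%s'?)", k, near)
    else sprintf("'%s'", k)
  }, character(1))
  paste0("unknown config key(s): ", paste(hints, collapse = ", "))
}

validate_config <- function(cfg) {
  stopifnot_msg <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  pos <- c("dt", "tau_m", "tau_h", "tau_inh", "tau_stdp", "tau_c", "tau_s",
           "tau_p", "tau_d", "tau_w", "delta_t", "pulse_period",
           "trial_duration")
  for (k in pos) stopifnot_msg(cfg[[k]] > 0, paste0("config key '", k, "' must be > 0"))
  stopifnot_msg(cfg$v_reset > cfg$v0, "v_reset must exceed the resting potential v0")
  stopifnot_msg(cfg$v_th > cfg$v_reset, "v_th must exceed v_reset")
  stopifnot_msg(cfg$dt < min(cfg$tau_m, cfg$tau_h, cfg$tau_inh),
                "dt must be smaller than every time constant")
  stopifnot_msg(cfg$t_off > cfg$t_on, "t_off must exceed t_on")
  stopifnot_msg(cfg$S_max > 0, "S_max must be positive")
  stopifnot_msg(cfg$dp_bound > 0, "dp_bound must be positive")
  stopifnot_msg(cfg$sigma_max >= cfg$sigma_min, "sigma bounds must be ordered")
  stopifnot_msg(cfg$psi_max > cfg$psi_min, "psi bounds must be ordered")
  stopifnot_msg(cfg$novelty_step >= 0 && cfg$novelty_step <= 1,
                "novelty_step must lie in [0, 1]")
  stopifnot_msg(cfg$decline_fraction >= 0 && cfg$decline_fraction < 1,
                "decline_fraction must lie in [0, 1)")
  stopifnot_msg(cfg$pair_connect_rule %in% c("unordered", "ordered"),
                "pair_connect_rule must be 'unordered' or 'ordered'")
  for (k in c("t_d", "t_h", "t_p", "delta_t", "pulse_period")) {
    r <- cfg[[k]] / cfg$dt
    stopifnot_msg(abs(r - round(r)) < 1e-9,
                  paste0("delay '", k, "' must be a multiple of dt"))
  }
  invisible(cfg)
}

#' Read a configuration from a flat key = value file
#'
#' The file format is one `key = value` pair per line; blank lines and lines
#' starting with `#` are ignored. Values are parsed as numbers when possible,
#' otherwise kept as strings. Keys absent from the file take the package
#' defaults of [pw_config()]; unknown keys are rejected with a suggestion.
#'
#' @param path file to read.
#' @param task optional task id applied before the file's overrides.
#' @return a validated `polywave_config`.
#' @export
load_config <- function(path, task = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("malformed config line: '", ln, "'", call. = FALSE)
    key <- trimws(parts[1]); val <- trimws(parts[2])
    num <- suppressWarnings(as.numeric(val))
    kv[[key]] <- if (!is.na(num)) num else val
  }
  do.call(pw_config, c(list(task = task), kv))
}

#' Write a configuration to a flat key = value file
#'
#' @param cfg a `polywave_config`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "polywave_config"))
  vals <- vapply(cfg, function(v) as.character(v), character(1))
  writeLines(paste(names(cfg), "=", vals), path)
  invisible(path)
}

#' @export
print.polywave_config <- function(x, ...) {
  cat("<polywave_config> ", length(x), " parameters\n", sep = "")
  cat(sprintf("  task trio: beta = %g, d_p = %g, eta = %g\n",
              x$beta, x$d_p, x$eta))
  cat(sprintf("  dt = %g ms, trial = %g ms, trials = %d\n",
              x$dt, x$trial_duration, as.integer(x$n_trials)))
  invisible(x)
}
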