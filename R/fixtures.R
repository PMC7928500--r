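#' Two-neuron fixture with scripted spike trains
#'
#' Builds a minimal network of one presynaptic and one postsynaptic neuron
#' joined by a single edge, with clamped (scripted) spike times that bypass
#' the membrane dynamics entirely. Used to test the STDP eligibility-trace
#' rule exactly against closed forms and a brute-force pairwise oracle.
#'
#' @param spike_times_pre,spike_times_post sorted spike times (ms) of the
#'   presynaptic and postsynaptic neuron.
#' @return list of class `polywave_fixture` with the edge (pre = 1, post = 2)
#'   and an event table sorted by time.
#' @export
make_two_neuron_fixture <- function(spike_times_pre, spike_times_post) {
  if (is.unsorted(spike_times_pre) || is.unsorted(spike_times_post))
    stop("spike time lists must be sorted")
  events <- rbind(
    data.frame(time = as.numeric(spike_times_pre),
               neuron = rep(1L, length(spike_times_pre))),
    data.frame(time = as.numeric(spike_times_post),
               neuron = rep(2L, length(spike_times_post))))
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL
  out <- list(edges = data.frame(pre = 1L, post = 2L, weight = 0),
              events = events, n = 2L)
  class(out) <- "polywave_fixture"
  out
}

#' Event-driven eligibility trace on a scripted fixture
#'
#' Evolves the eligibility trace `c` and the spike traces `fbar` of a
#' [make_two_neuron_fixture()] exactly in continuous time: between events both
#' decay analytically (`tau_c`, `tau_stdp`); at a spike of the postsynaptic
#' neuron `c` gains `gamma * fbar_pre`, at a spike of the presynaptic neuron
#' it loses `ltd_factor * gamma * fbar_post`, coincident events use the
#' pre-jump traces, the spiking neuron's trace then jumps to 1, and `c` is
#' clipped to `[-S_max/2, S_max/2]`.
#'
#' @param fixture a `polywave_fixture`.
#' @param cfg a `polywave_config`.
#' @param t_end time at which to report the final state (default: last event).
#' @return list with final `c`, `fbar`, and the per-event trace `history`.
#' @export
run_stdp_fixture <- function(fixture, cfg = pw_config(),
                             t_end = max(fixture$events$time, 0)) {
  ev <- fixture$events
  cc <- 0; fbar <- c(0, 0); t_cur <- 0
  hist <- numeric(0)
  for (tm in unique(ev$time)) {
    gap <- tm - t_cur
    cc <- cc * exp(-gap / cfg$tau_c)
    fbar <- fbar * exp(-gap / cfg$tau_stdp)
    t_cur <- tm
    who <- ev$neuron[ev$time == tm]
    dc <- 0
    if (2L %in% who) dc <- dc + cfg$gamma * fbar[1]            # pre-before-post
    if (1L %in% who) dc <- dc - cfg$ltd_factor * cfg$gamma * fbar[2]
    cc <- cc + dc
    bound <- cfg$S_max / 2
    cc <- min(max(cc, -bound), bound)
    fbar[who] <- fbar[who] + 1
    hist <- c(hist, cc)
  }
  if (t_end > t_cur) {
    cc <- cc * exp(-(t_end - t_cur) / cfg$tau_c)
    fbar <- fbar * exp(-(t_end - t_cur) / cfg$tau_stdp)
  }
  list(c = cc, fbar = fbar, history = hist)
}
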