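# Brute-force pairwise STDP oracle for the two-neuron fixture.
#
# With accumulating spike traces, the eligibility at time t_end equals the sum
# over all ordered spike pairs of the window value, each contribution decaying
# with tau_c from the moment of the later (triggering) spike:
#   post spike at t with pre spike at s < t:  +gamma     * exp(-(t-s)/tau_stdp)
#   pre  spike at t with post spike at s < t: -1.05gamma * exp(-(t-s)/tau_stdp)
# Coincident spikes (s == t) contribute nothing because increments use the
# traces before either spike's jump. Valid while |c| never hits its bounds.
stdp_pair_oracle <- function(pre, post, t_end = max(c(pre, post, 0)),
                             cfg = pw_config()) {
  total <- 0
  for (t in post) {
    s <- pre[pre < t]
    if (length(s))
      total <- total + cfg$gamma * sum(exp(-(t - s) / cfg$tau_stdp)) *
        exp(-(t_end - t) / cfg$tau_c)
  }
  for (t in pre) {
    s <- post[post < t]
    if (length(s))
      total <- total - cfg$ltd_factor * cfg$gamma *
        sum(exp(-(t - s) / cfg$tau_stdp)) * exp(-(t_end - t) / cfg$tau_c)
  }
  total
}

# Directly coded indicator forms of the three reward functions, used to
# cross-check compute_reward() by exhaustive enumeration.
reward_indicator_oracle <- function(task, n_true, n_false) {
  if (task == 1) {
    gate <- as.numeric(n_true + sum(n_false) > 5)
    (-0.5 + 1.5 * as.numeric(n_true > max(n_false))) * gate
  } else if (task == 2) {
    as.numeric(n_true > 0)
  } else {
    as.numeric(n_true >= n_false + 5) - as.numeric(n_false >= n_true + 5)
  }
}

# A directed chain network (1 -> 2 -> ... -> n) for wavefront tests.
chain_network <- function(n, weight = 0.12) {
  coords <- cbind(x = seq(100, by = 100, length.out = n), y = 100)
  edges <- data.frame(pre = seq_len(n - 1), post = 2:n, weight = weight)
  net <- list(n = n, coords = coords,
              roles = c("stimulated", rep("plain", n - 1)),
              edges = edges, task = 1L,
              stim_patterns = list(1L),
              pattern_targets = list(as.integer(n)),
              pattern_false = list(integer(0)))
  class(net) <- "polywave_network"
  net
}
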