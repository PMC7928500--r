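Package: polywave
Title: Traveling-Wave-Assisted Reward-Modulated STDP in Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates small excitatory leaky integrate-and-fire networks in
    which traveling waves of elevated membrane noise (upstates) combine with a
    reward-modulated spike-timing-dependent plasticity rule carrying both tonic
    and phasic dopamine components. Provides builders for three benchmark task
    networks (poly-synaptic path reinforcement on a lattice, shortcut finding,
    and XOR learning in a feedforward sheet), a fast compiled trial integrator,
    experiment drivers with ablation conditions (waves, tonic and phasic
    dopamine), and metrics such as success rate, first-spike latency index and
    path strength.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
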