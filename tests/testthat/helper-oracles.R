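# Independent oracles used across the suite.

# Classical RK4 integration of the single-neuron equations at a fine step,
# with the channel kinetics written out explicitly (independent of the C++
# exponential-Euler engine it validates). Byte-compiled inline arithmetic:
# a 10 s / 0.01 ms run is ~1e6 steps.
rk4_neuron <- function(params, duration_ms, dt = 0.01, V0 = params$EL,
                       gSynE = 0, threshold = -10,
                       syn = synaptic_parameters()) {
  gNa <- params$gNa; gNaP <- if (isTRUE(params$has_inap)) params$gNaP else 0
  gK <- params$gK; gL <- params$gL; EL <- params$EL
  ENa <- params$ENa; EK <- params$EK; C <- params$C
  EsE <- syn$EsynE
  deriv <- function(s) {
    V <- s[1]; hNa <- s[2]; hNaP <- s[3]; mK <- s[4]
    mNa <- 1 / (1 + exp(-(V + 34) / 7.8))
    g_na <- gNa * mNa * mNa * mNa * hNa
    g_nap <- gNaP * hNaP / (1 + exp(-(V + 47.1) / 3.1))
    mk2 <- mK * mK
    I <- (g_na + g_nap) * (V - ENa) + gK * mk2 * mk2 * (V - EK) +
      gL * (V - EL) + gSynE * (V - EsE)
    c(-I / C,
      (1 / (1 + exp((V + 55) / 7)) - hNa) *
        (exp((V + 50) / 15) + exp(-(V + 50) / 16)) / 20,
      (1 / (1 + exp((V + 60) / 6.5)) - hNaP) * cosh((V + 60) / 13) / 18000,
      (1 / (1 + exp(-(V + 28) / 4)) - mK) * cosh((V + 40) / 40) / 3.5)
  }
  s <- c(V0,
         1 / (1 + exp((V0 + 55) / 7)),
         1 / (1 + exp((V0 + 60) / 6.5)),
         1 / (1 + exp(-(V0 + 28) / 4)))
  n <- round(duration_ms / dt)
  n_spikes <- 0L
  above <- s[1] >= threshold
  h2 <- dt / 2
  for (i in seq_len(n)) {
    k1 <- deriv(s)
    k2 <- deriv(s + h2 * k1)
    k3 <- deriv(s + h2 * k2)
    k4 <- deriv(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (s[1] >= threshold) {
      if (!above) { n_spikes <- n_spikes + 1L; above <- TRUE }
    } else above <- FALSE
  }
  n_spikes
}

# Explicit evaluation of the exponential-sum synaptic conductance for a
# recorded spike train: g(t) = sum over spikes before t of inc * exp(-(t-tk)/tau).
explicit_syn_sum <- function(spike_times, t, inc, tau) {
  past <- spike_times[spike_times <= t]
  sum(inc * exp(-(t - past) / tau))
}

# Shared expensive simulations, memoised across test files (helpers are
# sourced once per test run).
.run_cache <- new.env(parent = emptyenv())
cached <- function(key, fn) {
  if (!exists(key, envir = .run_cache)) assign(key, fn(), envir = .run_cache)
  get(key, envir = .run_cache)
}

quarter_run <- function(topology, alpha, record_s = 60, settle_s = 15,
                        build_seed = 42, run_seed = 7) {
  key <- paste("q", topology, alpha, record_s, settle_s, build_seed, run_seed,
               sep = "_")
  cached(key, function() {
    net <- default_model("drug", topology, alpha = alpha, scale = 0.25,
                         seed = build_seed)
    run_simulation(net, config = sim_config(settle_s = settle_s,
                                            record_s = record_s),
                   seed = run_seed)
  })
}
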