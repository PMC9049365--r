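# Small fixtures shared across test files. Everything is generated in code.

tiny_network <- function(N_E = 6, N_I = 4, seed = 1, ...) {
  build_network(network_config(N_E = N_E, N_I = N_I, ...),
                default_params(), seed = seed)
}

short_protocol <- function(trial_ms = 200) {
  stimulus_protocol(pulse_ms = 50, rate_hz = 10, trial_ms = trial_ms)
}

# Independent fine-step integration of the Tsodyks-Markram equations for an
# arbitrary spike train, used as the oracle for measure_ppr and step_stp.
stp_brute_force <- function(spike_times, U, F, tau_u, tau_R, dt = 0.01,
                            t_max = max(spike_times) + dt) {
  u <- U; R <- 1
  releases <- numeric(0)
  steps <- ceiling(t_max / dt)
  spike_steps <- round(spike_times / dt)
  for (k in seq_len(steps)) {
    u <- u + dt * (U - u) / tau_u
    R <- R + dt * (1 - R) / tau_R
    if (k %in% spike_steps) {
      u <- u + (1 - u) * F       # facilitation applies before release
      releases <- c(releases, u * R)
      R <- R - u * R
    }
  }
  releases
}

# Cache for expensive trained networks shared between test files (built at
# most once per test run).
.train_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .train_cache)) {
    assign(key, force(expr), envir = .train_cache)
  }
  get(key, envir = .train_cache)
}
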