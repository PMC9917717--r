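# shared fixtures: compact grids and experiment configurations used across
# test files so individual tests stay fast

# mid-band grid for fast coherence tests (34 bands, 0.02-0.2 Hz)
small_grid <- function() band_grid(0.02, 0.2, 10)

# grid used by the scaled-down end-to-end experiments: 1/10-octave bands
# covering the candidate window 0.03-0.1 Hz with margin
e2e_grid <- function() band_grid(0.0212, 0.1484, 10)

qwtc <- function(x, y, fs = 10, grid = band_grid(), ...) {
  suppressWarnings(wtc(x, y, fs, grid, ...))
}

# study-condition parameters of the event-locked recovery experiment:
# coupling on the identical pair (2, 2) at 0.09 Hz, active only during
# either-up epochs, with the hemodynamic 5 s response delay
e2e_params <- function(amplitude = 3, n_channels = 3, duration = 600) {
  sim_params(n_channels = n_channels, duration = duration,
             coupling_pairs = data.frame(a = 2, b = 2, freq_hz = 0.09,
                                         amplitude = amplitude),
             lock = "either")
}

# one full pipeline run at the reduced test scale; returns the analysis
run_e2e_once <- function(seed, amplitude = 3, n_dyads = 20) {
  exp <- simulate_experiment(n_dyads, e2e_params(amplitude), seed = seed)
  suppressMessages(
    analyze_experiment(exp, grid = e2e_grid(), within = FALSE))
}

# brute-force reference for Storey's q-values (independent of the
# implementation): direct evaluation of the estimator definition
brute_force_qvalues <- function(p, lambda = 0.5) {
  m <- length(p)
  pi0 <- sum(p > lambda) / (m * (1 - lambda))
  pi0 <- min(1, max(pi0, 1 / m))
  r <- rank(p, ties.method = "max")
  q <- vapply(seq_len(m), function(i) {
    geq <- p >= p[i]
    min(pmin(pi0 * m * p[geq] / r[geq], 1))
  }, numeric(1))
  q
}
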