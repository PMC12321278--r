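# Shared fixtures: a reduced acquisition geometry (2 ns window at 2 ps
# channels, 1000 channels) that keeps unit tests fast while preserving
# the physics, and a fit configuration with a smaller population and
# generation cap suited to these problem sizes.

small_sim <- function(seed = 1, budget = 2e5,
                      model = decay_model(c(3, 1), c(0.010, 0.050)),
                      channel_width = 2e-3, n_frames = 6L,
                      drift = drift_spec("none"), ...) {
  simulation_config(channel_width = channel_width, photon_budget = budget,
                    true_model = model, seed = seed, n_frames = n_frames,
                    drift = drift, ...)
}

fast_cfg <- function(seed = 1, n = 2L, de_max_iter = 150L, ...) {
  fit_config(n_components = n, de_population = 12L,
             de_max_iter = de_max_iter, seed = seed, ...)
}

# analytic signal for a single-exponential decay convolved with a
# Gaussian IRF of mean mu / sd sigma (exponentially modified Gaussian),
# on the channel_width * unit-sum-IRF scale used by convolve_model
emg_signal <- function(t, A, tau, mu, sigma, channel_width) {
  z <- (sigma / tau - (t - mu) / sigma) / sqrt(2)
  channel_width * (A / 2) * exp(sigma^2 / (2 * tau^2) - (t - mu) / tau) *
    2 * stats::pnorm(z * sqrt(2), lower.tail = FALSE)
}
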