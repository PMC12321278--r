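# flimrecon

Reconvolution fitting and photodegradation time-series analysis for
time-correlated single-photon counting (TCSPC) fluorescence lifetime
data at picosecond resolution.

The package targets the kind of acquisition used to watch pigment
organelles (melanosomes) degrade under continuous laser exposure: a
2 ns window sampled at ≈0.5 ps channels, an instrument response
function (IRF) of ≈20 ps FWHM, and fluorescence lifetimes well below
0.1 ns — shorter than or comparable to the IRF itself, so the decay
parameters can only be recovered by reconvolution.

## The model

The measured signal is modeled as the convolution of a
multi-exponential decay with the measured instrument response,

    S(t) = ∫₀^∞ F(t′) R(t − t′ − Δt) dt′,
    F(t) = Σᵢ Aᵢ exp(−t / τᵢ),   i = 1 … n,  n ≤ 3,

where R is the unit-normalized IRF, Δt a non-integer channel alignment
shift, and (Aᵢ, τᵢ) the component amplitudes and lifetimes (τ₁ fast,
τ₂ slow).  Fitting uses variable projection: Differential Evolution
searches (τ₁ … τₙ, Δt) globally — lifetimes on a log scale — while the
amplitudes are solved exactly at every trial point by non-negative
least squares.  Goodness of fit is the Poisson-weighted reduced χ²
with pre-smoothing raw counts as weights; uncertainties come from a
parametric bootstrap (Poisson resampling of the fitted curve).
Around the fitter: Savitzky–Golay smoothing of signal and IRF,
per-minute frame metrics (peak counts, total counts, temporal FWHM),
per-frame lifetime and A₁/A₂ amplitude-ratio trajectories, a robust
Huber-loss polynomial trend between τ₁ and τ₂, and a synthetic
generator that emulates the whole acquisition including slow
photodegradation drifts.

## Worked example

Simulate one recording at the reference geometry (2 ns window, 0.5 ps
channels, 20 ps IRF, τ = 10/50 ps at amplitude ratio 3:1, 10⁶
photons), then fit it with smoothing:

```r
library(flimrecon)
cfg   <- simulation_config(seed = 42)
irf   <- make_irf(cfg)
decay <- simulate_decay(cfg)
fit   <- flim_fit(decay, irf, fit_config(seed = 42, smooth = TRUE))
fit
#> Reconvolution fit (2-exponential, DE + NNLS)
#> 2-exponential decay model
#>   tau1 = 0.01013 ns  (A1 = 3.669e+07)
#>   tau2 = 0.05004 ns  (A2 = 1.227e+07)
#>   IRF shift    = -2.519e-05 ns
#>   reduced chi2 = 0.06056  (poisson weights)
#>   converged after 58 generations, 1854 objective evaluations (seed 42)
summary(fit)
#> Reconvolution fit summary
#>  component  tau_ns amplitude intensity_fraction
#>          1 0.01013  36694705              0.377
#>          2 0.05004  12267563              0.623
#>   amplitude ratio A1/A2 = 2.991
#>   IRF shift -2.519e-05 ns; reduced chi2 0.06056 over 4000 channels; converged
```

Both true lifetimes (10 and 50 ps) are recovered to ≈0.3 % and 0.1 %,
the amplitude ratio to 0.3 %, and the reduced χ² is well below 1 — the
signature of fitting Savitzky–Golay-smoothed data with raw-count
Poisson weights.  `plot(fit)` shows the fit over the data with the
weighted residuals; `confint(fit)` gives bootstrap intervals.

For a 60-minute degradation series:

```r
series <- simulate_series(simulation_config(seed = 7))  # 60 frames + truth
sr     <- fit_series(series, fit_config(seed = 7))
plot(sr)                 # intensity, FWHM, tau trajectories, A1/A2 ratio
lifetime_trend(sr)       # Huber-loss quadratic tau2 ~ tau1
```

A command-line interface wraps the same functions
(`exec/flimrecon simulate|fit|metrics|series|validate`).

## Documentation

The methods vignette (`vignettes/reconvolution.Rmd`) describes the
model and its assumptions, the numerical choices (quadrature,
optimizer strategy, χ² convention), what the synthetic generator does
and does not emulate, and known limitations.
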