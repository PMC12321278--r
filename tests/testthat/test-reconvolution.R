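# The fitting engine: NNLS amplitudes, DE + variable projection,
# goodness of fit, model selection and bootstrap uncertainty.

test_that("NNLS recovers amplitudes exactly on self-consistent input", {
  cfg <- small_sim()
  irf <- make_irf(cfg)
  m <- decay_model(c(500, 200), c(0.01, 0.05))
  h <- decay_histogram(irf$time, convolve_model(m, irf, 0))
  sol <- solve_amplitudes(c(0.01, 0.05), 0, h, irf, weighting = "uniform")
  expect_lt(max(abs(sol$amplitudes - c(500, 200)) / c(500, 200)), 1e-6)

  # a single unit basis comes back as (1, 0)
  b1 <- convolve_model(decay_model(1, 0.01), irf, 0)
  h1 <- decay_histogram(irf$time, b1)
  sol1 <- solve_amplitudes(c(0.01, 0.05), 0, h1, irf, weighting = "uniform")
  expect_lt(abs(sol1$amplitudes[1] - 1), 1e-9)
  expect_lt(abs(sol1$amplitudes[2]), 1e-9)
})

test_that("NNLS amplitudes are never negative and degeneracy is caught", {
  cfg <- small_sim()
  irf <- make_irf(cfg)
  set.seed(17)
  for (i in 1:10) {
    h <- decay_histogram(irf$time, rpois(length(irf$time), 20))
    sol <- solve_amplitudes(sort(runif(2, 2e-3, 0.3)), 0, h, irf)
    expect_true(all(sol$amplitudes >= 0))
  }
  h <- simulate_decay(cfg)
  expect_error(solve_amplitudes(c(0.01, 0.01 + 1e-7), 0, h, irf),
               class = "flimrecon_degeneracy_error")
})

test_that("a noiseless single exponential is recovered to 0.1%", {
  cfg <- small_sim(model = decay_model(1, 0.05))
  irf <- make_irf(cfg)
  y <- convolve_model(cfg$true_model, irf, 0)
  h <- decay_histogram(irf$time, y * (1e6 / sum(y)))
  fit <- flim_fit(h, irf, fast_cfg(seed = 2, n = 1, weighting = "uniform"))
  expect_lt(abs(fit$model$lifetimes - 0.05) / 0.05, 1e-3)
  expect_lt(abs(fit$irf_shift), 1e-4)
})

test_that("two-component fits always report tau1 < tau2", {
  for (s in 1:3) {
    cfg <- small_sim(seed = 400 + s, budget = 1e5)
    fit <- flim_fit(simulate_decay(cfg), make_irf(cfg), fast_cfg(seed = s))
    expect_lt(fit$model$lifetimes[1], fit$model$lifetimes[2])
  }
})

test_that("fits are bit-reproducible under a fixed seed", {
  cfg <- small_sim(seed = 77, budget = 5e4, channel_width = 4e-3)
  irf <- make_irf(cfg)
  dec <- simulate_decay(cfg)
  f1 <- flim_fit(dec, irf, fast_cfg(seed = 123))
  f2 <- flim_fit(dec, irf, fast_cfg(seed = 123))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$reduced_chi2, f2$reduced_chi2)
})

test_that("DE matches an exhaustive lifetime grid search", {
  # 2-parameter single-exponential problem with the shift pinned near 0;
  # brute-force oracle: weighted SSE on a 10^4-point lifetime grid
  cfg <- small_sim(seed = 9, budget = 1e5, model = decay_model(1, 0.035),
                   channel_width = 4e-3)
  irf <- make_irf(cfg)
  dec <- simulate_decay(cfg)
  grid <- seq(1e-3, 0.2, length.out = 1e4)
  sse <- vapply(grid, function(tau)
    solve_amplitudes(tau, 0, dec, irf)$sse, numeric(1))
  tau_grid <- grid[which.min(sse)]
  fit <- flim_fit(dec, irf,
                  fast_cfg(seed = 9, n = 1,
                           shift_bounds = c(-1e-9, 1e-9)))
  step <- diff(grid)[1]
  expect_lt(abs(fit$model$lifetimes - tau_grid), step)
})

test_that("reduced chi-squared is zero for a perfect fit and self-consistent", {
  y <- c(5, 10, 20, 9, 3)
  expect_equal(reduced_chi2(y, y, 2), 0)
  expect_error(reduced_chi2(y, y, 5), class = "flimrecon_param_error")
  cfg <- small_sim(seed = 31, budget = 1e5)
  fit <- flim_fit(simulate_decay(cfg), make_irf(cfg), fast_cfg(seed = 31))
  raw <- fit$data$meta$raw_counts
  recomputed <- reduced_chi2(fit$data$counts, fit$fitted,
                             n_params = 2L * 2L + 1L,
                             weighting = "poisson",
                             raw_counts = if (is.null(raw)) NULL else raw)
  expect_identical(fit$reduced_chi2, recomputed)
})

test_that("Poisson chi-squared calibrates to 1 when the window is filled", {
  # correct model, raw Poisson noise, every channel populated: the
  # Neyman-weighted reduced chi-squared concentrates near 1
  chis <- sapply(1:15, function(s) {
    cfg <- small_sim(seed = 500 + s, budget = 5e5,
                     model = decay_model(1, 0.45), irf_center = 0.05)
    fit <- flim_fit(simulate_decay(cfg), make_irf(cfg),
                    fast_cfg(seed = 500 + s, n = 1))
    fit$reduced_chi2
  })
  expect_lt(abs(median(chis) - 1), 0.1)
})

test_that("Savitzky-Golay smoothing pulls the reduced chi-squared below 1", {
  chis <- sapply(1:8, function(s) {
    cfg <- small_sim(seed = 600 + s, budget = 2e5)
    fit <- flim_fit(simulate_decay(cfg), make_irf(cfg),
                    fast_cfg(seed = 600 + s, smooth = TRUE))
    fit$reduced_chi2
  })
  expect_lt(median(chis), 1)
})

test_that("model selection prefers the most parsimonious adequate model", {
  cfg1 <- small_sim(seed = 41, budget = 2e5, model = decay_model(1, 0.03))
  expect_equal(select_n_components(simulate_decay(cfg1), make_irf(cfg1),
                                   fast_cfg(seed = 41), n_max = 2L), 1L)
  cfg2 <- small_sim(seed = 42, budget = 5e5)  # tau ratio 5, well separated
  expect_equal(select_n_components(simulate_decay(cfg2), make_irf(cfg2),
                                   fast_cfg(seed = 42), n_max = 2L), 2L)
})

test_that("bootstrap intervals vanish with noise and widen when photons halve", {
  base <- small_sim(seed = 51, budget = 1e7, model = decay_model(1, 0.05),
                    channel_width = 4e-3)
  irf <- make_irf(base)
  y <- convolve_model(base$true_model, irf, 0)
  noiseless <- decay_histogram(irf$time, y * (1e7 / sum(y)))
  fit0 <- flim_fit(noiseless, irf, fast_cfg(seed = 51, n = 1))
  ci0 <- estimate_uncertainty(fit0, n_boot = 20)
  tau_row <- ci0[ci0$parameter == "tau1", ]
  expect_lt((tau_row$hi - tau_row$lo) / 2, 0.005 * tau_row$estimate)

  widths <- sapply(c(2e5, 5e4), function(budget) {
    med <- sapply(1:3, function(s) {
      cfg <- small_sim(seed = 700 + s, budget = budget,
                       model = decay_model(1, 0.05), channel_width = 4e-3)
      f <- flim_fit(simulate_decay(cfg), make_irf(cfg),
                    fast_cfg(seed = 700 + s, n = 1, de_max_iter = 80))
      ci <- estimate_uncertainty(f, n_boot = 20)
      r <- ci[ci$parameter == "tau1", ]
      r$hi - r$lo
    })
    median(med)
  })
  expect_lt(widths[1], widths[2])       # quarter budget -> wider interval
})

test_that("bootstrap intervals achieve near-nominal coverage", {
  # tested where the percentile interval is calibrated: a decay
  # populating every channel, so all counts are far from the Poisson
  # small-count regime and the estimator is unbiased
  hits <- sapply(1:30, function(s) {
    cfg <- small_sim(seed = 800 + s, budget = 5e5,
                     model = decay_model(1, 0.45), irf_center = 0.05,
                     channel_width = 8e-3)
    f <- flim_fit(simulate_decay(cfg), make_irf(cfg),
                  fast_cfg(seed = 800 + s, n = 1, de_max_iter = 60))
    ci <- estimate_uncertainty(f, n_boot = 20)
    r <- ci[ci$parameter == "tau1", ]
    r$lo <= 0.45 && 0.45 <= r$hi
  })
  expect_lt(abs(mean(hits) - 0.68), 0.15)
})

test_that("lifetime scatter grows as the lifetime approaches the window", {
  # dispersion of the recovered lifetime rises once the window no
  # longer comfortably contains the decay tail
  rec <- sapply(c(0.05, 0.5), function(tau) {
    est <- sapply(1:8, function(s) {
      cfg <- small_sim(seed = 930 + s, budget = 5e4,
                       model = decay_model(1, tau), channel_width = 8e-3)
      flim_fit(simulate_decay(cfg), make_irf(cfg),
               fast_cfg(seed = 930 + s, n = 1, de_max_iter = 80))$model$lifetimes
    })
    sd(est) / mean(est)
  })
  expect_gt(rec[2], rec[1])
})

test_that("degenerate inputs are rejected", {
  cfg <- small_sim()
  irf <- make_irf(cfg)
  zero <- decay_histogram(irf$time, numeric(length(irf$time)))
  expect_error(flim_fit(zero, irf, fast_cfg()),
               class = "flimrecon_data_error")
  other <- instrument_response(seq(0, by = 1e-3, length.out = 100),
                               rep(1, 100))
  expect_error(flim_fit(simulate_decay(cfg), other, fast_cfg()),
               class = "flimrecon_grid_error")
})
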