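# Domain types, validation and on-disk formats.

test_that("read_decay parses two-column text with metadata", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# units=ns", "# frame_index=3", "0.0 10", "0.0005 20",
               "0.001 5"), f)
  h <- read_decay(f)
  expect_s3_class(h, "decay_histogram")
  expect_length(h$counts, 3L)
  expect_equal(h$channel_width, 5e-4)
  expect_equal(sum(h$counts), 35)
  expect_equal(h$meta$frame_index, 3)
  expect_equal(h$window, 3 * 5e-4)
})

test_that("read_decay converts declared time units to nanoseconds", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# units=ps", "0 10", "0.5 20", "1 5"), f)
  h <- read_decay(f)
  expect_equal(h$channel_width, 5e-4)
  expect_equal(h$time, c(0, 5e-4, 1e-3))
})

test_that("malformed or invalid files produce informative format errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("0.001 10", "0.0005 20", "0.0 5"), f)   # decreasing time
  expect_error(read_decay(f), "increasing", class = "flimrecon_data_error")
  writeLines(c("0.0 10", "0.0005 oops"), f)
  expect_error(read_decay(f), ":2", class = "flimrecon_data_error")  # line no.
  writeLines(c("0.0 10", "0.0005 -4", "0.001 5"), f)
  expect_error(read_decay(f), "non-negative", class = "flimrecon_data_error")
  writeLines(c("0.0 10", "0.001 20", "0.0015 5"), f)   # non-uniform grid
  expect_error(read_decay(f), "uniform", class = "flimrecon_data_error")
  expect_error(read_decay(tempfile()), "not found",
               class = "flimrecon_data_error")
})

test_that("write_decay / read_decay round-trips to full precision", {
  f <- withr::local_tempfile(fileext = ".tsv")
  set.seed(42)
  h <- decay_histogram(seq(0, by = 5e-4, length.out = 200),
                       rpois(200, 50) + 0.123456789012345,
                       meta = list(label = "rt", frame_index = 7))
  write_decay(h, f)
  h2 <- read_decay(f)
  expect_identical(h2$counts, h$counts)           # bitwise on counts
  expect_true(max(abs(h2$time - h$time)) <= 1e-12)
  expect_equal(h2$meta$frame_index, 7)
  expect_error(write_decay(h, file.path(tempdir(), "no/such/dir/x.tsv")),
               class = "flimrecon_data_error")
})

test_that("JSON sidecar metadata overrides header metadata", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# frame_index=1", "# units=ns", "0.0 1", "0.0005 2"), f)
  jsonlite::write_json(list(frame_index = 9, extra = "yes"),
                       sub("\\.tsv$", ".json", f), auto_unbox = TRUE)
  h <- read_decay(f)
  expect_equal(h$meta$frame_index, 9)
  expect_equal(h$meta$extra, "yes")
})

test_that("histogram constructor enforces the grid invariants", {
  expect_error(decay_histogram(numeric(0), numeric(0)),
               class = "flimrecon_data_error")
  expect_error(decay_histogram(c(0, 1e-3), c(1, 2, 3)),
               class = "flimrecon_data_error")
  expect_error(decay_histogram(c(0, 1e-3, 2e-3), c(1, -1, 3)),
               class = "flimrecon_data_error")
  expect_error(decay_histogram(c(0, 1e-3, 2.1e-3), c(1, 1, 1)),
               class = "flimrecon_data_error")
  expect_error(decay_histogram(c(0, 1e-3), c(1.5, 2), meta = list(raw = TRUE)),
               class = "flimrecon_data_error")
  h <- decay_histogram(c(0, 1e-3), c(1, 2), meta = list(raw = TRUE))
  expect_equal(h$window, 2e-3)
})

test_that("validate_grid accepts identical grids and rejects mismatches", {
  t1 <- seq(0, by = 5e-4, length.out = 4000)
  a <- decay_histogram(t1, rep(1, 4000))
  b <- instrument_response(t1, rep(1, 4000))
  expect_true(validate_grid(a, b))
  b2 <- instrument_response(seq(0, by = 5e-4, length.out = 3999),
                            rep(1, 3999))
  expect_error(validate_grid(a, b2), class = "flimrecon_grid_error")
  b3 <- instrument_response(seq(0, by = 5e-4 + 1e-6, length.out = 4000),
                            rep(1, 4000))
  expect_error(validate_grid(a, b3), class = "flimrecon_grid_error")
})

test_that("decay models sort components by ascending lifetime", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(1:3, 1)
    taus <- sort(runif(n, 1e-3, 0.5)) * sample(c(1), 1)
    perm <- sample(n)
    m <- decay_model(seq_len(n)[perm], taus[perm])
    expect_equal(m$lifetimes, taus)
    expect_equal(m$amplitudes[order(m$lifetimes)], m$amplitudes)
  }
  expect_error(decay_model(1:4, c(0.01, 0.02, 0.03, 0.04)),
               class = "flimrecon_param_error")
  expect_error(decay_model(-1, 0.05), class = "flimrecon_param_error")
  expect_error(decay_model(1, 0), class = "flimrecon_param_error")
})

test_that("frame series round-trips through both on-disk dialects", {
  cfg <- small_sim(seed = 11, budget = 1e4, n_frames = 3L,
                   channel_width = 1e-2)
  s <- simulate_series(cfg)
  d <- withr::local_tempdir()
  write_frame_series(s, d)
  expect_true(file.exists(file.path(d, "truth.json")))
  s2 <- read_frame_series(d)
  expect_equal(length(s2$frames), 3L)
  expect_identical(s2$frames[[2]]$counts, s$frames[[2]]$counts)
  expect_equal(s2$irf$counts, s$irf$counts, tolerance = 1e-12)

  # wide-table dialect: time column plus one column per frame
  wide <- withr::local_tempfile(fileext = ".tsv")
  mat <- cbind(s$frames[[1]]$time, sapply(s$frames, `[[`, "counts"))
  writeLines(apply(mat, 1, paste, collapse = "\t"), wide)
  s3 <- read_frame_series(wide, irf = s$irf)
  expect_equal(length(s3$frames), 3L)
  expect_identical(s3$frames[[3]]$counts, s$frames[[3]]$counts)
  expect_error(read_frame_series(wide), class = "flimrecon_data_error")
})

test_that("fit results serialize to the documented JSON layout", {
  cfg <- small_sim(seed = 5, budget = 5e4, channel_width = 4e-3)
  irf <- make_irf(cfg)
  fit <- flim_fit(simulate_decay(cfg), irf, fast_cfg(seed = 5))
  f <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, f)
  j <- jsonlite::read_json(f, simplifyVector = FALSE)
  expect_equal(length(j$model$components), 2L)
  expect_equal(j$model$components[[1]][[2]], fit$model$lifetimes[1])
  expect_equal(j$model$components[[2]][[1]], fit$model$amplitudes[2])
  expect_equal(j$irf_shift_ns, fit$irf_shift)
  expect_equal(j$reduced_chi2, fit$reduced_chi2)
  expect_equal(j$seed, fit$seed)
  expect_type(j$converged, "logical")
})
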