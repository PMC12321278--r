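# On-disk formats: two-column delimited text with '#' key=value header
# lines, optional JSON sidecar (sidecar wins), and frame-series
# directories or wide tables.  Times are converted to nanoseconds on
# read using the declared `units` key (ns assumed when absent).

.UNIT_SCALE <- c(ns = 1, ps = 1e-3, fs = 1e-6, us = 1e3)

.sidecar_path <- function(path) {
  if (grepl("\\.[^./\\\\]+$", path)) sub("\\.[^./\\\\]+$", ".json", path)
  else paste0(path, ".json")
}

.parse_meta_value <- function(v) {
  v <- trimws(v)
  if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  v
}

.read_table_with_meta <- function(path) {
  if (!file.exists(path))
    .data_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  data_rows <- list()
  widths <- integer(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      kv <- sub("^#+\\s*", "", ln)
      if (grepl("=", kv, fixed = TRUE)) {
        key <- trimws(sub("=.*$", "", kv))
        meta[[key]] <- .parse_meta_value(sub("^[^=]*=", "", kv))
      }
      next
    }
    fields <- strsplit(ln, "[,\t ]+")[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals)))
      .data_error(sprintf("%s:%d: malformed row '%s'", path, i, lines[[i]]))
    data_rows[[length(data_rows) + 1L]] <- vals
    widths <- c(widths, length(vals))
  }
  if (!length(data_rows))
    .data_error(sprintf("%s: no data rows", path))
  if (length(unique(widths)) != 1L)
    .data_error(sprintf("%s: rows have inconsistent numbers of columns", path))
  sc <- .sidecar_path(path)
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    for (k in names(side)) meta[[k]] <- side[[k]]  # sidecar wins
  }
  list(mat = do.call(rbind, data_rows), meta = meta)
}

.time_scale <- function(meta, path) {
  units <- if (is.null(meta$units)) "ns" else tolower(as.character(meta$units))
  if (!units %in% names(.UNIT_SCALE))
    .data_error(sprintf("%s: unknown time units '%s'", path, units))
  .UNIT_SCALE[[units]]
}

#' Read a decay histogram from delimited text
#'
#' Expects UTF-8 text with two numeric columns (time, counts) separated
#' by whitespace or commas, and `# key=value` header lines.  A JSON
#' sidecar `<name>.json` with the same keys overrides header values.
#' Times are converted to nanoseconds according to the `units` key
#' (`ns`, `ps`, `fs`; default `ns`).
#'
#' @param path Path to the file.
#' @return A validated [decay_histogram()].
#' @seealso [write_decay()] for the inverse; the pair round-trips to
#'   full precision.
#' @export
read_decay <- function(path) {
  tb <- .read_table_with_meta(path)
  if (ncol(tb$mat) < 2L)
    .data_error(sprintf("%s: expected two columns (time, counts)", path))
  scale <- .time_scale(tb$meta, path)
  tb$meta$units <- NULL
  tryCatch(
    decay_histogram(tb$mat[, 1L] * scale, tb$mat[, 2L], meta = tb$meta),
    flimrecon_error = function(e)
      .data_error(sprintf("%s: %s", path, conditionMessage(e))))
}

#' Read an instrument response function from delimited text
#'
#' Same format as [read_decay()].
#'
#' @inheritParams read_decay
#' @param normalize Normalize counts to unit sum on read.
#' @return An [instrument_response()].
#' @export
read_irf <- function(path, normalize = FALSE) {
  h <- read_decay(path)
  instrument_response(h$time, h$counts, meta = h$meta, normalize = normalize)
}

#' Write a decay histogram (or IRF) to delimited text
#'
#' Writes `# key=value` metadata (always including `units=ns`) followed
#' by one `time<TAB>counts` row per channel at full double precision,
#' so [read_decay()] recovers the object exactly.
#'
#' @param h A [decay_histogram()].
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_decay <- function(h, path) {
  stopifnot(inherits(h, "decay_histogram"))
  if (length(h$time) < 1L)
    .data_error("refusing to write a histogram with no channels")
  hdr <- c(sprintf("# flimrecon %s", as.character(utils::packageVersion("flimrecon"))),
           "# units=ns")
  for (k in names(h$meta)) {
    v <- h$meta[[k]]
    if (is.atomic(v) && length(v) == 1L)
      hdr <- c(hdr, sprintf("# %s=%s", k,
                            if (is.logical(v)) tolower(as.character(v))
                            else format(v, digits = 17)))
  }
  rows <- sprintf("%.17g\t%.17g", h$time, h$counts)
  ok <- suppressWarnings(tryCatch({ writeLines(c(hdr, rows), path); TRUE },
                                  error = function(e) FALSE))
  if (!ok)
    .data_error(sprintf("cannot write to %s", path))
  invisible(path)
}

#' Assemble an ordered series of per-frame decay histograms
#'
#' @param frames List of [decay_histogram()] objects, all on the IRF's
#'   time grid, ordered by acquisition frame.  Frames lacking a
#'   `meta$frame_index` are numbered by position.
#' @param irf The [instrument_response()] shared by all frames (one IRF
#'   per acquisition session).
#' @param interval Frame spacing label in minutes (default 1, matching
#'   one-minute acquisition cycles).
#' @return An object of class `frame_series` with elements `frames`,
#'   `irf`, `interval`.
#' @export
frame_series <- function(frames, irf, interval = 1) {
  stopifnot(is.list(frames), inherits(irf, "instrument_response"))
  if (!length(frames))
    .data_error("frame series must contain at least one frame")
  idx <- numeric(length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!inherits(f, "decay_histogram"))
      .data_error(sprintf("frame %d is not a decay_histogram", i))
    validate_grid(f, irf)
    idx[i] <- if (!is.null(f$meta$frame_index)) f$meta$frame_index else i
  }
  if (any(diff(idx) <= 0))
    .data_error("frame indices must be strictly increasing")
  structure(list(frames = frames, irf = irf, interval = interval,
                 frame_index = idx),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("TCSPC frame series: %d frames, %d channels, interval %g min\n",
              length(x$frames), length(x$irf$time), x$interval))
  invisible(x)
}

#' Read a frame series from disk
#'
#' Two dialects are accepted: a directory containing `frame_<index>.tsv`
#' files plus one `irf.tsv`, or a single wide table whose first column
#' is time and remaining columns are successive frames (the IRF must
#' then be supplied via `irf`).
#'
#' @param path Directory or wide-table file.
#' @param irf Optional [instrument_response()] (or path to one); required
#'   for the wide-table dialect, overrides `irf.tsv` for directories.
#' @param interval Frame spacing in minutes.
#' @return A [frame_series()].
#' @export
read_frame_series <- function(path, irf = NULL, interval = 1) {
  if (is.character(irf)) irf <- read_irf(irf)
  if (dir.exists(path)) {
    ff <- list.files(path, pattern = "^frame_[0-9]+\\.(tsv|txt|csv|dat)$",
                     full.names = TRUE)
    if (!length(ff))
      .data_error(sprintf("%s: no frame_<index> files found", path))
    idx <- as.integer(sub("^frame_([0-9]+)\\..*$", "\\1", basename(ff)))
    ff <- ff[order(idx)]
    idx <- sort(idx)
    frames <- lapply(seq_along(ff), function(i) {
      h <- read_decay(ff[[i]])
      h$meta$frame_index <- idx[i]
      h
    })
    if (is.null(irf)) {
      ip <- list.files(path, pattern = "^irf\\.(tsv|txt|csv|dat)$",
                       full.names = TRUE)
      if (!length(ip))
        .data_error(sprintf("%s: no irf file and none supplied", path))
      irf <- read_irf(ip[[1L]])
    }
    return(frame_series(frames, irf, interval = interval))
  }
  tb <- .read_table_with_meta(path)
  if (ncol(tb$mat) < 3L)
    .data_error(sprintf("%s: wide table needs a time column plus >= 2 frames",
                        path))
  if (is.null(irf))
    .data_error("wide-table frame series requires an explicit IRF")
  scale <- .time_scale(tb$meta, path)
  time <- tb$mat[, 1L] * scale
  frames <- lapply(seq_len(ncol(tb$mat) - 1L), function(j) {
    decay_histogram(time, tb$mat[, j + 1L], meta = list(frame_index = j))
  })
  frame_series(frames, irf, interval = interval)
}

#' Write a frame series as a directory of per-frame files
#'
#' Produces `frame_<index>.tsv` files, `irf.tsv`, and — when the series
#' carries simulation ground truth — a `truth.json` sidecar.
#'
#' @param s A [frame_series()].
#' @param dir Destination directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_frame_series <- function(s, dir) {
  stopifnot(inherits(s, "frame_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(s$frames))
    write_decay(s$frames[[i]],
                file.path(dir, sprintf("frame_%03d.tsv", s$frame_index[i])))
  write_decay(s$irf, file.path(dir, "irf.tsv"))
  if (!is.null(s$truth))
    jsonlite::write_json(s$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Serialize a fit result to JSON
#'
#' Fields: `model.components` as `[[A, tau], ...]`, `irf_shift_ns`,
#' `reduced_chi2`, `converged`, `seed`, plus package version.
#'
#' @param fit A `flim_fit` object.
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "flim_fit"))
  comp <- lapply(seq_along(fit$model$lifetimes), function(i)
    c(fit$model$amplitudes[i], fit$model$lifetimes[i]))
  obj <- list(
    model = list(components = comp, baseline = fit$model$baseline),
    irf_shift_ns = fit$irf_shift,
    reduced_chi2 = fit$reduced_chi2,
    converged = fit$converged,
    n_evaluations = fit$n_evaluations,
    seed = fit$seed,
    version = as.character(utils::packageVersion("flimrecon")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
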