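# S3 methods for flim_fit objects.

#' @export
print.flim_fit <- function(x, digits = 4, ...) {
  n <- length(x$model$lifetimes)
  cat(sprintf("Reconvolution fit (%d-exponential, DE + NNLS)\n", n))
  print(x$model, digits = digits)
  cat(sprintf("  IRF shift    = %+.*g ns\n", digits, x$irf_shift))
  cat(sprintf("  reduced chi2 = %.*g  (%s weights)\n",
              digits, x$reduced_chi2, x$config$weighting))
  cat(sprintf("  %s after %d generations, %d objective evaluations (seed %d)\n",
              if (x$converged) "converged" else "NOT converged",
              x$de_iterations, x$n_evaluations, x$seed))
  invisible(x)
}

#' @export
summary.flim_fit <- function(object, ...) {
  n <- length(object$model$lifetimes)
  amps <- object$model$amplitudes
  taus <- object$model$lifetimes
  # intensity fraction of each component: A_i tau_i / sum A tau
  f <- amps * taus
  f <- if (sum(f) > 0) f / sum(f) else rep(NA_real_, n)
  tab <- data.frame(component = seq_len(n),
                    tau_ns = taus,
                    amplitude = amps,
                    intensity_fraction = f)
  out <- list(components = tab,
              amp_ratio = if (n == 2L && amps[2L] > 0) amps[1L] / amps[2L]
                          else NA_real_,
              irf_shift = object$irf_shift,
              reduced_chi2 = object$reduced_chi2,
              converged = object$converged,
              n_channels = length(object$fitted),
              seed = object$seed)
  class(out) <- "summary.flim_fit"
  out
}

#' @export
print.summary.flim_fit <- function(x, digits = 4, ...) {
  cat("Reconvolution fit summary\n")
  print(x$components, digits = digits, row.names = FALSE)
  if (!is.na(x$amp_ratio))
    cat(sprintf("  amplitude ratio A1/A2 = %.*g\n", digits, x$amp_ratio))
  cat(sprintf("  IRF shift %+.*g ns; reduced chi2 %.*g over %d channels; %s\n",
              digits, x$irf_shift, digits, x$reduced_chi2, x$n_channels,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
coef.flim_fit <- function(object, ...) {
  n <- length(object$model$lifetimes)
  stats::setNames(c(object$model$lifetimes, object$model$amplitudes,
                    object$irf_shift),
                  c(paste0("tau", seq_len(n)), paste0("A", seq_len(n)),
                    "shift"))
}

#' Predict from a reconvolution fit
#'
#' @param object A `flim_fit`.
#' @param type `"signal"` for the IRF-convolved expected counts on the
#'   fitted grid, `"decay"` for the bare multi-exponential F(t).
#' @param ... Unused.
#' @return Numeric vector, one value per channel.
#' @export
predict.flim_fit <- function(object, type = c("signal", "decay"), ...) {
  type <- match.arg(type)
  if (type == "signal") object$fitted
  else evaluate_decay(object$model, object$data$time - object$data$time[1L])
}

#' @export
fitted.flim_fit <- function(object, ...) object$fitted

#' @export
residuals.flim_fit <- function(object, ...) object$residuals

#' Simulate TCSPC resamples from a fitted model
#'
#' Draws per-channel Poisson counts with the fitted curve as mean —
#' the parametric-bootstrap generator used by [estimate_uncertainty()].
#'
#' @param object A `flim_fit`.
#' @param nsim Number of resampled histograms.
#' @param seed Optional integer seed (defaults to the fit's own seed).
#' @param ... Unused.
#' @return A list of `nsim` [decay_histogram()] objects.
#' @export
simulate.flim_fit <- function(object, nsim = 1, seed = NULL, ...) {
  set.seed(if (is.null(seed)) object$seed else seed)
  lam <- pmax(object$fitted, 0)
  lapply(seq_len(nsim), function(i)
    decay_histogram(object$data$time, stats::rpois(length(lam), lam),
                    meta = list(raw = TRUE, simulated_from_fit = TRUE)))
}

#' Plot a reconvolution fit
#'
#' Upper panel: measured counts (log scale), fitted curve and scaled
#' IRF; lower panel: weighted residuals.
#'
#' @param x A `flim_fit`.
#' @param ... Passed to the upper `plot` call.
#' @export
plot.flim_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(0.5, 4, 2, 1), oma = c(4, 0, 0, 0))
  on.exit(graphics::par(op))
  t <- x$data$time
  y <- pmax(x$data$counts, 0.5)
  graphics::plot(t, y, log = "y", pch = ".", col = "grey40",
                 xlab = "", ylab = "counts", xaxt = "n",
                 main = "Reconvolution fit", ...)
  graphics::lines(t, pmax(x$fitted, 0.5), col = "blue", lwd = 1.5)
  irf_sc <- x$irf$counts / max(x$irf$counts) * max(y)
  graphics::lines(t, pmax(irf_sc, 0.5), col = "darkgreen", lty = 2)
  graphics::legend("topright", c("data", "fit", "IRF (scaled)"),
                   col = c("grey40", "blue", "darkgreen"),
                   lty = c(NA, 1, 2), pch = c(20, NA, NA), bty = "n")
  w <- .fit_weights(x$data, x$config$weighting)
  graphics::par(mar = c(4, 4, 0.5, 1))
  graphics::plot(t, x$residuals * sqrt(w), type = "h", col = "grey40",
                 xlab = "time (ns)", ylab = "weighted residual")
  graphics::abline(h = 0, col = "red")
  invisible(x)
}
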