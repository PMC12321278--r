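# Non-negative least squares for the amplitude subproblem.  With at
# most 3 (plus baseline) columns the convex QP is solved exactly by
# enumerating active subsets: the unconstrained solution restricted to
# each feasible support is computed from the normal equations and the
# minimum-SSE feasible candidate is the global optimum.

# G = B' W B, b = B' W y, yty = y' W y; returns list(coef, sse)
.nnls_small <- function(G, b, yty) {
  n <- length(b)
  best_a <- rep(0, n)
  best_sse <- yty                       # empty support: all amplitudes 0
  for (mask in seq_len(2L^n - 1L)) {
    P <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    aP <- tryCatch(solve(G[P, P, drop = FALSE], b[P]),
                   error = function(e) NULL)
    if (is.null(aP) || any(!is.finite(aP)) || any(aP < -1e-12)) next
    aP[aP < 0] <- 0
    sse <- yty - 2 * sum(aP * b[P]) +
      sum(aP * (G[P, P, drop = FALSE] %*% aP))
    if (sse < best_sse - 1e-15 * max(1, abs(best_sse))) {
      best_sse <- sse
      best_a <- rep(0, n)
      best_a[P] <- aP
    }
  }
  list(coef = best_a, sse = max(best_sse, 0))
}

#' Solve decay amplitudes by non-negative least squares
#'
#' For fixed trial lifetimes and IRF shift, builds the unit-amplitude
#' convolved basis B_j(t) for each lifetime tau_j and solves
#' min_A sum_i w_i (S_obs(t_i) - sum_j A_j B_j(t_i))^2 subject to
#' A_j >= 0.  This is the linear half of the variable-projection
#' objective used inside the global fit.
#'
#' @param taus Positive lifetimes in nanoseconds, pairwise distinct by
#'   more than 1e-6 ns.
#' @param dt IRF shift in nanoseconds.
#' @param h Observed [decay_histogram()].
#' @param r [instrument_response()] on the same grid.
#' @param weighting `"poisson"` (weights 1/max(raw counts, 1); raw
#'   pre-smoothing counts are taken from `h$meta$raw_counts` when
#'   present) or `"uniform"`.
#' @return A list with `amplitudes` (non-negative, one per lifetime)
#'   and `sse` (the weighted sum of squared residuals at the optimum).
#' @export
solve_amplitudes <- function(taus, dt, h, r,
                             weighting = c("poisson", "uniform")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(h, "decay_histogram"), inherits(r, "instrument_response"))
  validate_grid(h, r)
  taus <- as.numeric(taus)
  if (any(taus <= 0))
    .param_error("lifetimes must be positive")
  if (length(taus) > 1L && min(dist(taus)) <= 1e-6)
    .data_error("degenerate basis: two lifetimes within 1e-6 ns",
                class = "flimrecon_degeneracy_error")
  w <- .fit_weights(h, weighting)
  rs <- if (dt != 0) shift_irf(r, dt) else r
  rc <- rs$counts / sum(rs$counts)
  B <- vapply(taus, function(tau) .conv_exp(rc, tau, r$channel_width),
              numeric(length(rc)))
  sol <- .nnls_small(crossprod(B, w * B), crossprod(B, w * h$counts)[, 1L],
                     sum(w * h$counts^2))
  list(amplitudes = sol$coef, sse = sol$sse)
}

.fit_weights <- function(h, weighting) {
  if (weighting == "poisson") {
    raw <- if (!is.null(h$meta$raw_counts)) h$meta$raw_counts else h$counts
    1 / pmax(raw, 1)
  } else {
    rep(1, length(h$counts))
  }
}
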