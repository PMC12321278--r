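# Differential Evolution (rand-to-best/1/bin) over a box.
# Population-based stochastic global optimizer; mutation factor
# dithered in [0.5, 1) per generation, crossover rate 0.9.  The
# rand-to-best mutant x_i + F (best - x_i) + F (x_r1 - x_r2) trades
# some of best/1's greed for the diversity needed when several
# lifetime basins compete; out-of-bounds components are resampled
# uniformly inside the box rather than clipped, so the population
# never piles up on a bound.  Convergence when the population's
# objective spread falls below tol * |mean objective|.  Uses R's RNG;
# callers seed it.

.de_optimize <- function(fn, lower, upper, popsize = 30L, maxiter = 300L,
                         tol = 1e-8, cr = 0.9) {
  d <- length(lower)
  popsize <- max(as.integer(popsize), 4L)
  pop <- matrix(stats::runif(popsize * d, rep(lower, each = popsize),
                             rep(upper, each = popsize)),
                nrow = popsize)
  fvals <- apply(pop, 1L, fn)
  nfev <- popsize
  converged <- FALSE
  iters <- 0L
  for (gen in seq_len(maxiter)) {
    iters <- gen
    Fmut <- stats::runif(1L, 0.5, 1.0)
    best <- pop[which.min(fvals), ]
    for (i in seq_len(popsize)) {
      rr <- sample.int(popsize, 3L)        # cheap draw; ensure distinct from i
      rr <- rr[rr != i][1:2]
      if (anyNA(rr)) next
      mutant <- pop[i, ] + Fmut * (best - pop[i, ]) +
        Fmut * (pop[rr[1L], ] - pop[rr[2L], ])
      cross <- stats::runif(d) < cr
      cross[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      oob <- trial < lower | trial > upper
      if (any(oob))
        trial[oob] <- lower[oob] +
          stats::runif(sum(oob)) * (upper[oob] - lower[oob])
      ft <- fn(trial)
      nfev <- nfev + 1L
      if (ft <= fvals[i]) {
        pop[i, ] <- trial
        fvals[i] <- ft
      }
    }
    fin <- fvals[is.finite(fvals) & fvals < 1e29]
    if (length(fin) == popsize &&
        stats::sd(fvals) <= tol * abs(mean(fvals))) {
      converged <- TRUE
      break
    }
  }
  ib <- which.min(fvals)
  list(par = pop[ib, ], value = fvals[ib], nfev = nfev,
       converged = converged, iterations = iters)
}
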