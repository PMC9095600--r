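# Bounded derivative-free local search.
#
# A Nelder-Mead subspace/simplex search in the spirit of Subplex: the
# parameters are mapped to an unconstrained scale through a logistic
# transform of their box bounds, stats::optim's simplex search runs on that
# scale, and the search is restarted from its own optimum (a fresh simplex)
# until the objective stops improving or the restart budget is exhausted.
# Deterministic: no random restarts.

to_unit <- function(x, lo, hi) {
  z <- (x - lo) / (hi - lo)
  z <- pmin(pmax(z, 1e-6), 1 - 1e-6)
  stats::qlogis(z)
}

from_unit <- function(z, lo, hi) lo + (hi - lo) * stats::plogis(z)

#' Bounded derivative-free minimization
#'
#' Minimizes `fn` inside box bounds by a logistic-transformed Nelder-Mead
#' simplex search with deterministic refinement restarts. Used for every
#' calibration and assimilation fit in the package.
#'
#' @param par Start vector (inside the bounds).
#' @param fn Objective function of the parameter vector, to minimize.
#' @param lower,upper Bound vectors; a coordinate with `lower == upper` is
#'   held fixed.
#' @param maxeval Total evaluation budget across restarts.
#' @param restarts Maximum refinement restarts after the first search.
#' @param reltol Relative convergence tolerance of each simplex run.
#' @return List with `par`, `value`, `counts` (objective evaluations) and
#'   `convergence` (0 if any simplex run converged).
#' @export
bounded_minimize <- function(par, fn, lower, upper, maxeval = 1000,
                             restarts = 2, reltol = 1e-8) {
  stopifnot(length(par) == length(lower), length(par) == length(upper))
  fixed <- upper <= lower
  if (all(fixed))
    return(list(par = par, value = fn(par), counts = 1, convergence = 0))
  lo <- lower[!fixed]; hi <- upper[!fixed]
  full <- function(zf) {
    x <- par
    x[!fixed] <- from_unit(zf, lo, hi)
    fn(x)
  }
  z <- to_unit(pmin(pmax(par[!fixed], lo), hi), lo, hi)
  total <- 0
  best <- NULL
  for (k in seq_len(restarts + 1)) {
    left <- maxeval - total
    if (left < 10) break
    o <- if (length(z) == 1) {
      stats::optim(z, full, method = "Brent", lower = -12, upper = 12,
                   control = list(maxit = min(left, 500)))
    } else {
      stats::optim(z, full, method = "Nelder-Mead",
                   control = list(maxit = left, reltol = reltol,
                                  parscale = rep(2.5, length(z))))
    }
    total <- total + o$counts[["function"]]
    if (is.null(best) || o$value < best$value - 1e-12) {
      improved <- is.null(best) || best$value - o$value > abs(best$value) * 1e-6
      best <- o
      z <- o$par
      if (!improved) break
    } else break
  }
  x <- par
  x[!fixed] <- from_unit(best$par, lo, hi)
  list(par = x, value = best$value, counts = total,
       convergence = best$convergence)
}
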