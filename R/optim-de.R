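#' Differential evolution global optimizer
#'
#' Classic DE/rand/1/bin (population-based stochastic search) for bound-
#' constrained minimization, used for the global fit of the stock-and-flow
#' model where the loss surface is multimodal. Mutation builds a trial vector
#' from three distinct population members, `x_r1 + F (x_r2 - x_r3)`, binomial
#' crossover mixes it with the target at rate `CR`, and greedy selection
#' keeps the better of target and trial. Out-of-bounds trial components are
#' reflected back into the box. Fully reproducible for a given `seed`.
#'
#' @param fn Objective function taking a numeric parameter vector.
#' @param lower,upper Numeric bound vectors of equal length (>= 1).
#' @param seed Integer seed for the optimizer's RNG stream.
#' @param np Population size (default `15 * length(lower)`, min 8).
#' @param maxiter Maximum number of generations (default 1000).
#' @param F Differential weight in (0, 2] (default 0.8).
#' @param CR Crossover probability in [0, 1] (default 0.9).
#' @param tol Early-stop tolerance: stop when the population loss spread
#'   satisfies `max - min <= tol * (abs(min) + tol)` (default 1e-10).
#' @return A list with `par`, `value`, `trace` (best loss per generation),
#'   `iterations`, and `converged` (TRUE if the spread criterion was met
#'   before `maxiter`).
#' @examples
#' sphere <- function(x) sum(x^2)
#' differential_evolution(sphere, c(-5, -5), c(5, 5), seed = 1,
#'                        maxiter = 200)$value
#' @export
differential_evolution <- function(fn, lower, upper, seed,
                                   np = max(8L, 15L * length(lower)),
                                   maxiter = 1000L, F = 0.8, CR = 0.9,
                                   tol = 1e-10) {
  d <- length(lower)
  stopifnot(length(upper) == d, d >= 1L, all(is.finite(lower)),
            all(is.finite(upper)), all(upper > lower),
            is.numeric(seed), length(seed) == 1L)
  np <- as.integer(np)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  pop <- matrix(stats::runif(np * d, rep(lower, each = np),
                             rep(upper, each = np)), nrow = np)
  loss <- apply(pop, 1L, fn)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxiter)) {
    for (i in seq_len(np)) {
      r <- sample(seq_len(np)[-i], 3L)
      trial <- pop[r[1L], ] + F * (pop[r[2L], ] - pop[r[3L], ])
      # reflect out-of-bounds components back into the box
      lo_bad <- trial < lower
      trial[lo_bad] <- pmin(upper[lo_bad],
                            2 * lower[lo_bad] - trial[lo_bad])
      hi_bad <- trial > upper
      trial[hi_bad] <- pmax(lower[hi_bad],
                            2 * upper[hi_bad] - trial[hi_bad])
      cross <- stats::runif(d) < CR
      cross[sample.int(d, 1L)] <- TRUE  # at least one mutated component
      trial[!cross] <- pop[i, !cross]
      f_trial <- fn(trial)
      if (is.finite(f_trial) && f_trial <= loss[i]) {
        pop[i, ] <- trial
        loss[i] <- f_trial
      }
    }
    trace <- c(trace, min(loss))
    spread <- max(loss) - min(loss)
    if (is.finite(spread) && spread <= tol * (abs(min(loss)) + tol)) {
      converged <- TRUE
      break
    }
  }
  best <- which.min(loss)
  list(par = pop[best, ], value = loss[best], trace = trace,
       iterations = iter, converged = converged)
}
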