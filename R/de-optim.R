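# Compact differential-evolution optimizer (DE/rand/1/bin) used for the
# segment-wise least-squares fits. Deterministic under a fixed seed; keeps
# the best member ever seen, so the returned objective can never exceed the
# best of the initial population.

#' Fit configuration for the evolutionary least-squares optimizer
#'
#' @param pop_size population size.
#' @param generations maximal number of generations.
#' @param f differential weight.
#' @param cr crossover probability.
#' @param seed RNG seed used for every stochastic fitting step.
#' @param tol convergence tolerance: the search stops early once the spread
#'   of objective values across the population falls below `tol` (absolute).
#' @param rate_upper upper bound (1/min) for rate constants.
#' @param act_max_factor upper bound for `act_max` as a multiple of the
#'   observed actin peak.
#' @param ss_window number of trailing samples averaged for the steady-state
#'   actin level.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(pop_size = 30, generations = 300, f = 0.8, cr = 0.9,
                       seed = 42, tol = 1e-10, rate_upper = 50,
                       act_max_factor = 5, ss_window = 3) {
  stopifnot(pop_size >= 4, generations >= 1, f > 0, cr >= 0, cr <= 1,
            tol >= 0, rate_upper > 0, act_max_factor > 1, ss_window >= 1)
  structure(list(pop_size = pop_size, generations = generations, f = f,
                 cr = cr, seed = as.integer(seed), tol = tol,
                 rate_upper = rate_upper, act_max_factor = act_max_factor,
                 ss_window = ss_window),
            class = "fit_config")
}

#' Minimize an objective by differential evolution
#'
#' Classic DE/rand/1/bin with reflection at the box bounds. Runs inside a
#' private RNG scope so fitting does not disturb the caller's random stream.
#'
#' @param fn objective, called with a numeric vector of length
#'   `length(lower)`; must return a finite scalar (or `Inf`).
#' @param lower,upper box constraints.
#' @param config a [fit_config()].
#' @return List with `par`, `value`, `initial_best` (best objective in the
#'   starting population) and `generations_used`.
#' @export
de_optimize <- function(fn, lower, upper, config = fit_config()) {
  stopifnot(length(lower) == length(upper), all(upper > lower))
  d <- length(lower)
  np <- config$pop_size
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  pop <- matrix(stats::runif(np * d, rep(lower, each = np),
                             rep(upper, each = np)), nrow = np)
  score <- apply(pop, 1, fn)
  score[!is.finite(score)] <- Inf
  initial_best <- min(score)
  gens <- config$generations
  used <- gens
  for (g in seq_len(gens)) {
    for (i in seq_len(np)) {
      idx <- sample.int(np, 3)
      while (any(idx == i)) idx <- sample.int(np, 3)
      trial <- pop[idx[1], ] + config$f * (pop[idx[2], ] - pop[idx[3], ])
      # reflect out-of-bounds coordinates back into the box
      below <- trial < lower
      trial[below] <- pmin(upper[below],
                           2 * lower[below] - trial[below])
      above <- trial > upper
      trial[above] <- pmax(lower[above],
                           2 * upper[above] - trial[above])
      cross <- stats::runif(d) < config$cr
      cross[sample.int(d, 1)] <- TRUE
      cand <- ifelse(cross, trial, pop[i, ])
      s <- fn(cand)
      if (!is.finite(s)) s <- Inf
      if (s <= score[i]) {
        pop[i, ] <- cand
        score[i] <- s
      }
    }
    if (max(score) - min(score) < config$tol) {
      used <- g
      break
    }
  }
  best <- which.min(score)
  list(par = pop[best, ], value = score[best], initial_best = initial_best,
       generations_used = used)
}
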