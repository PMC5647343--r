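#' Monte-Carlo simulation of the origin-fixation chain
#'
#' Samples a trajectory of the monomorphic origin-fixation chain by
#' categorical sampling of the rows of a per-generation transition matrix.
#' Serves as an independent stochastic check of the analytic stationary
#' distribution: long-run occupancy fractions converge to the eigenvector
#' solution.
#'
#' @param tm A `transition_matrix` (or bare row-stochastic matrix).
#' @param steps Number of generations to simulate.
#' @param burn_in Number of initial generations excluded from the occupancy
#'   counts (default 1 percent of `steps`).
#' @param seed RNG seed; one stream per trajectory, seeded explicitly.
#' @param init Initial state index (default 1, the wild type).
#' @return An object of class `chain_trajectory`: `states` (visited state
#'   per generation), `occupancy` (time-in-state counts after burn-in,
#'   summing to `steps - burn_in`), `freq` (occupancy fractions), `seed`,
#'   `burn_in`.
#' @export
simulate_origin_fixation <- function(tm, steps, burn_in = floor(steps / 100),
                                     seed = 1L, init = 1L) {
  T <- if (inherits(tm, "transition_matrix")) tm$T else as.matrix(tm)
  if (any(T < 0) || any(abs(rowSums(T) - 1) > 1e-9))
    stop("matrix is not row-stochastic")
  steps <- as.integer(steps)
  burn_in <- as.integer(burn_in)
  if (!(steps > burn_in && burn_in >= 0))
    stop("'steps' must exceed 'burn_in' and 'burn_in' must be non-negative")
  res <- with_seed(seed, .cpp_chain_sample(T, steps, burn_in, as.integer(init)))
  occ <- res$occupancy
  names(occ) <- rownames(T)
  structure(list(states = res$states, occupancy = occ,
                 freq = occ / (steps - burn_in),
                 steps = steps, burn_in = burn_in, seed = seed),
            class = "chain_trajectory")
}

#' @export
print.chain_trajectory <- function(x, ...) {
  cat(sprintf("Origin-fixation trajectory: %d steps (burn-in %d), seed %d\n",
              x$steps, x$burn_in, x$seed))
  print(signif(x$freq, 4))
  invisible(x)
}

#' Goodness of fit of a trajectory's occupancy against a target distribution
#'
#' Chi-squared test of the empirical state distribution against the
#' analytic stationary distribution. Consecutive states of the chain are
#' autocorrelated (the chain rarely jumps), so the raw time-in-state
#' counts would overdisperse a chi-squared statistic; the test therefore
#' thins the trajectory to every `thin`-th state after burn-in, which for
#' thinning intervals well above the chain's relaxation time yields
#' near-independent draws and a calibrated test.
#'
#' @param trajectory A `chain_trajectory` from [simulate_origin_fixation()].
#' @param x_star Target probability vector (e.g. from
#'   [stationary_distribution()]).
#' @param thin Thinning interval in generations (default 1000).
#' @return A list with the thinned `counts`, `statistic`, `df`, `p_value`.
#' @export
occupancy_gof <- function(trajectory, x_star, thin = 1000L) {
  stopifnot(inherits(trajectory, "chain_trajectory"))
  if (inherits(x_star, "stationary_result")) x_star <- x_star$x_star
  idx <- seq(trajectory$burn_in + 1L, trajectory$steps, by = thin)
  s <- trajectory$states[idx]
  counts <- tabulate(s, nbins = length(x_star))
  ht <- suppressWarnings(stats::chisq.test(counts, p = x_star))
  list(counts = counts, statistic = unname(ht$statistic),
       df = unname(ht$parameter), p_value = ht$p.value)
}

# Evaluate `expr` under a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
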