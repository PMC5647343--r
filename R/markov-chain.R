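#' Edge mutation rates from the exponential beneficial-effect distribution
#'
#' Beneficial ("uphill") edges receive `p_b(x) = u_b * mu * rho(x)` with
#' `rho(x) = exp(-x / s_bar) / s_bar`: each of the `n` drift-fragile steps
#' gets `p_b(s/n)` and the single drift-robust step gets `p_b(s)` (or
#' `p_b(s - epsilon)` when `use_epsilon_in_u14 = TRUE`). Deleterious/back
#' edges receive the overall mutation rate `mu`. The flux ratio
#' `M = (u_fragile/mu)^n * (mu/u_robust)` then equals `kappa^{n-1}` exactly
#' under the default, because `mu` cancels.
#'
#' @param spec A [markov_landscape_spec()].
#' @return An object of class `edge_rates`: a list with `u_fragile`,
#'   `u_robust`, `u_down`, the flux ratio `M` and `kappa`.
#' @export
dfe_mutation_rates <- function(spec) {
  stopifnot(inherits(spec, "markov_landscape_spec"))
  if (spec$kappa >= 1)
    stop("model assumption violated: kappa must be < 1 for a peak crossing to exist")
  p_b <- function(x) spec$u_b * spec$mu * exp(-x / spec$s_bar) / spec$s_bar
  u_fragile <- p_b(spec$s / spec$n)
  u_robust <- p_b(if (spec$use_epsilon_in_u14) spec$s - spec$epsilon else spec$s)
  edge_rates(u_fragile, u_robust, spec$mu, n = spec$n, kappa = spec$kappa)
}

#' Assemble edge rates directly
#'
#' Low-level constructor used by [dfe_mutation_rates()]; also useful for
#' degenerate or hand-chosen rate sets (e.g. all rates equal, for which the
#' flux ratio `M` is 1).
#'
#' @param u_fragile Beneficial rate of each drift-fragile step.
#' @param u_robust Beneficial rate of the drift-robust step.
#' @param u_down Deleterious/back-mutation rate of every downhill edge.
#' @param n Number of drift-fragile steps.
#' @param kappa Optional `u_b/s_bar` ratio to record alongside the rates.
#' @return An `edge_rates` object.
#' @export
edge_rates <- function(u_fragile, u_robust, u_down, n = 2L, kappa = NULL) {
  stopifnot(u_fragile > 0, u_robust > 0, u_down > 0)
  M <- (u_fragile / u_down)^n * (u_down / u_robust)
  structure(list(u_fragile = u_fragile, u_robust = u_robust, u_down = u_down,
                 n = as.integer(n), M = M, kappa = kappa),
            class = "edge_rates")
}

#' Per-generation transition matrix of the origin-fixation chain
#'
#' Builds the row-stochastic transition matrix of the two-peak
#' origin-fixation Markov chain: off-diagonal entry `i -> j` is
#' `u_ij * pi_ij` for every mutational edge, the diagonal is the
#' complement, and entries are zero where no single-mutation edge exists
#' (the fragile and robust branches are only connected through the wild
#' type). Edge selection coefficients are the landscape's additive fitness
#' increments (`s/n` per fragile step, `s - epsilon` for the robust step),
#' the convention under which the chain's detailed-balance factors are
#' `e^{2 delta (N-1)}` per edge; for the exact Sella-Hirsh kernel the
#' increments are mapped to Wrightian ratios via `r = e^{delta}` so that
#' both kernels satisfy the same detailed balance (see the package
#' vignette).
#'
#' @param spec A [markov_landscape_spec()].
#' @param model A [fixation_model()].
#' @param rates Optional `edge_rates` override; defaults to
#'   [dfe_mutation_rates()] applied to `spec`.
#' @return An object of class `transition_matrix`: list with the matrix
#'   `T`, `states`, `spec`, `model`, `rates`.
#' @export
build_transition_matrix <- function(spec, model, rates = dfe_mutation_rates(spec)) {
  stopifnot(inherits(spec, "markov_landscape_spec"), inherits(model, "fixation_model"),
            inherits(rates, "edge_rates"))
  k <- spec$n + 2L
  step <- spec$s / spec$n
  # map additive increments to kernel arguments (Wrightian ratio e^delta for
  # the exact kernel, increment itself for the diffusion kernel)
  arg <- if (model$kind == "sella_hirsh") function(d) expm1(d) else function(d) d
  T <- matrix(0, k, k, dimnames = list(spec$states, spec$states))
  put <- function(i, j, u, delta) {
    T[i, j] <<- u * fixation_probability(arg(delta), model)
  }
  for (kk in seq_len(spec$n)) {           # fragile ladder: 1 <-> 2 <-> ... <-> n+1
    put(kk, kk + 1L, rates$u_fragile, step)
    put(kk + 1L, kk, rates$u_down, -step)
  }
  put(1L, spec$i_robust, rates$u_robust, spec$s - spec$epsilon)
  put(spec$i_robust, 1L, rates$u_down, -(spec$s - spec$epsilon))
  off <- rowSums(T)
  if (any(off > 1))
    stop("mutation rates too large for a per-generation chain (row sum > 1)")
  diag(T) <- 1 - off
  structure(list(T = T, states = spec$states, spec = spec, model = model,
                 rates = rates),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("Origin-fixation transition matrix (%d states, %s kernel, N = %g)\n",
              nrow(x$T), x$model$kind, x$model$N))
  print(signif(x$T, 4))
  invisible(x)
}

#' Stationary distribution of a finite Markov chain
#'
#' The stationary distribution is the left eigenvector of the transition
#' matrix with eigenvalue 1. It is computed by direct state reduction
#' (the Grassmann-Taksar-Heyman elimination): a deterministic,
#' subtraction-free solve of `x (T - I) = 0` that retains componentwise
#' relative accuracy even when stationary masses span many orders of
#' magnitude, as they do near strong selection. The chain must be
#' irreducible.
#'
#' @param tm A `transition_matrix`, or a bare row-stochastic matrix.
#' @return An object of class `stationary_result` with the probability
#'   vector `x_star` and the stationarity residual.
#' @export
stationary_distribution <- function(tm) {
  T <- if (inherits(tm, "transition_matrix")) tm$T else as.matrix(tm)
  k <- nrow(T)
  if (ncol(T) != k) stop("transition matrix must be square")
  if (any(T < 0) || any(abs(rowSums(T) - 1) > 1e-9))
    stop("matrix is not row-stochastic")
  if (!is_irreducible(T))
    stop("chain is reducible: no unique stationary distribution")
  P <- T
  if (k > 1) {
    for (n in k:2) {
      below <- seq_len(n - 1)
      S <- sum(P[n, below])
      P[below, n] <- P[below, n] / S
      P[below, below] <- P[below, below] + P[below, n] %o% P[n, below]
    }
    x <- numeric(k)
    x[1] <- 1
    for (n in 2:k) x[n] <- sum(x[seq_len(n - 1)] * P[seq_len(n - 1), n])
  } else {
    x <- 1
  }
  x <- x / sum(x)
  resid <- max(abs(drop(x %*% T) - x))
  if (any(x < 0) || any(!is.finite(x)) || resid > 1e-10)
    stop("failed to compute stationary distribution to tolerance")
  names(x) <- rownames(T)
  structure(list(x_star = x, residual = resid), class = "stationary_result")
}

is_irreducible <- function(T) {
  k <- nrow(T)
  B <- (T > 0) | diag(k) > 0
  R <- B
  for (i in seq_len(k)) R <- R | ((R %*% B) > 0)
  all(R)
}

#' @export
print.stationary_result <- function(x, ...) {
  cat("Stationary distribution (residual ", format(x$residual, digits = 3), ")\n", sep = "")
  print(signif(x$x_star, 5))
  invisible(x)
}

#' Occupancy ratio of the drift-fragile over the drift-robust peak
#'
#' `R = x*_fragile_top / x*_robust`, the stationary occupancy of the top of
#' the drift-fragile peak relative to the drift-robust peak. Under the
#' default rates this equals `M e^{2 epsilon (N-1)}` so that `R = 1` at the
#' closed-form critical population size.
#'
#' @param result A `stationary_result` (or bare probability vector).
#' @param spec The [markov_landscape_spec()] identifying the two peak states.
#' @return The scalar ratio `R`.
#' @export
occupancy_ratio <- function(result, spec) {
  x <- if (inherits(result, "stationary_result")) result$x_star else result
  stopifnot(inherits(spec, "markov_landscape_spec"))
  if (x[spec$i_robust] == 0)
    stop("degenerate landscape: drift-robust peak has zero stationary mass")
  unname(x[spec$i_fragile_top] / x[spec$i_robust])
}

#' Solve the origin-fixation model at one population size
#'
#' Convenience wrapper: builds the transition matrix, solves the stationary
#' distribution and assembles the quantities of interest.
#'
#' @inheritParams build_transition_matrix
#' @return A list with `x_star`, `R`, `M`, and the inputs.
#' @export
solve_markov <- function(spec, model, rates = dfe_mutation_rates(spec)) {
  tm <- build_transition_matrix(spec, model, rates)
  st <- stationary_distribution(tm)
  list(x_star = st$x_star, residual = st$residual,
       R = occupancy_ratio(st, spec), M = rates$M,
       spec = spec, model = model, rates = rates)
}
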