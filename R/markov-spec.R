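#' Two-peak landscape specification for the origin-fixation model
#'
#' Defines the genotype network used throughout the origin-fixation theory:
#' a wild type at fitness 1, a drift-fragile peak reached through `n` equal
#' beneficial steps of size `s/n` (step `k` has fitness `1 + k s/n`), and a
#' drift-robust peak at fitness `1 + s - epsilon` reached in a single step.
#' Beneficial mutation rates follow an exponential distribution of effects,
#' `p_b(x) = u_b * mu * rho(x)` with `rho(x) = exp(-x/s_bar)/s_bar`.
#'
#' @param s Selection coefficient of the drift-fragile peak (total height
#'   above the wild type); must be positive.
#' @param epsilon Fitness deficit of the drift-robust peak relative to the
#'   drift-fragile peak; `0 < epsilon < s`.
#' @param n Number of beneficial steps to the top of the drift-fragile peak
#'   (integer, at least 2; the minimal four-genotype model has `n = 2`).
#' @param u_b Likelihood that a mutation is beneficial.
#' @param s_bar Mean effect of the exponential beneficial-effect
#'   distribution. The ratio `kappa = u_b / s_bar` must be below 1.
#' @param mu Overall (deleterious/back) mutation rate per genotype per
#'   generation.
#' @param use_epsilon_in_u14 If `TRUE`, the beneficial rate toward the
#'   drift-robust peak is `p_b(s - epsilon)`; the default `FALSE` uses the
#'   small-`epsilon` approximation `p_b(s)`, under which the closed-form
#'   critical population size is exact.
#' @return An object of class `markov_landscape_spec` with the fitness
#'   vector (`fitness`), state labels, and the indices of the fragile-top
#'   and robust states.
#' @seealso [dfe_mutation_rates()], [build_transition_matrix()],
#'   [n_crit_closed()], [n_crit_numeric()]
#' @export
markov_landscape_spec <- function(s, epsilon, n = 2L, u_b = 1e-3, s_bar = 0.1,
                                  mu = 0.01, use_epsilon_in_u14 = FALSE) {
  stopifnot(is.numeric(s), length(s) == 1L, is.numeric(epsilon), length(epsilon) == 1L)
  if (s <= 0 || epsilon <= 0 || u_b <= 0 || s_bar <= 0 || mu <= 0)
    stop("all rates and effects must be strictly positive")
  if (epsilon >= s) stop("'epsilon' must be smaller than 's'")
  n <- as.integer(n)
  if (n < 2L) stop("'n' must be an integer >= 2")
  kappa <- u_b / s_bar
  if (kappa >= 1)
    stop("model assumption violated: kappa = u_b/s_bar must be < 1")
  fitness <- c(1, 1 + seq_len(n) * s / n, 1 + s - epsilon)
  states <- c("wild", paste0("fragile_", seq_len(n)), "robust")
  structure(
    list(s = s, epsilon = epsilon, n = n, u_b = u_b, s_bar = s_bar, mu = mu,
         use_epsilon_in_u14 = isTRUE(use_epsilon_in_u14),
         kappa = kappa, fitness = fitness, states = states,
         i_wild = 1L, i_fragile_top = n + 1L, i_robust = n + 2L),
    class = "markov_landscape_spec")
}

#' @export
print.markov_landscape_spec <- function(x, ...) {
  cat("Two-peak origin-fixation landscape\n")
  cat(sprintf("  s = %g, epsilon = %g, n = %d (states: %d)\n",
              x$s, x$epsilon, x$n, length(x$states)))
  cat(sprintf("  u_b = %g, s_bar = %g, mu = %g  (kappa = %g)\n",
              x$u_b, x$s_bar, x$mu, x$kappa))
  cat("  fitness:", paste(sprintf("%s=%g", x$states, x$fitness), collapse = ", "), "\n")
  invisible(x)
}

#' Fixation model (kernel and population size)
#'
#' @param kind `"kimura"` for the diffusion approximation
#'   `(1 - e^{-2s}) / (1 - e^{-2Ns})`, or `"sella_hirsh"` for the exact
#'   Wright-Fisher form `(1 - r^{-2}) / (1 - r^{-2N})` in terms of the
#'   Wrightian fitness ratio `r = 1 + s_eff`, pinned by the detailed-balance
#'   property `pi_ij / pi_ji = (w_j/w_i)^{2(N-1)}`.
#' @param N Population size; real values `>= 1` are allowed (the analytic
#'   theory is continuous in `N`).
#' @return An object of class `fixation_model`.
#' @export
fixation_model <- function(kind = c("kimura", "sella_hirsh"), N) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(N), length(N) == 1L)
  if (N < 1) stop("'N' must be at least 1")
  structure(list(kind = kind, N = N), class = "fixation_model")
}

#' @export
print.fixation_model <- function(x, ...) {
  cat(sprintf("Fixation model: %s, N = %g\n", x$kind, x$N))
  invisible(x)
}
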