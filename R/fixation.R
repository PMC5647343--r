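#' Probability of fixation of a new mutant
#'
#' Probability that a single new mutant with selection coefficient `s_eff`
#' relative to the resident genotype replaces a haploid asexual
#' Wright-Fisher population of size `N`. Two kernels are available:
#' Kimura's diffusion approximation, `(1 - e^{-2 s}) / (1 - e^{-2 N s})`,
#' and the exact Sella-Hirsh Wright-Fisher form expressed in the Wrightian
#' fitness ratio `r = 1 + s_eff`, `(1 - r^{-2}) / (1 - r^{-2N})`. Both are
#' continuous at `s_eff = 0` with the neutral limit `1/N`, handled
#' analytically below `|s_eff| < 1e-12`.
#'
#' @param s_eff Selection coefficient(s) of the mutant relative to the
#'   resident; must exceed -1 (a mutant at `s_eff <= -1` is non-viable and
#'   outside the model).
#' @param model A [fixation_model()].
#' @return Fixation probabilities in `(0, 1]`, same length as `s_eff`.
#' @examples
#' m <- fixation_model("kimura", N = 10)
#' fixation_probability(0, m)    # neutral: 1/N
#' fixation_probability(0.1, m)
#' @export
fixation_probability <- function(s_eff, model) {
  stopifnot(inherits(model, "fixation_model"))
  if (any(!is.finite(s_eff)) || any(s_eff <= -1))
    stop("invalid selection coefficient: 's_eff' must be finite and > -1")
  N <- model$N
  if (N == 1) return(rep(1, length(s_eff)))
  out <- numeric(length(s_eff))
  neutral <- abs(s_eff) < 1e-12
  out[neutral] <- 1 / N
  s <- s_eff[!neutral]
  if (length(s)) {
    if (model$kind == "kimura") {
      out[!neutral] <- expm1(-2 * s) / expm1(-2 * N * s)
    } else {
      lr <- log1p(s)
      out[!neutral] <- expm1(-2 * lr) / expm1(-2 * N * lr)
    }
  }
  out
}

#' Ratio of forward to backward fixation probabilities
#'
#' Computes `P = pi_ij / pi_ji` for a mutation of effect `s_eff` and its
#' reversal, by evaluating the fixation probability in both directions and
#' dividing. Under the Kimura kernel the reverse step has coefficient
#' `-s_eff` and the ratio equals `exp(2 s_eff (N - 1))`; under the
#' Sella-Hirsh kernel the reverse Wrightian ratio is `1/(1 + s_eff)` and the
#' ratio equals `(1 + s_eff)^{2(N-1)}`, the detailed-balance property
#' `(w_j/w_i)^{2(N-1)}`.
#'
#' @inheritParams fixation_probability
#' @return Ratio(s) `P_ij`, same length as `s_eff`.
#' @export
fixation_ratio <- function(s_eff, model) {
  stopifnot(inherits(model, "fixation_model"))
  if (any(!is.finite(s_eff)) || any(s_eff <= -1))
    stop("invalid selection coefficient: 's_eff' must be finite and > -1")
  s_rev <- if (model$kind == "kimura") -s_eff else 1 / (1 + s_eff) - 1
  fixation_probability(s_eff, model) / fixation_probability(s_rev, model)
}
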