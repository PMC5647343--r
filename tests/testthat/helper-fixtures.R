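# Shared fixtures, built in code.

# Exact Wright-Fisher fixation probability of a mutant at 1 copy, by solving
# the absorption equations of the (N+1)-state copy-number chain. Independent
# of the package's fixation kernels.
wf_exact_fixation <- function(s, N) {
  P <- matrix(0, N + 1, N + 1)
  for (i in 0:N) {
    p <- i * (1 + s) / (i * (1 + s) + (N - i))
    P[i + 1, ] <- stats::dbinom(0:N, N, p)
  }
  Q <- P[2:N, 2:N, drop = FALSE]
  a <- solve(diag(N - 1) - Q, P[2:N, N + 1])
  a[1]
}

# Hand-built 2-site, 3-letter landscape whose four point mutants of the wild
# type have fitnesses 0, 0.99, 1.0 and 1.10.
hand_landscape <- function() {
  synthetic_landscape(factors = rbind(c(1, 0, 0.99),
                                      c(1, 1, 1.10)))
}

# Landscape with one modifier whose k target sites have all states viable
# small-effect deleterious before the toggle: L = 4, A = 5; site 1 is the
# modifier (on-state 2, benefit 0.04, so losing it is itself small-effect),
# sites 2 and 3 are its targets, site 4 is neutral.
modifier_landscape <- function() {
  f <- matrix(1, 4, 5)
  f[1, 2] <- 1.04
  f[2, 2:5] <- 0.97
  f[3, 2:5] <- 0.97
  synthetic_landscape(factors = f,
                      modifiers = list(list(site = 1L, on_state = 2L,
                                            targets = c(2L, 3L), benefit = 0.04)))
}

# A line-of-descent stand-in carrying genomes, for analysis functions that
# only need fitnesses and genomes.
fake_lod <- function(fitness, genomes = NULL) {
  lod <- data.frame(id = seq_along(fitness), birth = seq_along(fitness),
                    site = NA_integer_, from = NA_integer_, to = NA_integer_,
                    fitness = fitness)
  if (!is.null(genomes)) attr(lod, "genomes") <- genomes
  class(lod) <- c("line_of_descent", class(lod))
  lod
}

# Small all-neutral landscape (every mutation exactly neutral).
neutral_landscape <- function(L = 10L, A = 4L, seed = 1L) {
  generate_landscape(landscape_config(
    L = L, A = A,
    fractions = c(core_lethal = 0, additive_small = 0, module_member = 0,
                  neutral = 1, modifier = 0),
    seed = seed))
}

# Landscape where every point mutation of the wild type is lethal.
lethal_landscape <- function(L = 10L, A = 4L, seed = 1L) {
  generate_landscape(landscape_config(
    L = L, A = A,
    fractions = c(core_lethal = 1, additive_small = 0, module_member = 0,
                  neutral = 0, modifier = 0),
    seed = seed))
}

# Fast-mixing two-peak specs for Monte-Carlo checks: mutation supply high
# enough that a 10^6-step trajectory decorrelates thousands of times.
mc_test_specs <- function() {
  grid <- expand.grid(u_b = c(0.02, 0.05), mu = c(0.1, 0.2),
                      s = c(0.3, 0.4), eps = c(0.1, 0.2))
  lapply(seq_len(nrow(grid)), function(i) {
    markov_landscape_spec(s = grid$s[i], epsilon = grid$eps[i], n = 2,
                          u_b = grid$u_b[i], s_bar = 0.5, mu = grid$mu[i])
  })
}
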