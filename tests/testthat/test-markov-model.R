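test_that("landscape spec derives the fitness ladder and validates inputs", {
  spec <- markov_landscape_spec(s = 0.1, epsilon = 0.05, n = 2)
  expect_equal(spec$fitness, c(1, 1.05, 1.1, 1.05))
  spec5 <- markov_landscape_spec(s = 0.5, epsilon = 0.1, n = 5)
  expect_equal(spec5$fitness, c(1, 1 + (1:5) * 0.1, 1.4))
  expect_error(markov_landscape_spec(s = 0.1, epsilon = 0.2, n = 2), "epsilon")
  expect_error(markov_landscape_spec(s = 0.1, epsilon = 0.05, n = 1), "n")
  expect_error(markov_landscape_spec(s = 0.1, epsilon = 0.05, u_b = 0.2, s_bar = 0.1),
               "kappa")
  expect_error(markov_landscape_spec(s = -0.1, epsilon = 0.05), "positive")
})

test_that("edge rates follow the exponential-DFE construction and mu cancels in M", {
  spec <- markov_landscape_spec(s = 0.1, epsilon = 0.05, n = 2,
                                u_b = 1e-3, s_bar = 0.1, mu = 0.01)
  expect_equal(spec$kappa, 0.01)
  r <- dfe_mutation_rates(spec)
  expect_true(r$u_robust < r$u_fragile)
  expect_true(r$u_fragile < spec$mu)
  expect_equal(r$M, 0.01, tolerance = 1e-12)
  # mu cancels: same kappa, different mu, same flux ratio
  for (mu in c(1e-4, 1e-3, 0.05)) {
    spec_mu <- markov_landscape_spec(s = 0.1, epsilon = 0.05, n = 2,
                                     u_b = 1e-3, s_bar = 0.1, mu = mu)
    expect_equal(dfe_mutation_rates(spec_mu)$M, 0.01, tolerance = 1e-12)
  }
  # general n: M = kappa^(n-1)
  spec3 <- markov_landscape_spec(s = 0.1, epsilon = 0.05, n = 3,
                                 u_b = 1e-3, s_bar = 0.1, mu = 0.01)
  expect_equal(dfe_mutation_rates(spec3)$M, 0.01^2, tolerance = 1e-12)
  # degenerate override: all rates equal gives M = 1
  expect_equal(edge_rates(0.01, 0.01, 0.01, n = 2)$M, 1)
})

test_that("transition matrix has the minimal-model sparsity pattern and is row-stochastic", {
  spec <- markov_landscape_spec(s = 0.1, epsilon = 0.05, n = 2)
  tm <- build_transition_matrix(spec, fixation_model("kimura", 20))
  T <- tm$T
  for (idx in list(c(1, 3), c(3, 1), c(2, 4), c(4, 2), c(3, 4), c(4, 3))) {
    expect_identical(T[idx[1], idx[2]], 0)
  }
  expect_true(all(T >= 0 & T <= 1))
  expect_equal(rowSums(T), rep(1, 4), tolerance = 1e-12, ignore_attr = TRUE)
  # near-certain fixation of huge-effect steps at unit mutation rates
  spec_big <- markov_landscape_spec(s = 0.95, epsilon = 0.05, n = 2)
  expect_error(
    build_transition_matrix(spec_big, fixation_model("kimura", 50),
                            rates = edge_rates(1, 1, 1)),
    "row sum")
})

test_that("row-stochasticity and stationarity hold for random specs and both kernels", {
  set.seed(7)
  for (i in 1:40) {
    s <- runif(1, 0.05, 0.4)
    spec <- markov_landscape_spec(
      s = s, epsilon = runif(1, 0.01, s * 0.9), n = sample(2:6, 1),
      u_b = 10^runif(1, -4, -1.5), s_bar = runif(1, 0.05, 0.5),
      mu = 10^runif(1, -3, -1),
      use_epsilon_in_u14 = sample(c(TRUE, FALSE), 1))
    kind <- sample(c("kimura", "sella_hirsh"), 1)
    tm <- build_transition_matrix(spec, fixation_model(kind, runif(1, 1, 100)))
    expect_equal(rowSums(tm$T), rep(1, spec$n + 2), tolerance = 1e-12,
                 ignore_attr = TRUE)
    st <- stationary_distribution(tm)
    expect_true(all(st$x_star >= 0))
    expect_equal(sum(st$x_star), 1, tolerance = 1e-12)
    expect_lt(max(abs(drop(st$x_star %*% tm$T) - st$x_star)), 1e-10)
  }
})

test_that("uniform chains are uniform and reducible chains are rejected", {
  for (k in c(3, 4, 6)) {
    T <- matrix(1 / k, k, k)
    st <- stationary_distribution(T)
    expect_equal(unname(st$x_star), rep(1 / k, k), tolerance = 1e-12)
  }
  # two disconnected blocks: no unique stationary distribution
  T <- rbind(c(0.5, 0.5, 0, 0), c(0.5, 0.5, 0, 0),
             c(0, 0, 0.5, 0.5), c(0, 0, 0.5, 0.5))
  expect_error(stationary_distribution(T), "reducible")
  expect_error(stationary_distribution(matrix(c(0.5, 0.3, 0.4, 0.8), 2, 2)),
               "stochastic")
})

test_that("eigenvector peak ratio matches the detailed-balance product (reversibility)", {
  set.seed(11)
  for (i in 1:100) {
    # generic-parameter regime: the occupancy range stays within what a
    # double-precision linear solve resolves componentwise
    s <- runif(1, 0.05, 0.3)
    spec <- markov_landscape_spec(
      s = s, epsilon = runif(1, 0.01, s * 0.5), n = 2,
      u_b = 10^runif(1, -4, -2), s_bar = runif(1, 0.05, 0.5),
      mu = 10^runif(1, -3, -1))
    N <- runif(1, 1.5, 50)
    kind <- sample(c("kimura", "sella_hirsh"), 1)
    sol <- solve_markov(spec, fixation_model(kind, N))
    # independent product over the tree path (mutation rates and fixation
    # probabilities recomputed directly)
    r <- dfe_mutation_rates(spec)
    m <- fixation_model(kind, N)
    arg <- if (kind == "sella_hirsh") function(d) expm1(d) else function(d) d
    up <- function(d) fixation_probability(arg(d), m)
    dn <- function(d) fixation_probability(arg(-d), m)
    half <- spec$s / 2
    prod_eq4 <- (r$u_down * dn(spec$s - spec$epsilon) *
                 r$u_fragile * up(half) * r$u_fragile * up(half)) /
                (r$u_robust * up(spec$s - spec$epsilon) *
                 r$u_down * dn(half) * r$u_down * dn(half))
    expect_equal(sol$R, prod_eq4, tolerance = 1e-8)
  }
})

test_that("occupancy ratio is M at N = 1, increases with N, and crosses 1 once", {
  spec <- markov_landscape_spec(s = 0.2, epsilon = 0.1, n = 2,
                                u_b = 1e-3, s_bar = 0.1, mu = 0.01)
  sol1 <- solve_markov(spec, fixation_model("kimura", 1))
  expect_equal(sol1$R, sol1$M, tolerance = 1e-10)
  Ns <- seq(1, 60, by = 1)
  Rs <- vapply(Ns, function(N) solve_markov(spec, fixation_model("kimura", N))$R,
               numeric(1))
  expect_true(all(diff(Rs) > 0))
  expect_equal(sum(diff(sign(Rs - 1)) != 0), 1)
  ncrit <- n_crit_closed(spec$kappa, spec$epsilon, spec$n)
  crossing <- Ns[which(diff(sign(Rs - 1)) != 0)]
  expect_true(crossing <= ncrit && ncrit <= crossing + 1)
})
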