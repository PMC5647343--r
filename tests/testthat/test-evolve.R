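test_that("without mutation the population stays the ancestral clone", {
  land <- generate_landscape(landscape_config(seed = 4))
  run <- evolve_population(evolution_config(land, N = 30, generations = 200,
                                            U = 0, seed = 1))
  expect_equal(nrow(run$genotypes), 1)
  expect_equal(run$genotypes$n_final, 30)
  expect_identical(run$genomes[1, ], land$wild)
  # zero generations: report of the ancestral state only
  run0 <- evolve_population(evolution_config(land, N = 10, generations = 0, seed = 1))
  expect_equal(most_abundant_genotype(run0)$fitness, 1)
})

test_that("runs are seed-reproducible and keep N constant", {
  land <- generate_landscape(landscape_config(seed = 4))
  cfg <- evolution_config(land, N = 60, generations = 500, seed = 42)
  a <- evolve_population(cfg)
  b <- evolve_population(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$population, b$population)
  expect_equal(sum(a$genotypes$n_final), 60)
  expect_equal(length(a$population), 60)
  c <- evolve_population(evolution_config(land, N = 60, generations = 500, seed = 43))
  expect_false(identical(a$population, c$population))
})

test_that("reverting deleterious mutations makes lineage fitness non-decreasing", {
  land <- generate_landscape(landscape_config(seed = 4))
  run <- evolve_population(evolution_config(land, N = 50, generations = 3000,
                                            revert_deleterious = TRUE, seed = 7))
  lod <- extract_lod(run)
  expect_true(all(diff(lod$fitness) >= 0))
  # without reverting, dips are possible in principle; fitness recorded on
  # the LOD must match re-evaluation either way
  w <- apply(attr(lod, "genomes"), 1, function(g) fitness_of(land, g))
  expect_equal(unname(w), lod$fitness, tolerance = 1e-12)
})

test_that("whole-population non-viability signals extinction", {
  land <- lethal_landscape(L = 8L, A = 4L)
  expect_error(evolve_population(evolution_config(land, N = 2, generations = 50,
                                                  U = 1, seed = 1)),
               "extinct")
})

test_that("most abundant genotype follows count, then birth, then id", {
  fake_run <- function(counts, births) {
    n <- length(counts)
    structure(list(
      genotypes = data.frame(id = seq_len(n), parent = NA_integer_,
                             birth = births, site = NA, from = NA, to = NA,
                             fitness = 1, n_final = counts),
      genomes = matrix(1L, n, 3), population = integer(0)),
      class = "evolution_run")
  }
  expect_equal(most_abundant_genotype(fake_run(c(5, 3), c(1, 1)))$id, 1)
  expect_equal(most_abundant_genotype(fake_run(c(3, 5), c(1, 1)))$id, 2)
  # tie on count: earlier birth wins
  expect_equal(most_abundant_genotype(fake_run(c(4, 4), c(20, 10)))$id, 2)
  # tie on count and birth: lowest id wins
  expect_equal(most_abundant_genotype(fake_run(c(4, 4), c(10, 10)))$id, 1)
})

test_that("line of descent walks parent pointers and differs by one site per step", {
  land <- generate_landscape(landscape_config(seed = 4))
  run <- evolve_population(evolution_config(land, N = 100, generations = 2000,
                                            seed = 5))
  # focal = founder: single-entry LOD
  lod0 <- extract_lod(run, focal = 1)
  expect_equal(nrow(lod0), 1)
  expect_true(is.na(lod0$site[1]))
  lod <- extract_lod(run)
  expect_identical(lod$fitness[1], 1)
  gm <- attr(lod, "genomes")
  if (nrow(lod) > 1) {
    for (i in 2:nrow(lod)) {
      expect_lte(sum(gm[i, ] != gm[i - 1, ]), 1)
    }
  }
  expect_error(extract_lod(run, focal = 1e18), "not found")
})

test_that("a hand-built genealogy yields the known four-entry chain", {
  run <- structure(list(
    genotypes = data.frame(id = c(1, 4, 9, 12),
                           parent = c(NA, 1L, 2L, 3L),
                           birth = c(0L, 3L, 8L, 20L),
                           site = c(NA, 1L, 2L, 3L),
                           from = c(NA, 1L, 1L, 1L),
                           to = c(NA, 2L, 3L, 2L),
                           fitness = c(1, 1.1, 1.05, 1.2),
                           n_final = c(0L, 0L, 0L, 10L)),
    genomes = rbind(c(1L, 1L, 1L), c(2L, 1L, 1L), c(2L, 3L, 1L), c(2L, 3L, 2L)),
    population = rep(4L, 10)), class = "evolution_run")
  lod <- extract_lod(run, focal = most_abundant_genotype(run))
  expect_equal(lod$id, c(1, 4, 9, 12))
  expect_equal(lod$fitness, c(1, 1.1, 1.05, 1.2))
})

test_that("neutral marked mutants fix at frequency 1/N (compact check)", {
  # 400 replicates here; the full 2000-replicate 99-percent-CI version runs
  # in the acceptance suite
  land <- neutral_landscape(L = 6L, A = 3L)
  N <- 10L
  marked <- land$wild; marked[1] <- 2L
  fixed <- vapply(1:400, function(r) {
    cfg <- evolution_config(land, N = N, generations = 200, U = 0,
                            founders = list(genomes = list(land$wild, marked),
                                            counts = c(N - 1L, 1L)),
                            seed = 5000 + r)
    run <- evolve_population(cfg)
    g <- run$genotypes
    alive <- g$n_final > 0
    sum(alive) == 1 && run$genomes[which(alive), 1] == 2L
  }, logical(1))
  p <- mean(fixed)
  # 99.9 percent binomial band around 1/10
  expect_lt(abs(p - 1 / N), 3.29 * sqrt(0.1 * 0.9 / 400))
})

test_that("drift assay returns 1 when no variant can ever fix", {
  lethal <- lethal_landscape(L = 10L, A = 4L)
  rel <- drift_robustness_assay(lethal$wild, lethal, replicates = 3,
                                N_test = 20, generations_test = 100, seed = 2)
  expect_equal(rel, rep(1, 3))
  land <- generate_landscape(landscape_config(seed = 4))
  rel0 <- drift_robustness_assay(land$wild, land, replicates = 3, N_test = 20,
                                 generations_test = 100, U = 0, seed = 2)
  expect_equal(rel0, rep(1, 3))
})

test_that("the drift-fragile preset peak declines under strong drift", {
  land <- generate_landscape(landscape_config(preset = "drift_fragile", seed = 3))
  peak <- peak_genotype(land, "fragile")
  rel <- drift_robustness_assay(peak, land, replicates = 50, N_test = 50,
                                generations_test = 1000, seed = 11)
  expect_lt(median(rel), 1)
})
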