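#' Configuration of a forward-evolution run
#'
#' Discrete-generation Wright-Fisher evolution on a synthetic landscape:
#' each generation, `N` parents are sampled with replacement proportional
#' to fitness (non-viable genotypes occupy slots but never reproduce) and
#' each offspring carries at most one point mutation - with probability `U`
#' a uniform site is changed to a uniform non-identical state. With
#' `revert_deleterious = TRUE` a mutant whose fitness falls below its
#' parent's is prevented from entering the population (the offspring
#' reverts to the parent genome), the treatment without deleterious
#' mutations.
#'
#' @param landscape A `synthetic_landscape`.
#' @param N Population size (`>= 2`), constant across generations.
#' @param generations Number of generations to run.
#' @param U Genomic mutation rate per division, in `[0, 1]` (default 0.1).
#' @param revert_deleterious Logical; see above.
#' @param ancestor Founding genome (default: the landscape wild type).
#' @param founders Optional founding population for runs started from
#'   standing variation: a list with `genomes` (list of genomes) and
#'   `counts` (integer vector summing to `N`). Overrides `ancestor`.
#' @param prune_every Genealogy pruning interval in generations; pruning
#'   retains only ancestors of living individuals (default 100; 0 disables
#'   interim pruning - the final genealogy is always pruned).
#' @param seed RNG seed.
#' @return An object of class `evolution_config`.
#' @export
evolution_config <- function(landscape, N, generations, U = 0.1,
                             revert_deleterious = FALSE, ancestor = NULL,
                             founders = NULL, prune_every = 100L, seed = 1L) {
  stopifnot(inherits(landscape, "synthetic_landscape"))
  N <- as.integer(N)
  if (N < 2L) stop("'N' must be at least 2")
  if (U < 0 || U > 1) stop("'U' must lie in [0, 1]")
  generations <- as.integer(generations)
  if (generations < 0L) stop("'generations' must be non-negative")
  if (is.null(founders)) {
    if (is.null(ancestor)) ancestor <- landscape$wild
    founders <- list(genomes = list(as_genome(ancestor, landscape)),
                     counts = N)
  } else {
    founders$genomes <- lapply(founders$genomes, as_genome, landscape = landscape)
    if (sum(founders$counts) != N) stop("founder counts must sum to N")
  }
  structure(list(landscape = landscape, N = N, U = U,
                 generations = generations,
                 revert_deleterious = isTRUE(revert_deleterious),
                 founders = founders, prune_every = as.integer(prune_every),
                 seed = as.integer(seed)),
            class = "evolution_config")
}

#' Run a forward-evolution experiment
#'
#' Executes the Wright-Fisher process described in [evolution_config()],
#' tracking the full genealogy (pruned of extinct side branches) so that
#' the line of descent of any surviving genotype can be reconstructed.
#' Seed-reproducible: identical config and seed give an identical final
#' population and genealogy.
#'
#' @param config An [evolution_config()].
#' @return An object of class `evolution_run`: `genotypes` (data frame with
#'   `id`, `parent` row index, `birth` generation, mutation `site`/`from`/
#'   `to`, `fitness`, `n_final` count in the final population), `genomes`
#'   (integer matrix, one row per genotype record), `population` (genotype
#'   row per individual), and the `config`.
#' @export
evolve_population <- function(config) {
  stopifnot(inherits(config, "evolution_config"))
  fg <- do.call(rbind, config$founders$genomes)
  res <- with_seed(config$seed,
    .cpp_evolve(unclass(config$landscape), fg, as.integer(config$founders$counts),
                config$N, config$U, config$generations,
                config$revert_deleterious, config$prune_every))
  if (isTRUE(res$extinct))
    stop("population went extinct: every individual is non-viable")
  structure(list(genotypes = res$genotypes, genomes = res$genomes,
                 population = res$population, config = config),
            class = "evolution_run")
}

#' @export
print.evolution_run <- function(x, ...) {
  cat(sprintf("Evolution run: N = %d, U = %g, %d generations%s, seed %d\n",
              x$config$N, x$config$U, x$config$generations,
              if (x$config$revert_deleterious) " (deleterious reverted)" else "",
              x$config$seed))
  cat(sprintf("  genealogy: %d genotype records, %d distinct genotypes alive\n",
              nrow(x$genotypes), sum(x$genotypes$n_final > 0)))
  mab <- most_abundant_genotype(x)
  cat(sprintf("  most abundant genotype: id %g, fitness %g (count %d)\n",
              mab$id, mab$fitness, mab$count))
  invisible(x)
}

#' Most abundant genotype of the final population
#'
#' Ties are broken by earliest birth generation, then by lowest genotype
#' id.
#'
#' @param run An `evolution_run`.
#' @return An object of class `genotype`: `genome` (integer vector), `id`,
#'   `row` (genealogy row), `fitness`, `birth`, `count`.
#' @export
most_abundant_genotype <- function(run) {
  stopifnot(inherits(run, "evolution_run"))
  g <- run$genotypes
  alive <- which(g$n_final > 0)
  if (length(alive) == 0) stop("empty population")
  ord <- alive[order(-g$n_final[alive], g$birth[alive], g$id[alive])]
  row <- ord[1]
  structure(list(genome = run$genomes[row, ], id = g$id[row], row = row,
                 fitness = g$fitness[row], birth = g$birth[row],
                 count = g$n_final[row]),
            class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  cat(sprintf("Genotype id %g (birth %d, fitness %g, count %d)\n%s\n",
              x$id, x$birth, x$fitness, x$count, genome_string(x$genome)))
  invisible(x)
}

#' Extract the line of descent (LOD)
#'
#' Walks the parent pointers from a focal genotype back to its founding
#' ancestor and reverses the path: the "fossil record" of the successful
#' lineage. Consecutive entries differ by at most one site.
#'
#' @param run An `evolution_run`.
#' @param focal A `genotype` (e.g. from [most_abundant_genotype()], the
#'   default), a genealogy row index, or a genotype id.
#' @return An object of class `line_of_descent`: a data frame (`id`,
#'   `birth`, `site`, `from`, `to`, `fitness`) ordered ancestor to focal,
#'   with the genome matrix in `attr(, "genomes")`.
#' @export
extract_lod <- function(run, focal = most_abundant_genotype(run)) {
  stopifnot(inherits(run, "evolution_run"))
  g <- run$genotypes
  row <- if (inherits(focal, "genotype")) focal$row
         else if (is.numeric(focal) && length(focal) == 1L && focal <= nrow(g)) as.integer(focal)
         else match(focal, g$id)
  if (is.na(row) || row < 1L || row > nrow(g))
    stop("focal genotype not found in genealogy")
  path <- integer(0)
  i <- row
  while (!is.na(i)) {
    path <- c(path, i)
    i <- g$parent[i]
  }
  path <- rev(path)
  lod <- g[path, c("id", "birth", "site", "from", "to", "fitness")]
  rownames(lod) <- NULL
  attr(lod, "genomes") <- run$genomes[path, , drop = FALSE]
  class(lod) <- c("line_of_descent", class(lod))
  lod
}

#' Fitness series of a line of descent
#'
#' @param lod A `line_of_descent` (or any data frame with a `fitness`
#'   column, or a bare numeric fitness series).
#' @return Numeric vector of fitnesses, ancestor first.
#' @export
lod_fitness <- function(lod) {
  if (is.numeric(lod)) return(as.numeric(lod))
  as.numeric(lod$fitness)
}

#' Drift-robustness assay
#'
#' Measures a genotype's susceptibility to fitness decline under strong
#' drift: evolves `replicates` populations of size `N_test` founded by the
#' genotype for `generations_test` generations and reports, per replicate,
#' the relative fitness of the final most-abundant genotype,
#' `w(final) / w(genotype)`. Defaults follow the test of 10 populations of
#' 50 individuals for 1000 generations.
#'
#' @param genotype Genome (integer vector, string, or `genotype` object).
#' @param landscape A `synthetic_landscape`.
#' @param replicates Number of replicate test populations (default 10).
#' @param N_test Test population size (default 50).
#' @param generations_test Test run length (default 1000).
#' @param U Genomic mutation rate (default 0.1).
#' @param seed Master seed; replicate seeds are derived deterministically.
#' @return Numeric vector of per-replicate relative fitnesses.
#' @export
drift_robustness_assay <- function(genotype, landscape, replicates = 10L,
                                   N_test = 50L, generations_test = 1000L,
                                   U = 0.1, seed = 1L) {
  g <- if (inherits(genotype, "genotype")) genotype$genome else genotype
  g <- as_genome(g, landscape)
  w0 <- fitness_of(landscape, g)
  if (w0 <= 0) stop("genotype must be viable")
  vapply(seq_len(replicates), function(r) {
    cfg <- evolution_config(landscape, N = N_test, generations = generations_test,
                            U = U, ancestor = g,
                            seed = derive_seed(seed, "drift", r))
    run <- evolve_population(cfg)
    most_abundant_genotype(run)$fitness / w0
  }, numeric(1))
}
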