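#' Configuration of the synthetic genotype-to-fitness landscape
#'
#' The generator emulates the mutational structure of a digital organism
#' with a genome of `L` sites over an `A`-letter alphabet: a lethal core
#' (about one third of sites), additive sites with coexisting small-effect
#' deleterious and small beneficial states, epistatic modules whose joint
#' completion yields a large benefit (so single losses are large-effect),
#' exactly-neutral sites, and modifier loci that - when switched on - grant
#' a benefit while converting their target sites' mutations from
#' small-effect deleterious to lethal. Fitness is multiplicative over site,
#' module and modifier factors; the wild type has fitness exactly 1.
#'
#' Three presets are provided. `"default"` mixes all five site classes and
#' is the study landscape of the evolution experiments. `"drift_robust"`
#' has only modules and modifiers besides the lethal core, so its peak
#' genotype has no viable deleterious mutation below 5 percent.
#' `"drift_fragile"` has only additive small-effect sites with effect
#' ranges capped so that every viable deleterious mutation of its peak
#' genotype stays below 5 percent.
#'
#' @param preset One of `"default"`, `"drift_robust"`, `"drift_fragile"`.
#' @param L Genome length (default 50).
#' @param A Alphabet size (default 26, rendered as letters A-Z).
#' @param fractions Named fractions of the five site classes
#'   (`core_lethal`, `additive_small`, `module_member`, `neutral`,
#'   `modifier`); must sum to 1.
#' @param additive_ben_range Range of the per-site beneficial effect of
#'   additive sites. The lower end sits below the drift barrier of a
#'   population of a few hundred individuals, so that small populations
#'   cannot reliably hold every climbed site.
#' @param additive_del_range Range of small deleterious effects of
#'   additive sites' `del_small` states (below 0.05).
#' @param additive_del_large_range Range of large deleterious effects of
#'   additive sites' `del_large` states.
#' @param additive_state_counts Named integer vector partitioning the
#'   `A - 1` non-wild states of an additive site into `beneficial`,
#'   `neutral`, `del_small` and `del_large` states. The beneficial states
#'   all carry the site's benefit; once a site is climbed, falling back to
#'   the wild or a neutral state is a small-effect deleterious mutation -
#'   fragility is acquired by climbing.
#' @param module_size Number of member sites per epistatic module.
#' @param module_benefit_range Range of the module benefit `S_mod`
#'   (at least 0.05, so single member losses are large-effect).
#' @param member_del_range Range of the large deleterious effect of a
#'   module member's off-pathway states.
#' @param modifier_benefit Direct benefit `b_mod` of switching a modifier
#'   on. The default is small (0.008): a modifier's payoff is
#'   drift-conditional (it forecloses future small-effect fixations), not
#'   a large direct gain. The `drift_robust` preset raises it to 0.06 so
#'   that losing the modifier, `b/(1+b) > 0.05`, is large-effect.
#' @param targets_per_modifier Number of sites whose mutations each
#'   modifier converts to lethal.
#' @param seed Generator seed.
#' @return An object of class `landscape_config`.
#' @export
landscape_config <- function(preset = c("default", "drift_robust", "drift_fragile"),
                             L = 50L, A = 26L,
                             fractions = NULL,
                             additive_ben_range = c(0.001, 0.02),
                             additive_del_range = c(0.005, 0.045),
                             additive_del_large_range = c(0.05, 0.25),
                             additive_state_counts = c(beneficial = 5L, neutral = 5L,
                                                       del_small = 3L, del_large = 12L),
                             module_size = 3L,
                             module_benefit_range = c(0.08, 0.15),
                             member_del_range = c(0.05, 0.25),
                             modifier_benefit = 0.008,
                             targets_per_modifier = 4L,
                             seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(fractions)) {
    fractions <- switch(preset,
      default = c(core_lethal = 0.34, additive_small = 0.30,
                  module_member = 0.18, neutral = 0.12, modifier = 0.06),
      drift_robust = c(core_lethal = 0.34, additive_small = 0,
                       module_member = 0.36, neutral = 0.24, modifier = 0.06),
      drift_fragile = c(core_lethal = 0.34, additive_small = 0.54,
                        module_member = 0, neutral = 0.12, modifier = 0))
  }
  if (preset == "drift_robust" && missing(modifier_benefit)) {
    # every viable deleterious step off the robust peak must be large-effect
    modifier_benefit <- 0.06
  }
  if (preset == "drift_fragile") {
    # all-small neighbourhood: no large-effect states, and effects capped so
    # that losing a site's benefit while landing on a deleterious state stays
    # below the 5 percent boundary
    additive_ben_range <- pmin(additive_ben_range, 0.02)
    additive_del_range <- pmin(additive_del_range, 0.02)
    additive_state_counts <- c(beneficial = 5L, neutral = 5L,
                               del_small = 15L, del_large = 0L)
  }
  classes <- c("core_lethal", "additive_small", "module_member", "neutral", "modifier")
  if (!setequal(names(fractions), classes))
    stop("'fractions' must be named with the five site classes")
  fractions <- fractions[classes]
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("site-class fractions must sum to 1")
  L <- as.integer(L); A <- as.integer(A)
  if (L < 1L || A < 2L) stop("'L' and 'A' must be positive (A >= 2)")
  additive_state_counts <- vapply(additive_state_counts, as.integer, integer(1))
  if (fractions["additive_small"] > 0 && sum(additive_state_counts) != A - 1L)
    stop("'additive_state_counts' must partition the A - 1 non-wild states")
  structure(list(preset = preset, L = L, A = A, fractions = fractions,
                 additive_ben_range = additive_ben_range,
                 additive_del_range = additive_del_range,
                 additive_del_large_range = additive_del_large_range,
                 additive_state_counts = additive_state_counts,
                 module_size = as.integer(module_size),
                 module_benefit_range = module_benefit_range,
                 member_del_range = member_del_range,
                 modifier_benefit = modifier_benefit,
                 targets_per_modifier = as.integer(targets_per_modifier),
                 seed = as.integer(seed)),
            class = "landscape_config")
}

#' Construct a synthetic landscape from explicit tables
#'
#' Low-level constructor behind [generate_landscape()], also useful for
#' hand-built landscapes in tests and examples. Validates the core
#' invariants: the wild type has fitness exactly 1 and all factors are
#' non-negative.
#'
#' @param factors `L x A` matrix of per-site per-state multiplicative
#'   factors (0 encodes lethal).
#' @param wild Wild state per site (default state 1 everywhere).
#' @param site_class Optional per-site class labels.
#' @param modules List of `list(sites, targets, benefit)`.
#' @param modifiers List of `list(site, on_state, targets, benefit)`.
#' @param config Optional [landscape_config()] to carry along.
#' @return A `synthetic_landscape`.
#' @export
synthetic_landscape <- function(factors, wild = rep(1L, nrow(factors)),
                                site_class = NULL, modules = list(),
                                modifiers = list(), config = NULL) {
  factors <- as.matrix(factors)
  if (any(factors < 0)) stop("fitness factors must be non-negative")
  L <- nrow(factors); A <- ncol(factors)
  if (is.null(site_class)) site_class <- rep("unspecified", L)
  land <- structure(list(L = L, A = A, wild = as.integer(wild),
                         site_class = site_class, factors = factors,
                         modules = modules, modifiers = modifiers,
                         config = config),
                    class = "synthetic_landscape")
  if (abs(fitness_of(land, land$wild) - 1) > 1e-12)
    stop("wild-type genome must have fitness exactly 1")
  land
}

#' Generate a synthetic fitness landscape
#'
#' Deterministic given the config's seed: site classes are assigned,
#' per-site per-state multiplicative factors are drawn (0 encodes lethal),
#' module member sites are grouped with target states and a joint benefit,
#' and modifier loci are wired to disjoint target-site sets.
#'
#' @param config A [landscape_config()].
#' @return An object of class `synthetic_landscape` with elements `L`, `A`,
#'   `wild` (wild state per site, all state 1), `site_class`, `factors`
#'   (`L x A` matrix of multiplicative factors), `modules`, `modifiers`,
#'   and the `config`.
#' @export
generate_landscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "landscape_config"))
  with_seed(config$seed, {
    L <- config$L; A <- config$A
    counts <- round(config$fractions * L)
    # reconcile rounding so counts sum to L (adjust the neutral class)
    counts["neutral"] <- counts["neutral"] + (L - sum(counts))
    if (any(counts < 0)) stop("site-class fractions incompatible with L")
    n_modules <- if (counts["module_member"] > 0) counts["module_member"] %/% config$module_size else 0L
    counts["neutral"] <- counts["neutral"] + counts["module_member"] - n_modules * config$module_size
    counts["module_member"] <- n_modules * config$module_size
    site_class <- sample(rep(names(counts), counts))
    wild <- rep(1L, L)
    factors <- matrix(1, L, A)
    for (l in which(site_class == "core_lethal")) factors[l, -1L] <- 0
    for (l in which(site_class == "additive_small")) {
      b <- runif(1, config$additive_ben_range[1], config$additive_ben_range[2])
      states <- sample(2:A)
      cnt <- config$additive_state_counts
      grp <- rep(names(cnt), cnt)
      factors[l, states[grp == "beneficial"]] <- 1 + b
      ds <- states[grp == "del_small"]
      factors[l, ds] <- 1 - runif(length(ds), config$additive_del_range[1],
                                  config$additive_del_range[2])
      dl <- states[grp == "del_large"]
      factors[l, dl] <- 1 - runif(length(dl), config$additive_del_large_range[1],
                                  config$additive_del_large_range[2])
    }
    module_sites <- which(site_class == "module_member")
    modules <- list()
    if (n_modules > 0) {
      grp <- split(module_sites, rep(seq_len(n_modules), each = config$module_size))
      modules <- lapply(grp, function(sites) {
        targets <- sample(2:A, length(sites), replace = TRUE)
        for (i in seq_along(sites)) {
          others <- setdiff(2:A, targets[i])
          factors[sites[i], others] <<- 1 - runif(length(others),
                                                  config$member_del_range[1],
                                                  config$member_del_range[2])
        }
        list(sites = sites, targets = targets,
             benefit = runif(1, config$module_benefit_range[1],
                             config$module_benefit_range[2]))
      })
      names(modules) <- NULL
    }
    modifier_sites <- which(site_class == "modifier")
    target_pool <- which(site_class == "additive_small")
    if (length(target_pool) == 0) target_pool <- which(site_class == "neutral")
    target_pool <- sample(target_pool)
    modifiers <- list()
    for (i in seq_along(modifier_sites)) {
      k <- min(config$targets_per_modifier, length(target_pool))
      targets <- if (k > 0) sort(target_pool[seq_len(k)]) else integer(0)
      target_pool <- target_pool[-seq_len(max(k, 0))]
      on_state <- sample(2:A, 1)
      factors[modifier_sites[i], on_state] <- 1 + config$modifier_benefit
      modifiers[[i]] <- list(site = modifier_sites[i], on_state = on_state,
                             targets = targets, benefit = config$modifier_benefit)
    }
    land <- structure(list(L = L, A = A, wild = wild,
                           site_class = site_class, factors = factors,
                           modules = modules, modifiers = modifiers,
                           config = config),
                      class = "synthetic_landscape")
    stopifnot(fitness_of(land, wild) == 1)
    land
  })
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat(sprintf("Synthetic fitness landscape: L = %d, A = %d (preset '%s', seed %d)\n",
              x$L, x$A, x$config$preset, x$config$seed))
  print(table(x$site_class))
  cat(sprintf("  %d modules, %d modifiers; wild-type fitness %g\n",
              length(x$modules), length(x$modifiers), fitness_of(x, x$wild)))
  invisible(x)
}

#' Evaluate the fitness of a genome
#'
#' Pure multiplicative evaluation of a genome on a synthetic landscape.
#' Fitness 0 encodes a non-viable genotype: any non-wild state at a lethal
#' core site, or - with a modifier switched on - any non-wild state at one
#' of its target sites.
#'
#' @param landscape A `synthetic_landscape`.
#' @param genome Integer state vector of length `L`, or a single character
#'   string over the landscape alphabet (letters starting at "A").
#' @return Non-negative fitness; 0 means non-viable.
#' @export
fitness_of <- function(landscape, genome) {
  .cpp_fitness(unclass(landscape), as_genome(genome, landscape))
}

#' Enumerate every point mutant of a genome
#'
#' Generates all `(A - 1) * L` single point mutants and evaluates each one,
#' the mutant census underlying every DFE calculation (1250 mutants for the
#' default 50-site, 26-letter genome).
#'
#' @inheritParams fitness_of
#' @return A data frame with `(A - 1) * L` rows: `site`, `from`, `to`
#'   (letters), `w_mutant`.
#' @export
enumerate_point_mutants <- function(landscape, genome) {
  g <- as_genome(genome, landscape)
  d <- .cpp_enumerate_mutants(unclass(landscape), g)
  d$from <- state_letters(d$from)
  d$to <- state_letters(d$to)
  d
}

#' Convert genomes between letter and integer-state representations
#'
#' @param genome Character string or integer vector.
#' @param landscape Landscape supplying `L` and `A`.
#' @return Integer state vector (1-based states).
#' @export
as_genome <- function(genome, landscape) {
  if (is.character(genome)) {
    stopifnot(length(genome) == 1L)
    g <- utf8ToInt(toupper(genome)) - utf8ToInt("A") + 1L
  } else {
    g <- as.integer(genome)
  }
  if (length(g) != landscape$L)
    stop("genome length does not match landscape")
  if (any(is.na(g)) || any(g < 1L) || any(g > landscape$A))
    stop("alphabet mismatch: genome states outside landscape alphabet")
  g
}

state_letters <- function(states) {
  intToUtf8(utf8ToInt("A") + as.integer(states) - 1L, multiple = TRUE)
}

#' @rdname as_genome
#' @param states Integer state vector.
#' @export
genome_string <- function(states) {
  intToUtf8(utf8ToInt("A") + as.integer(states) - 1L)
}

#' The constructed peak genotypes of a landscape
#'
#' `"fragile"`: every additive site set to its (first) beneficial state -
#' the drift-fragile peak, reached by many small steps and surrounded by
#' small-effect deleterious mutations. `"robust"`: every module completed
#' and every modifier switched on - the drift-robust peak, whose viable
#' deleterious neighbours are all large-effect.
#'
#' @param landscape A `synthetic_landscape`.
#' @param which `"fragile"` or `"robust"`.
#' @return Integer genome vector.
#' @export
peak_genotype <- function(landscape, which = c("fragile", "robust")) {
  peak <- match.arg(which)
  g <- landscape$wild
  if (peak == "fragile") {
    for (l in base::which(landscape$site_class == "additive_small")) {
      best <- max(landscape$factors[l, ])
      g[l] <- which(landscape$factors[l, ] == best)[1]
    }
  } else {
    for (m in landscape$modules) g[m$sites] <- m$targets
    for (m in landscape$modifiers) g[m$site] <- m$on_state
  }
  g
}

#' Write genomes to FASTA / read genomes from FASTA
#'
#' Genomes are stored as upper-case letter sequences over the landscape
#' alphabet (A-Z).
#'
#' @param genomes List of integer genomes (or a single genome).
#' @param file Path.
#' @param names Sequence names (default `g1`, `g2`, ...).
#' @return `read_genomes_fasta` returns a named list of integer genomes.
#' @export
write_genomes_fasta <- function(genomes, file, names = NULL) {
  if (!is.list(genomes)) genomes <- list(genomes)
  if (is.null(names)) names <- paste0("g", seq_along(genomes))
  seqinr::write.fasta(lapply(genomes, function(g) strsplit(genome_string(g), "")[[1]]),
                      names = names, file.out = file)
  invisible(file)
}

#' @rdname write_genomes_fasta
#' @param landscape Landscape used to validate the alphabet.
#' @export
read_genomes_fasta <- function(file, landscape) {
  seqs <- seqinr::read.fasta(file, seqtype = "AA", as.string = TRUE)
  out <- lapply(seqs, function(s) as_genome(as.character(s), landscape))
  names(out) <- names(seqs)
  out
}
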