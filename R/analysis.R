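#' Classify the fitness effect of a point mutation
#'
#' Classes over the effect `s = w_mutant / w_parent - 1`: `lethal`
#' (non-viable, `w_mutant = 0`), `deleterious_large` (`s <= -0.05`),
#' `deleterious_small` (`-0.05 < s < 0`), `neutral` (`|s|` below the
#' neutrality tolerance; the synthetic landscape makes neutral effects
#' exact, so the tolerance is numerical, not biological), `beneficial`
#' (`s > 0`). A mutation of effect exactly -5 percent is large-effect.
#'
#' @param w_parent Fitness of the reference genotype (must be positive).
#' @param w_mutant Fitness of the mutant (0 = non-viable). Vectorised;
#'   `w_parent` is recycled.
#' @param small_threshold Boundary between small- and large-effect
#'   deleterious mutations (default 0.05).
#' @param neutral_tol Neutrality tolerance on `|s|` (default 1e-12).
#' @return Factor with levels `lethal`, `deleterious_large`,
#'   `deleterious_small`, `neutral`, `beneficial`.
#' @export
classify_mutation <- function(w_parent, w_mutant, small_threshold = 0.05,
                              neutral_tol = 1e-12) {
  if (any(w_parent <= 0)) stop("non-viable reference: 'w_parent' must be positive")
  s <- w_mutant / w_parent - 1
  cls <- ifelse(w_mutant == 0, "lethal",
         ifelse(abs(s) < neutral_tol, "neutral",
         ifelse(s > 0, "beneficial",
         ifelse(s <= -small_threshold, "deleterious_large", "deleterious_small"))))
  factor(cls, levels = mutation_classes())
}

#' @rdname classify_mutation
#' @export
mutation_classes <- function() {
  c("lethal", "deleterious_large", "deleterious_small", "neutral", "beneficial")
}

#' Distribution-of-fitness-effects summary of a genotype
#'
#' Enumerates all `(A - 1) * L` point mutants, classifies each one, and
#' returns the per-class fractions (number in class divided by the mutant
#' count) together with the mean mutant relative fitness
#' `mean(w_m / w_0)`.
#'
#' @param landscape A `synthetic_landscape`.
#' @param genotype Genome (integer vector, string, or `genotype` object).
#' @param label Optional source label (e.g. treatment) carried through.
#' @param id Optional genotype identifier.
#' @return One-row data frame of class `dfe_summary`: `id`, `label`, `w`,
#'   per-class fractions `f_lethal`, `f_deleterious_large`,
#'   `f_deleterious_small`, `f_neutral`, `f_beneficial`,
#'   `mean_relative_fitness` and `n_mutants`.
#' @export
dfe_summary <- function(landscape, genotype, label = NA_character_, id = NA) {
  g <- if (inherits(genotype, "genotype")) genotype$genome else genotype
  g <- as_genome(g, landscape)
  w0 <- fitness_of(landscape, g)
  if (w0 <= 0) stop("genotype must be viable")
  mut <- enumerate_point_mutants(landscape, g)
  cls <- classify_mutation(w0, mut$w_mutant)
  frac <- as.numeric(table(cls)) / nrow(mut)
  out <- data.frame(id = if (is.na(id[1])) NA else id, label = label, w = w0,
                    f_lethal = frac[1], f_deleterious_large = frac[2],
                    f_deleterious_small = frac[3], f_neutral = frac[4],
                    f_beneficial = frac[5],
                    mean_relative_fitness = mean(mut$w_mutant / w0),
                    n_mutants = nrow(mut))
  class(out) <- c("dfe_summary", class(out))
  out
}

#' Write a genotype's full DFE table as TSV
#'
#' One row per point mutant: `site`, `from_state`, `to_state` (letters),
#' `w_mutant`, the fitness effect `s_effect = w_m/w_0 - 1`, and the
#' mutation `class`.
#'
#' @inheritParams dfe_summary
#' @param file Output path.
#' @return Invisibly, the written path.
#' @export
write_dfe_tsv <- function(landscape, genotype, file) {
  g <- if (inherits(genotype, "genotype")) genotype$genome else genotype
  g <- as_genome(g, landscape)
  w0 <- fitness_of(landscape, g)
  if (w0 <= 0) stop("genotype must be viable")
  mut <- enumerate_point_mutants(landscape, g)
  out <- data.frame(site = mut$site, from_state = mut$from, to_state = mut$to,
                    w_mutant = mut$w_mutant,
                    s_effect = mut$w_mutant / w0 - 1,
                    class = classify_mutation(w0, mut$w_mutant))
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Maintained beneficial mutations on a line of descent
#'
#' A beneficial step (fitness strictly increasing over the previous LOD
#' entry) is *maintained* if (1) it attains a new fitness maximum on the
#' LOD up to that point, and (2) fitness never falls below the value
#' immediately preceding the step except transiently - every maximal run
#' of consecutive later entries below that value must be shorter than
#' `transient_max + 1` genotypes and must be followed by a recovery to at
#' least that value (a sub-threshold run extending to the end of the LOD
#' disqualifies the step).
#'
#' @param lod A `line_of_descent`, or a bare numeric fitness series.
#' @param relative_to `"previous"` (default): the reference value is the
#'   fitness immediately before the step, `w[i-1]`; `"running_max"`: the
#'   running maximum before the step (alternative reading, provided but
#'   not endorsed).
#' @param transient_max Longest tolerated sub-reference run (default 4,
#'   i.e. fewer than five consecutive genotypes).
#' @return Data frame with one row per maintained step: `step` (LOD index
#'   of the post-step genotype), `fitness_effect`
#'   (`w[i]/w[i-1] - 1`), `w_before`, `w_after`.
#' @export
maintained_beneficials <- function(lod, relative_to = c("previous", "running_max"),
                                   transient_max = 4L) {
  relative_to <- match.arg(relative_to)
  w <- lod_fitness(lod)
  m <- length(w)
  if (m < 2L) stop("LOD must contain at least 2 entries")
  keep <- integer(0)
  for (i in 2:m) {
    if (w[i] <= w[i - 1]) next                       # not a beneficial step
    if (w[i] <= max(w[1:(i - 1)])) next              # not a new maximum
    ref <- if (relative_to == "previous") w[i - 1] else max(w[1:(i - 1)])
    ok <- TRUE
    if (i < m) {
      below <- w[(i + 1):m] < ref
      r <- rle(below)
      runs <- r$lengths[r$values]
      if (length(runs)) {
        if (any(runs > transient_max)) ok <- FALSE
        # a transient dip must recover: a final below-reference run never does
        if (below[length(below)]) ok <- FALSE
      }
    }
    if (ok) keep <- c(keep, i)
  }
  data.frame(step = keep,
             fitness_effect = w[keep] / w[keep - 1L] - 1,
             w_before = w[keep - 1L], w_after = w[keep])
}

#' Equal-fitness cohorts across treatments
#'
#' For each lineage, selects one genotype per distinct fitness value - the
#' last genotype on the LOD at that value - then retains only fitness
#' values represented by more than `min_lineages` lineages in *both*
#' treatments. Used to compare genotypes of equal fitness evolved at
#' different population sizes, removing fitness as a confounder. Matching
#' is exact by default; `bin_digits` rounds fitness to significant digits
#' first (useful when effects are continuous).
#'
#' @param lods_small,lods_large Lists of `line_of_descent` objects (or
#'   bare fitness series), one per lineage.
#' @param landscape Optional `synthetic_landscape`; if supplied, each
#'   selected genotype's small-effect-deleterious fraction is computed
#'   (requires true `line_of_descent` inputs carrying genomes).
#' @param min_lineages Minimum lineage count per treatment, exclusive
#'   (default 20: a value qualifies with more than 20 lineages in both).
#' @param bin_digits Optional significant digits for fitness binning.
#' @return A list of class `fitness_cohorts`: `values` (data frame of
#'   qualifying fitness values with lineage counts) and `members` (one row
#'   per selected genotype: `fitness`, `treatment`, `lineage`, `lod_index`,
#'   and `f_deleterious_small` when a landscape was supplied). Empty, with
#'   a diagnostic message, when no fitness value qualifies.
#' @export
equal_fitness_cohorts <- function(lods_small, lods_large, landscape = NULL,
                                  min_lineages = 20L, bin_digits = NULL) {
  stopifnot(length(lods_small) > 0, length(lods_large) > 0)
  pick <- function(lods, treatment) {
    do.call(rbind, lapply(seq_along(lods), function(i) {
      w <- lod_fitness(lods[[i]])
      wb <- if (is.null(bin_digits)) w else signif(w, bin_digits)
      idx <- vapply(unique(wb), function(v) max(which(wb == v)), integer(1))
      data.frame(fitness = wb[idx], treatment = treatment, lineage = i,
                 lod_index = idx)
    }))
  }
  members <- rbind(pick(lods_small, "small"), pick(lods_large, "large"))
  counts <- table(members$fitness, members$treatment)
  vals <- rownames(counts)[counts[, "small"] > min_lineages &
                           counts[, "large"] > min_lineages]
  if (length(vals) == 0) {
    message("no fitness value is shared by more than ", min_lineages,
            " lineages in both treatments")
    return(structure(list(values = data.frame(fitness = numeric(0),
                                              n_small = integer(0),
                                              n_large = integer(0)),
                          members = members[0, ]),
                     class = "fitness_cohorts"))
  }
  members$fitness_key <- as.character(members$fitness)
  members <- members[members$fitness_key %in% vals, ]
  if (!is.null(landscape)) {
    lods <- list(small = lods_small, large = lods_large)
    members$f_deleterious_small <- vapply(seq_len(nrow(members)), function(r) {
      lod <- lods[[members$treatment[r]]][[members$lineage[r]]]
      gm <- attr(lod, "genomes")
      if (is.null(gm)) return(NA_real_)
      dfe_summary(landscape, gm[members$lod_index[r], ])$f_deleterious_small
    }, numeric(1))
  }
  values <- data.frame(fitness = as.numeric(vals), fitness_key = vals,
                       n_small = as.integer(counts[vals, "small"]),
                       n_large = as.integer(counts[vals, "large"]))
  structure(list(values = values, members = members), class = "fitness_cohorts")
}

#' Epistatic signatures along a line of descent
#'
#' For each maintained beneficial step, compares the mutational
#' neighbourhood before and after the step: the viable-deleterious
#' likelihood (small- plus large-effect fractions), the lethal likelihood,
#' and their components. A step is flagged when it reduces the
#' viable-deleterious likelihood by at least 50 percent relative
#' (`flag_relative`) or by at least 0.1 absolute (`flag_absolute`) - the
#' signature of an epistatic mutation that buys robustness by converting
#' deleterious neighbours into lethal ones. `share_small` reports the
#' fraction of the deleterious decrease attributable to the small-effect
#' class.
#'
#' @param lod A `line_of_descent` carrying genomes.
#' @param landscape The `synthetic_landscape` the LOD evolved on.
#' @param rel_threshold Relative-reduction flag threshold (default 0.5).
#' @param abs_threshold Absolute-reduction flag threshold (default 0.1).
#' @return Data frame with one row per maintained beneficial step.
#' @export
epistatic_signatures <- function(lod, landscape, rel_threshold = 0.5,
                                 abs_threshold = 0.1) {
  gm <- attr(lod, "genomes")
  if (is.null(gm)) stop("LOD does not carry genomes")
  steps <- maintained_beneficials(lod)
  if (nrow(steps) == 0) {
    return(data.frame(fitness_effect = numeric(0), step = integer(0),
                      pre_deleterious = numeric(0), post_deleterious = numeric(0),
                      pre_lethal = numeric(0), post_lethal = numeric(0),
                      pre_small = numeric(0), post_small = numeric(0),
                      pre_large = numeric(0), post_large = numeric(0),
                      drop_deleterious = numeric(0), relative_drop = numeric(0),
                      share_small = numeric(0), flag_relative = logical(0),
                      flag_absolute = logical(0)))
  }
  out <- lapply(steps$step, function(i) {
    pre <- dfe_summary(landscape, gm[i - 1L, ])
    post <- dfe_summary(landscape, gm[i, ])
    pre_del <- pre$f_deleterious_small + pre$f_deleterious_large
    post_del <- post$f_deleterious_small + post$f_deleterious_large
    drop_del <- pre_del - post_del
    drop_small <- pre$f_deleterious_small - post$f_deleterious_small
    data.frame(step = i,
               pre_deleterious = pre_del, post_deleterious = post_del,
               pre_lethal = pre$f_lethal, post_lethal = post$f_lethal,
               pre_small = pre$f_deleterious_small,
               post_small = post$f_deleterious_small,
               pre_large = pre$f_deleterious_large,
               post_large = post$f_deleterious_large,
               drop_deleterious = drop_del,
               relative_drop = if (pre_del > 0) drop_del / pre_del else NA_real_,
               share_small = if (drop_del > 0) drop_small / drop_del else NA_real_,
               flag_relative = pre_del > 0 && drop_del / pre_del >= rel_threshold,
               flag_absolute = drop_del >= abs_threshold)
  })
  cbind(steps[, "fitness_effect", drop = FALSE], do.call(rbind, out))
}

#' Compare a metric between two treatments
#'
#' Medians and a one-tailed Mann-Whitney U test (normal approximation,
#' suitable for tied data), as used for all treatment contrasts; the
#' reported `U` is the number of pairs in which the first sample exceeds
#' the second (ties count one half).
#'
#' @param x,y Numeric samples, or `dfe_summary` data frames with `metric`.
#' @param metric Column name when `x`/`y` are data frames.
#' @param alternative `"less"` (the first sample is stochastically
#'   smaller) or `"greater"`; one-tailed directions are fixed by the
#'   stated hypothesis and recorded in the result.
#' @return A list of class `treatment_comparison`: `median_x`, `median_y`,
#'   `U`, `p_value`, `alternative`, `n_x`, `n_y`, `metric`.
#' @export
compare_treatments <- function(x, y, metric = NULL,
                               alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.data.frame(x)) {
    stopifnot(!is.null(metric))
    x <- x[[metric]]
    y <- y[[metric]]
  }
  ht <- stats::wilcox.test(x, y, alternative = alternative, exact = FALSE,
                           correct = FALSE)
  structure(list(median_x = stats::median(x), median_y = stats::median(y),
                 U = unname(ht$statistic), p_value = ht$p.value,
                 alternative = alternative, n_x = length(x), n_y = length(y),
                 metric = metric),
            class = "treatment_comparison")
}

#' @export
print.treatment_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, n = %d vs %d, p = %.3g (%s)%s\n",
              x$U, x$n_x, x$n_y, x$p_value, x$alternative,
              if (is.null(x$metric)) "" else paste0(" [", x$metric, "]")))
  cat(sprintf("  medians: %.4g vs %.4g\n", x$median_x, x$median_y))
  invisible(x)
}

#' Spearman rank correlation with an error on constant input
#'
#' @param x,y Paired numeric covariates.
#' @return List with `rho` and `p_value`.
#' @export
spearman_rho <- function(x, y) {
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("undefined correlation: constant input")
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ht$estimate), p_value = ht$p.value)
}

#' Per-cohort treatment comparison with Bonferroni correction
#'
#' For every qualifying fitness value in a [equal_fitness_cohorts()]
#' result, compares the small-effect-deleterious fractions of the two
#' treatments (one-tailed: small below large) and applies a Bonferroni
#' correction across the cohort family.
#'
#' @param cohorts A `fitness_cohorts` result with `f_deleterious_small`.
#' @param alpha Family-wise significance level (default 0.05).
#' @return Data frame: `fitness`, `n_small`, `n_large`, `U`, `p_value`,
#'   `p_bonferroni`, `significant`.
#' @export
cohort_comparison <- function(cohorts, alpha = 0.05) {
  stopifnot(inherits(cohorts, "fitness_cohorts"))
  if (nrow(cohorts$values) == 0) return(
    data.frame(fitness = numeric(0), n_small = integer(0), n_large = integer(0),
               U = numeric(0), p_value = numeric(0), p_bonferroni = numeric(0),
               significant = logical(0)))
  rows <- lapply(seq_len(nrow(cohorts$values)), function(i) {
    v <- cohorts$values$fitness[i]
    m <- cohorts$members[cohorts$members$fitness_key == cohorts$values$fitness_key[i], ]
    cmp <- compare_treatments(m$f_deleterious_small[m$treatment == "small"],
                              m$f_deleterious_small[m$treatment == "large"],
                              alternative = "less")
    data.frame(fitness = v, n_small = cmp$n_x, n_large = cmp$n_y,
               U = cmp$U, p_value = cmp$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- stats::p.adjust(out$p_value, method = "bonferroni")
  out$significant <- out$p_bonferroni < alpha
  out
}
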