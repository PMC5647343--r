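test_that("mutation classification partitions effects with the 5 percent boundary", {
  expect_equal(as.character(classify_mutation(1, 0.97)), "deleterious_small")
  expect_equal(as.character(classify_mutation(1, 0)), "lethal")
  # s = -0.05 exactly is large-effect ("greater than or equal to 5 percent")
  expect_equal(as.character(classify_mutation(1, 0.95)), "deleterious_large")
  expect_equal(as.character(classify_mutation(1, 0.9500001)), "deleterious_small")
  expect_equal(as.character(classify_mutation(1, 1)), "neutral")
  expect_equal(as.character(classify_mutation(1, 1 + 1e-14)), "neutral")
  expect_equal(as.character(classify_mutation(1, 1.02)), "beneficial")
  expect_equal(as.character(classify_mutation(2, 1.92)), "deleterious_small")
  expect_error(classify_mutation(0, 0.5), "non-viable reference")
  # exhaustive and exclusive over arbitrary mutants
  set.seed(1)
  cls <- classify_mutation(1, c(0, runif(500, 0, 2)))
  expect_false(any(is.na(cls)))
})

test_that("DFE summary reproduces the hand-enumerated 2-site example", {
  land <- hand_landscape()
  sm <- dfe_summary(land, land$wild)
  expect_equal(sm$n_mutants, 4)
  expect_equal(sm$f_lethal, 0.25)
  expect_equal(sm$f_deleterious_small, 0.25)
  expect_equal(sm$f_deleterious_large, 0)
  expect_equal(sm$f_neutral, 0.25)
  expect_equal(sm$f_beneficial, 0.25)
  expect_equal(sm$mean_relative_fitness, 0.7725)
})

test_that("DFE fractions always sum to one", {
  land <- generate_landscape(landscape_config(seed = 9))
  set.seed(3)
  for (i in 1:5) {
    g <- land$wild
    idx <- sample(land$L, 4)
    for (l in idx) {
      viable <- which(land$factors[l, ] > 0)
      g[l] <- sample(viable, 1)
    }
    if (fitness_of(land, g) == 0) next
    sm <- dfe_summary(land, g)
    expect_equal(sm$f_lethal + sm$f_deleterious_large + sm$f_deleterious_small +
                   sm$f_neutral + sm$f_beneficial, 1, tolerance = 1e-12)
  }
})

test_that("the DFE TSV export round-trips the enumerated mutants", {
  land <- hand_landscape()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dfe_tsv(land, land$wild, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 4)
  expect_equal(sort(tab$w_mutant), c(0, 0.99, 1, 1.10))
  expect_equal(tab$s_effect, tab$w_mutant - 1)
  expect_setequal(tab$class, c("lethal", "deleterious_small", "neutral", "beneficial"))
})

test_that("maintained-beneficial detection follows the transience rule", {
  # monotone LOD: every beneficial step is maintained
  mb <- maintained_beneficials(fake_lod(c(1, 1.1, 1.1, 1.3, 1.45)))
  expect_equal(mb$step, c(2, 4, 5))
  # a five-genotype sub-reference run disqualifies the step to 1.2; the
  # final step to 1.3 is a new maximum with no later entries
  mb <- maintained_beneficials(fake_lod(c(1, 1.2, 0.9, 0.9, 0.9, 0.9, 0.9, 1.3)))
  expect_equal(mb$step, 8)
  # a shallow dip (staying at or above the pre-step value) is harmless
  mb <- maintained_beneficials(fake_lod(c(1, 1.2, 1.1, 1.25)))
  expect_equal(mb$step, c(2, 4))
  # four consecutive low genotypes are transient, five are not
  w4 <- c(1, 1.2, rep(0.95, 4), 1.21)
  expect_true(2 %in% maintained_beneficials(fake_lod(w4))$step)
  w5 <- c(1, 1.2, rep(0.95, 5), 1.21)
  expect_false(2 %in% maintained_beneficials(fake_lod(w5))$step)
  # a trailing sub-reference run never recovers, so the step is lost
  wt <- c(1, 1.2, 0.95, 0.95)
  expect_false(2 %in% maintained_beneficials(fake_lod(wt))$step)
  # beneficial steps that do not set a new maximum are never maintained
  wnm <- c(1, 1.3, 0.9, 1.1, 1.4)
  mb <- maintained_beneficials(fake_lod(wnm))
  expect_equal(mb$step, c(2, 5))
  expect_error(maintained_beneficials(fake_lod(1)), "at least 2")
})

test_that("maintained steps are a subset of new-maximum beneficial steps", {
  set.seed(21)
  for (i in 1:25) {
    w <- cumprod(c(1, exp(rnorm(30, 0.01, 0.08))))
    mb <- maintained_beneficials(fake_lod(w))
    if (nrow(mb) == 0) next
    for (s in mb$step) {
      expect_gt(w[s], w[s - 1])
      expect_gt(w[s], max(w[1:(s - 1)]))
    }
  }
})

test_that("equal-fitness cohorts take the last genotype and the >20-lineage rule", {
  # one lineage hits fitness 1.5 three times: the last index is selected
  lods <- list(fake_lod(c(1, 1.5, 1.2, 1.5, 1.5, 1.7)))
  cohort <- suppressMessages(
    equal_fitness_cohorts(lods, lods, min_lineages = 0))
  m <- cohort$members[cohort$members$treatment == "small", ]
  expect_equal(m$lod_index[m$fitness == 1.5], 5)
  # 21 vs 21 lineages qualifies; 20 vs 21 does not
  mk <- function(n) replicate(n, fake_lod(c(1, 2)), simplify = FALSE)
  both21 <- equal_fitness_cohorts(mk(21), mk(21))
  expect_equal(both21$values$fitness, c(1, 2))
  short <- suppressMessages(equal_fitness_cohorts(mk(20), mk(21)))
  expect_equal(nrow(short$values), 0)
  # disjoint fitness supports: empty result with a diagnostic, not an error
  expect_message(
    out <- equal_fitness_cohorts(mk(25),
                                 replicate(25, fake_lod(c(3, 4)), simplify = FALSE)),
    "no fitness value")
  expect_equal(nrow(out$values), 0)
  # members of one cohort always share the (binned) fitness value
  expect_true(all(tapply(both21$members$fitness, both21$members$fitness_key,
                         function(v) length(unique(v)) == 1)))
})

test_that("a modifier toggle converts its targets' deleterious states to lethal", {
  land <- modifier_landscape()
  g_on <- land$wild; g_on[1] <- 2L
  lod <- fake_lod(c(1, 1.04), genomes = rbind(land$wild, g_on))
  sig <- epistatic_signatures(lod, land)
  expect_equal(nrow(sig), 1)
  k <- 2; A <- land$A; L <- land$L
  # exact counts from the modifier semantics: the k target sites' (A-1)
  # deleterious states each become lethal; the toggle's own A-1 reversal
  # states (losing the small benefit) are the only deleterious neighbours
  # left afterwards
  expect_equal(sig$pre_deleterious, k * (A - 1) / ((A - 1) * L))
  expect_equal(sig$post_deleterious, (A - 1) / ((A - 1) * L))
  expect_equal(sig$post_lethal - sig$pre_lethal, k * (A - 1) / ((A - 1) * L))
  expect_equal(sig$drop_deleterious, (k - 1) * (A - 1) / ((A - 1) * L))
  expect_equal(sig$share_small, 1)
  expect_true(sig$flag_relative)   # 50 percent relative drop (boundary)
  expect_true(sig$flag_absolute)   # 0.25 absolute drop
})

test_that("signature flags follow the 50 percent and 0.1 thresholds", {
  # a weak modifier targeting only a neutral site: the toggle adds its own
  # reversal states to the deleterious neighbourhood, so the deleterious
  # likelihood rises and neither flag fires
  f <- matrix(1, 4, 5)
  f[1, 2] <- 1.04
  f[2, 2:5] <- 0.97
  land <- synthetic_landscape(factors = f,
                              modifiers = list(list(site = 1L, on_state = 2L,
                                                    targets = 3L, benefit = 0.04)))
  g_on <- land$wild; g_on[1] <- 2L
  sig <- epistatic_signatures(fake_lod(c(1, 1.04), rbind(land$wild, g_on)), land)
  expect_equal(sig$drop_deleterious, -0.25)
  expect_false(sig$flag_relative)
  expect_false(sig$flag_absolute)
  # an unchanged-DFE LOD yields zero flags
  lod <- fake_lod(c(1, 1), rbind(land$wild, land$wild))
  expect_equal(nrow(epistatic_signatures(lod, land)), 0)
})

test_that("treatment comparison reproduces closed-form U statistics", {
  cmp <- compare_treatments(rep(1:4, 2), rep(1:4, 2), alternative = "less")
  expect_equal(cmp$U, 8^2 / 2)
  cmp <- compare_treatments(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(cmp$U, 0)
  expect_lt(cmp$p_value, 0.05)
  cmp2 <- compare_treatments(c(4, 5, 6), c(1, 2, 3), alternative = "greater")
  expect_equal(cmp2$U, 9)
  expect_equal(compare_treatments(c(1, 2, 3), c(4, 5, 6),
                                  alternative = "greater")$p_value,
               1 - cmp2$p_value, tolerance = 0.2)
})

test_that("Spearman correlation handles monotone and constant input", {
  expect_equal(spearman_rho(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_rho(1:10, -(1:10)^2)$rho, -1)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("cohort comparison applies the Bonferroni correction", {
  set.seed(2)
  lods_small <- replicate(25, fake_lod(c(1, 2)), simplify = FALSE)
  lods_large <- replicate(25, fake_lod(c(1, 2)), simplify = FALSE)
  cohorts <- equal_fitness_cohorts(lods_small, lods_large)
  cohorts$members$f_deleterious_small <-
    ifelse(cohorts$members$treatment == "small",
           runif(nrow(cohorts$members), 0, 0.1),
           runif(nrow(cohorts$members), 0.2, 0.3))
  out <- cohort_comparison(cohorts)
  expect_equal(nrow(out), 2)
  expect_equal(out$p_bonferroni, pmin(1, out$p_value * nrow(out)))
  expect_true(all(out$significant))
})
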