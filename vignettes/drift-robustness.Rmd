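---
title: "Drift robustness: model, simulator, and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drift robustness: model, simulator, and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftscape)
```

## The question

Small populations experience strong genetic drift: deleterious mutations of
effect smaller than roughly $1/N$ fix almost as if neutral, so a genotype
whose mutational neighbourhood is rich in *small-effect* deleterious
mutations bleeds fitness under drift. Drift robustness is the hypothesis
that small populations preferentially evolve to fitness peaks whose viable
deleterious neighbours are *large-effect* (and hence still purged even at
small $N$) or outright lethal — even when such peaks are lower than the
alternative. This package implements the three layers needed to study the
phenomenon end to end: an exact origin-fixation Markov model on a minimal
two-peak landscape, a forward-time Wright–Fisher simulator on a synthetic
multi-class fitness landscape, and the DFE/line-of-descent analysis
pipeline that connects the two.

## The origin-fixation model

The minimal landscape has four genotypes: the wild type at fitness
$w_1 = 1$; a drift-fragile peak reached through an intermediate step,
$w_2 = 1 + s/2$, $w_3 = 1 + s$; and a drift-robust peak $w_4 = 1 + s -
\epsilon$ reached in a single large step ($0 < \epsilon < s$). The extended
model subdivides the fragile ascent into $n$ steps of benefit $s/n$. In the
weak-mutation strong-selection regime the population is monomorphic and
evolution is a Markov chain whose per-generation transition probabilities
are $u_{ij}\pi_{ij}$ — mutation supply times fixation probability — with
the complementary diagonal. Mutational edges exist only along the fragile
ladder and between the wild type and the robust peak; the two branches
communicate only through the wild type, so the chain is a tree and hence
reversible.

Beneficial rates follow an exponential distribution of effects:
$p_b(x) = u_b\,\mu\,\rho(x)$ with $\rho(x) = e^{-x/\bar s}/\bar s$, so each
fragile step gets $p_b(s/n)$, the robust step gets $p_b(s)$, and every
downhill edge gets the overall rate $\mu$. Because $\mu$ multiplies every
beneficial rate, it cancels from the flux ratio
$M = (u_\text{fragile}/\mu)^n\,(\mu/u_\text{robust}) = \kappa^{n-1}$ with
$\kappa = u_b/\bar s < 1$. The stationary occupancy ratio of the two peak
tops is then

$$R(N) = M\,e^{2\epsilon(N-1)},$$

and setting $R = 1$ gives the critical population size

$$N_\text{crit} = 1 + (n-1)\,\frac{\log \kappa^{-1}}{2\epsilon}.$$

Below $N_\text{crit}$ the *lower*, drift-robust peak dominates the
stationary distribution; above it the higher, drift-fragile peak does.
$N_\text{crit}$ shrinks as the fitness deficit $\epsilon$ grows (robustness
is abandoned when it costs too much) and grows linearly in the number of
fragile steps $n - 1$.

```{r ncrit}
spec <- markov_landscape_spec(s = 0.1, epsilon = 0.05, n = 2,
                              u_b = 1e-3, s_bar = 0.1, mu = 0.01)
n_crit_closed(spec$kappa, spec$epsilon, spec$n)
n_crit_numeric(spec, "kimura")
```

### Fixation kernels and the Malthusian convention

Two kernels are provided. `kimura` is the diffusion approximation
$\pi(s_\text{eff}) = (1 - e^{-2 s_\text{eff}})/(1 - e^{-2N s_\text{eff}})$;
`sella_hirsh` is the exact Wright–Fisher form
$(1 - r^{-2})/(1 - r^{-2N})$ in the Wrightian fitness ratio
$r = 1 + s_\text{eff}$, which satisfies the detailed-balance property
$\pi_{ij}/\pi_{ji} = (w_j/w_i)^{2(N-1)}$. (Conventions for the exact form
differ in the literature; this package pins the variant by that ratio
property. Alternatives with other exponent conventions are untested.)

The chain assigns each edge its *additive* fitness increment as the
selection coefficient ($s/n$ per fragile step regardless of the background,
$s - \epsilon$ for the robust step) — the convention under which the
half-step ratio is exactly $e^{s(N-1)}$ and the closed forms above are
exact. For the exact kernel the increments are mapped to Wrightian ratios
as $r = e^{\Delta}$ (the standard Malthusian-to-Wrightian mapping). Under
that mapping the exact kernel's edge factors coincide with the diffusion
ones, which is precisely why the critical population size is identical for
both kernels: the intermediate steps' fixation probabilities cancel
telescopically either way. Had the increments been fed to the exact kernel
as raw Wrightian ratios, the two kernels' critical sizes would differ at
order $s$ — an inconsistency with the additive fitness ladder, not a
property of the model.

### Numerical choices

* **Stationary distribution.** Solved by Grassmann–Taksar–Heyman state
  reduction — a deterministic, subtraction-free direct solve of
  $x(T - I) = 0$. Unlike a generic linear solve, GTH retains componentwise
  *relative* accuracy when stationary masses span many orders of magnitude,
  which they do as soon as $2\epsilon N$ is a few tens. The result is
  validated against the residual $\lVert xT - x\rVert_\infty < 10^{-10}$
  and, in the test suite, against the reversibility product of the tree
  chain.
* **Critical-size root finding.** `n_crit_numeric()` brackets the root of
  $\log R(N)$ by doubling and calls `uniroot` (tolerance $10^{-6}$).
  $\log R$ is evaluated through the chain's detailed-balance product with
  log-space fixation probabilities, because at $N\!\cdot\!\Delta \gtrsim
  350$ the per-generation downhill probabilities underflow double
  precision; in the representable regime the product is identical to the
  eigenvector ratio (a tested property), so nothing is lost.
* **Neutral limit.** $\pi$ switches to the analytic limit $1/N$ below
  $|s_\text{eff}| < 10^{-12}$ rather than evaluating the $0/0$ form.
* **Real-valued $N$** is allowed throughout the analytic layer (the closed
  forms are continuous in $N$); the simulators round to integers.

### The Monte-Carlo cross-check

`simulate_origin_fixation()` samples the chain directly and serves as an
independent stochastic oracle for the eigenvector solution. Time-in-state
counts of a sticky chain are heavily autocorrelated, so `occupancy_gof()`
thins the trajectory (default every 1000th state) before the chi-squared
test; for the fast-mixing parameter sets used in the tests the relaxation
time is 50–200 generations, so thinned draws are effectively independent
and the test is calibrated.

## The synthetic landscape

The forward experiments need a genotype–fitness map with the mutational
structure of a digital organism: genomes of $L = 50$ sites over an
$A = 26$-letter alphabet, about one third lethal point mutations,
coexisting small-effect ($<5\%$) and large-effect ($\geq 5\%$) deleterious
classes, exactly-neutral mutations, and epistatic loci. Fitness is
multiplicative over per-site factors, module factors and modifier factors;
0 encodes non-viable; the wild type is exactly 1. Five site classes:

* **Lethal core** (17 sites): any non-wild state is lethal. Fixes the
  lethal fraction of every genotype's DFE near 1/3.
* **Additive sites** (15): each has 5 beneficial states carrying a per-site
  benefit $b \sim U(0.001, 0.02)$, 5 exactly neutral states, 3 small-effect
  and 12 large-effect deleterious states. The key design point: *fragility
  is acquired by climbing*. An unclimbed site's deleterious neighbours are
  mostly large-effect, but once a beneficial state is fixed, falling back
  to the wild or a neutral state loses $b$ — a small-effect deleterious
  mutation. A fully climbed genotype is a drift-fragile peak for exactly
  the reason the theory posits: it was reached by small steps whose
  reversals are small-effect deleterious.
* **Modules** (3 of 3 sites): neutral member target states; completing all
  members multiplies fitness by $1 + S_\text{mod}$, $S_\text{mod} \sim
  U(0.08, 0.15)$. Single losses from a completed module are large-effect —
  the drift-robust kind of benefit.
* **Neutral sites** (6): all states factor 1. Neutrality is exact by
  construction, so the classifier's neutrality tolerance ($10^{-12}$) is
  numerical, not biological.
* **Modifiers** (3, 4 target sites each): switching one on multiplies
  fitness by $1 + b_\text{mod}$ and converts every mutation at its target
  sites to lethal — the epistatic mechanism that buys robustness by trading
  small-effect deleterious neighbours for lethal ones. A genome with a
  modifier on and a non-wild target is non-viable, so a modifier is
  permanently blocked once one of its targets is climbed.

The benefit ranges are deliberate. Additive benefits straddle the drift
barrier of the small treatment ($2Nb$ spans $0.4$–$4$ at $N = 100$) while
sitting far above it for the large treatment ($8$–$80$ at $N = 2000$): large
populations hold every climbed site, small populations cannot, and the DFE
contrast between the treatments follows. The modifier's direct benefit is
small ($b_\text{mod} = 0.008$) because its payoff is drift-conditional —
an early calibration with a large direct benefit ($0.06$) made modifiers
win the initial clonal-interference race in *large* populations, which
locks large populations onto robust peaks and inverts the phenomenon.
These defaults were fixed from that design reasoning before the
end-to-end suite was written and have not been revisited since.

Two presets anchor the analysis tests: `drift_robust` (modules + modifiers
only; its peak genotype has *no* viable deleterious mutation below 5%) and
`drift_fragile` (additive sites only, with effects capped so every viable
deleterious mutation of its peak stays below 5%).

What the generator does *not* emulate: self-replication mechanics,
instruction execution, or any genotype–phenotype map — fitness is assigned,
not computed from behaviour. Passing tests therefore show that the
*population-genetic* mechanism operates as the theory predicts on a
landscape with this class structure; they do not show that any particular
organism's landscape has this structure.

## The forward simulator

`evolve_population()` is a discrete-generation Wright–Fisher process:
parents are sampled with replacement proportional to fitness (fitness-0
individuals occupy slots but never reproduce, mirroring a world where
non-viable organisms still fill cells); each offspring mutates with
probability $U = 0.1$ at one uniform site to a uniform non-identical state
— at most one mutation per offspring, exactly. The third treatment reverts
any offspring whose fitness falls below its parent's
(`revert_deleterious`), so no deleterious mutation ever enters the
population. Wright–Fisher generations replace the original overlapping
update scheduling of digital-evolution platforms; population sizes and
generation counts map one to one, and the drift–selection balance the
theory addresses is preserved. How generation counting should interact
with fitness-0 individuals in an overlapping-update world is ambiguous;
here generations are defined purely by the synchronous update.

The genealogy records every genotype with its parent pointer, mutation and
birth generation, pruned every 100 generations to ancestors of the living
(a memory bound for $10^4$–$10^5$-generation runs). `extract_lod()` walks
parent pointers from the most abundant final genotype back to the
ancestor: the line of descent, the lineage's fossil record. Ties for most
abundant break by earliest birth, then lowest id. Genotype identity is by
genealogy record (mutation event), not by sequence: two independent
origins of the same sequence are distinct records, as in digital-evolution
genealogies.

The simulator's fitness evaluation and inner loop are in C++ (Rcpp); a
$N = 2000$, $2\times10^4$-generation run takes seconds, and the whole
scaled-down study minutes. Randomness comes from R's RNG, so every run is
reproducible from its config seed; per-replicate seeds derive from a
master seed by a fixed hash (`derive_seed()`), making replicates
independently re-runnable.

## Study design and scale

The default study is a scaled-down version of the three-experiment design:
30 replicates per treatment (small $N = 100$, large $N = 2000$, and small
with deleterious mutations reverted), $2\times10^4$ generations, followed
by the drift-robustness test — every evolved genotype founds 10 populations
of 50 individuals for $10^3$ generations, and its median relative fitness
after the test measures its decline under drift. These sizes keep the full
study inside minutes of CPU while leaving the drift barrier
well-separated between treatments; the full-scale design (100 replicates,
$N = 10^4$, $10^5$ generations) runs through the same functions by changing
the manifest. The headline contrasts this package reproduces are
sign-level: lower small-effect-deleterious likelihood in small-population
genotypes, smaller decline in the drift test, a positive rank correlation
between decline and small-effect-deleterious likelihood, and reversal of
all of it (plus higher final fitness) when deleterious mutations are
prevented. Exact medians depend on the landscape's genome mechanics and
are not reproduction targets.

## Analysis definitions

* **Classification.** $s = w_m/w_0 - 1$ over all $(A-1)L$ point mutants;
  lethal means $w_m = 0$ exactly; $|s| < 10^{-12}$ is neutral; $s \le
  -0.05$ is large-effect deleterious (the boundary itself is large-effect,
  following the "greater than or equal to 5%" reading); $-0.05 < s < 0$
  small-effect; $s > 0$ beneficial.
* **Maintained beneficial mutations.** A beneficial LOD step is maintained
  if it attains a new fitness maximum and fitness never falls below the
  value immediately before the step except transiently — every
  sub-reference run must be shorter than five consecutive genotypes *and*
  recover; a trailing run that never recovers disqualifies the step.
  "The previous fitness value" is read as $w_{i-1}$, the fitness
  immediately before the step (the sentence's referent); reading it as the
  running maximum is available via `relative_to = "running_max"` but not
  endorsed.
* **Equal-fitness cohorts.** Per lineage and fitness value, the *last*
  genotype at that value; only values with more than 20 lineages in both
  treatments are kept. Matching is exact by default with an optional
  significant-digit binning (`bin_digits`), needed because this landscape's
  fitness values are continuous products rather than ratios of integers.
* **Epistatic signatures.** For each maintained step, the viable-deleterious
  likelihood before and after; flags at $\geq 50\%$ relative and $\geq 0.1$
  absolute reduction; the share of the reduction attributable to the
  small-effect class. Note that the toggled locus's own reversal states
  count as deleterious after the step (they lose the step's benefit), so an
  idealised "targets-only" count overstates the net deleterious drop by one
  site's worth.
* **Tests.** One-tailed Mann–Whitney U (normal approximation, ties-safe)
  with directions fixed by the stated hypotheses; Spearman correlations;
  Bonferroni correction across the cohort family.

## Known limitations

* The origin-fixation layer covers the two-peak landscape family (any
  $n \geq 2$), not arbitrary genotype networks; `stationary_distribution()`
  accepts any row-stochastic matrix, but the critical-size machinery
  assumes the tree topology.
* The eigenvector solve is accurate while occupancies are representable in
  doubles; beyond that regime only the log-space ratio (and hence
  `n_crit_numeric`) is meaningful.
* The forward simulator is asexual, well-mixed, constant-$N$, with a fixed
  mutation rate — deliberately so, matching the study design; none of
  recombination, spatial structure or mutation-rate evolution is modelled.
* Small-sample caveat: with 30 replicates per treatment the qualitative
  contrasts are strongly significant, but per-cohort equal-fitness
  comparisons can be underpowered; the cohort machinery reports counts so
  users can judge.
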