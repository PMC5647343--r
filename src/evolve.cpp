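#include "landscape.h"
#include <algorithm>
using namespace Rcpp;

// Forward-time Wright-Fisher simulator with genealogy tracking.
//
// Discrete generations; N parents sampled with replacement proportional to
// fitness; each offspring carries at most one point mutation (Bernoulli(U),
// then uniform site, uniform non-identical state). Non-viable genotypes
// (fitness 0) occupy slots but never reproduce. Optional revert_deleterious:
// a mutant offspring whose fitness is below its parent's reverts to the
// parent genome. Genealogy is pruned periodically to ancestors of the living.

struct GenotypeStore {
  std::vector<double> id;       // stable original id (1-based, double: > 2^31 safe)
  std::vector<int> parent;      // index into store, -1 for founders
  std::vector<int> birth;
  std::vector<int> msite, mfrom, mto; // 1-based, 0 = none (founder)
  std::vector<double> fit;
  std::vector<std::vector<uint8_t> > genome;
  double next_id = 1;

  int add(int par, int b, int site, int from, int to, double w,
          std::vector<uint8_t> &&g) {
    id.push_back(next_id++);
    parent.push_back(par);
    birth.push_back(b);
    msite.push_back(site);
    mfrom.push_back(from);
    mto.push_back(to);
    fit.push_back(w);
    genome.push_back(std::move(g));
    return (int)id.size() - 1;
  }

  size_t size() const { return id.size(); }

  // Retain ancestors of `pop`; remap indices (store is topologically ordered:
  // parents precede children, preserved by in-order compaction).
  void prune(std::vector<int> &pop) {
    std::vector<char> keep(size(), 0);
    for (int i : pop) {
      int j = i;
      while (j >= 0 && !keep[j]) { keep[j] = 1; j = parent[j]; }
    }
    std::vector<int> remap(size(), -1);
    size_t w = 0;
    for (size_t i = 0; i < size(); ++i) {
      if (!keep[i]) continue;
      remap[i] = (int)w;
      if (w != i) {
        id[w] = id[i];
        parent[w] = parent[i];
        birth[w] = birth[i];
        msite[w] = msite[i];
        mfrom[w] = mfrom[i];
        mto[w] = mto[i];
        fit[w] = fit[i];
        genome[w] = std::move(genome[i]);
      }
      ++w;
    }
    id.resize(w); parent.resize(w); birth.resize(w); msite.resize(w);
    mfrom.resize(w); mto.resize(w); fit.resize(w); genome.resize(w);
    for (size_t i = 0; i < w; ++i)
      if (parent[i] >= 0) parent[i] = remap[parent[i]];
    for (int &i : pop) i = remap[i];
  }
};

// [[Rcpp::export(name = ".cpp_evolve")]]
List cpp_evolve(List land, IntegerMatrix founder_genomes, IntegerVector founder_counts,
                int N, double U, int generations, bool revert_deleterious,
                int prune_every) {
  ParsedLandscape pl = parse_landscape(land);
  if (founder_genomes.ncol() != pl.L) stop("founder genome length does not match landscape");
  GenotypeStore st;
  std::vector<int> pop;
  pop.reserve(N);
  for (int f = 0; f < founder_genomes.nrow(); ++f) {
    std::vector<uint8_t> g(pl.L);
    for (int l = 0; l < pl.L; ++l) {
      int s = founder_genomes(f, l);
      if (s < 1 || s > pl.A) stop("founder state outside landscape alphabet");
      g[l] = (uint8_t)(s - 1);
    }
    double w = pl.fitness(g.data());
    int idx = st.add(-1, 0, 0, 0, 0, w, std::move(g));
    for (int c = 0; c < founder_counts[f]; ++c) pop.push_back(idx);
  }
  if ((int)pop.size() != N) stop("founder counts must sum to N");

  std::vector<double> cum(N);
  std::vector<int> newpop(N);
  bool extinct = false;

  for (int gen = 1; gen <= generations && !extinct; ++gen) {
    double tot = 0.0;
    for (int i = 0; i < N; ++i) {
      tot += st.fit[pop[i]];
      cum[i] = tot;
    }
    if (tot <= 0.0) { extinct = true; break; }
    for (int k = 0; k < N; ++k) {
      double r = unif_rand() * tot;
      int lo = 0, hi = N - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (cum[mid] > r) hi = mid; else lo = mid + 1;
      }
      int pid = pop[lo];
      int child = pid;
      if (U > 0.0 && unif_rand() < U) {
        int site = (int)(unif_rand() * pl.L);
        if (site >= pl.L) site = pl.L - 1;
        int cur = st.genome[pid][site];
        int a = (int)(unif_rand() * (pl.A - 1));
        if (a >= pl.A - 1) a = pl.A - 2;
        if (a >= cur) ++a;
        std::vector<uint8_t> g = st.genome[pid];
        g[site] = (uint8_t)a;
        double w = pl.fitness(g.data());
        if (revert_deleterious && w < st.fit[pid]) {
          child = pid; // mutant prevented from entering the population
        } else {
          child = st.add(pid, gen, site + 1, cur + 1, a + 1, w, std::move(g));
        }
      }
      newpop[k] = child;
    }
    std::swap(pop, newpop);
    if (prune_every > 0 && gen % prune_every == 0) st.prune(pop);
  }

  st.prune(pop);
  size_t n = st.size();
  NumericVector id(n), fit(n);
  IntegerVector parent(n), birth(n), msite(n), mfrom(n), mto(n), nfinal(n);
  for (size_t i = 0; i < n; ++i) {
    id[i] = st.id[i];
    parent[i] = st.parent[i] >= 0 ? st.parent[i] + 1 : NA_INTEGER;
    birth[i] = st.birth[i];
    msite[i] = st.msite[i] > 0 ? st.msite[i] : NA_INTEGER;
    mfrom[i] = st.msite[i] > 0 ? st.mfrom[i] : NA_INTEGER;
    mto[i] = st.msite[i] > 0 ? st.mto[i] : NA_INTEGER;
    fit[i] = st.fit[i];
    nfinal[i] = 0;
  }
  for (int i : pop) nfinal[i]++;
  IntegerMatrix genomes(n, pl.L);
  for (size_t i = 0; i < n; ++i)
    for (int l = 0; l < pl.L; ++l) genomes(i, l) = st.genome[i][l] + 1;
  IntegerVector popv(pop.size());
  for (size_t i = 0; i < pop.size(); ++i) popv[i] = pop[i] + 1;
  return List::create(
    _["genotypes"] = DataFrame::create(
      _["id"] = id, _["parent"] = parent, _["birth"] = birth,
      _["site"] = msite, _["from"] = mfrom, _["to"] = mto,
      _["fitness"] = fit, _["n_final"] = nfinal),
    _["genomes"] = genomes,
    _["population"] = popv,
    _["extinct"] = extinct);
}

// Monte-Carlo sampler of the origin-fixation chain: categorical sampling of
// rows of a stochastic matrix.
// [[Rcpp::export(name = ".cpp_chain_sample")]]
List cpp_chain_sample(NumericMatrix T, int steps, int burn_in, int init) {
  int k = T.nrow();
  if (T.ncol() != k) stop("transition matrix must be square");
  std::vector<double> cum((size_t)k * k);
  for (int i = 0; i < k; ++i) {
    double t = 0.0;
    for (int j = 0; j < k; ++j) {
      t += T(i, j);
      cum[(size_t)i * k + j] = t;
    }
    if (std::abs(t - 1.0) > 1e-9) stop("transition matrix rows must sum to 1");
  }
  IntegerVector states(steps);
  IntegerVector occ(k);
  int s = init - 1;
  for (int t = 0; t < steps; ++t) {
    double r = unif_rand();
    const double *row = &cum[(size_t)s * k];
    int j = 0;
    while (j < k - 1 && row[j] <= r) ++j;
    s = j;
    states[t] = s + 1;
    if (t >= burn_in) occ[s]++;
  }
  return List::create(_["states"] = states, _["occupancy"] = occ);
}
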