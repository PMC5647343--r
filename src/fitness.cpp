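#include "landscape.h"
using namespace Rcpp;

ParsedLandscape parse_landscape(const List &land) {
  ParsedLandscape pl;
  pl.L = as<int>(land["L"]);
  pl.A = as<int>(land["A"]);
  IntegerVector wild = land["wild"];
  pl.wild.resize(pl.L);
  for (int l = 0; l < pl.L; ++l) pl.wild[l] = wild[l] - 1;
  NumericMatrix fac = land["factors"];
  if (fac.nrow() != pl.L || fac.ncol() != pl.A)
    stop("factor table does not match L x A");
  pl.factors.assign(fac.begin(), fac.end());
  List mods = land["modules"];
  for (int i = 0; i < mods.size(); ++i) {
    List m = mods[i];
    ParsedLandscape::Module pm;
    IntegerVector sites = m["sites"], targets = m["targets"];
    for (int k = 0; k < sites.size(); ++k) {
      pm.sites.push_back(sites[k] - 1);
      pm.targets.push_back(targets[k] - 1);
    }
    pm.benefit = as<double>(m["benefit"]);
    pl.modules.push_back(pm);
  }
  List mfs = land["modifiers"];
  for (int i = 0; i < mfs.size(); ++i) {
    List m = mfs[i];
    ParsedLandscape::Modifier pm;
    pm.site = as<int>(m["site"]) - 1;
    pm.on_state = as<int>(m["on_state"]) - 1;
    IntegerVector targets = m["targets"];
    for (int k = 0; k < targets.size(); ++k) pm.targets.push_back(targets[k] - 1);
    pl.modifiers.push_back(pm);
  }
  return pl;
}

static std::vector<uint8_t> as_states(const IntegerVector &genome, const ParsedLandscape &pl) {
  if (genome.size() != pl.L) stop("genome length does not match landscape");
  std::vector<uint8_t> g(pl.L);
  for (int l = 0; l < pl.L; ++l) {
    int s = genome[l];
    if (s < 1 || s > pl.A) stop("genome state outside landscape alphabet");
    g[l] = (uint8_t)(s - 1);
  }
  return g;
}

// [[Rcpp::export(name = ".cpp_fitness")]]
double cpp_fitness(List land, IntegerVector genome) {
  ParsedLandscape pl = parse_landscape(land);
  std::vector<uint8_t> g = as_states(genome, pl);
  return pl.fitness(g.data());
}

// Enumerate all (A-1)*L single point mutants of `genome`.
// [[Rcpp::export(name = ".cpp_enumerate_mutants")]]
DataFrame cpp_enumerate_mutants(List land, IntegerVector genome) {
  ParsedLandscape pl = parse_landscape(land);
  std::vector<uint8_t> g = as_states(genome, pl);
  int n = (pl.A - 1) * pl.L;
  IntegerVector site(n), from(n), to(n);
  NumericVector w(n);
  int i = 0;
  for (int l = 0; l < pl.L; ++l) {
    uint8_t orig = g[l];
    for (int a = 0; a < pl.A; ++a) {
      if (a == orig) continue;
      g[l] = (uint8_t)a;
      site[i] = l + 1;
      from[i] = orig + 1;
      to[i] = a + 1;
      w[i] = pl.fitness(g.data());
      ++i;
    }
    g[l] = orig;
  }
  return DataFrame::create(_["site"] = site, _["from"] = from, _["to"] = to,
                           _["w_mutant"] = w);
}
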