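#ifndef DRIFTSCAPE_LANDSCAPE_H
#define DRIFTSCAPE_LANDSCAPE_H

#include <Rcpp.h>
#include <vector>
#include <cstdint>

// Parsed genotype->fitness map. States are 0-based internally.
struct ParsedLandscape {
  int L;
  int A;
  std::vector<int> wild;              // wild state per site
  std::vector<double> factors;        // L x A, column-major [site + L*state]
  struct Module {
    std::vector<int> sites;
    std::vector<int> targets;
    double benefit;
  };
  struct Modifier {
    int site;
    int on_state;
    std::vector<int> targets;
  };
  std::vector<Module> modules;
  std::vector<Modifier> modifiers;

  inline double factor(int site, int state) const {
    return factors[site + (size_t)L * state];
  }

  // Multiplicative fitness; 0 encodes non-viable.
  double fitness(const uint8_t *g) const {
    double w = 1.0;
    for (int l = 0; l < L; ++l) {
      double f = factor(l, g[l]);
      if (f == 0.0) return 0.0;
      w *= f;
    }
    for (const Modifier &m : modifiers) {
      if (g[m.site] == m.on_state) {
        for (int t : m.targets) {
          if (g[t] != wild[t]) return 0.0;
        }
      }
    }
    for (const Module &mod : modules) {
      bool complete = true;
      for (size_t k = 0; k < mod.sites.size(); ++k) {
        if (g[mod.sites[k]] != mod.targets[k]) { complete = false; break; }
      }
      if (complete) w *= 1.0 + mod.benefit;
    }
    return w;
  }
};

ParsedLandscape parse_landscape(const Rcpp::List &land);

#endif
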