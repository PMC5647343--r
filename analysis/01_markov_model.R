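#!/usr/bin/env Rscript
# Origin-fixation theory on the two-peak landscape: stationary occupancy of
# the drift-robust vs drift-fragile peak across population sizes, and the
# critical population size N_crit as a function of the robustness trade-off.
#
# Writes: results/markov/occupancy_vs_N.tsv, results/markov/ncrit_sweep.tsv

suppressPackageStartupMessages(library(driftscape))
out_dir <- "results/markov"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

spec <- markov_landscape_spec(s = 0.1, epsilon = 0.05, n = 2,
                              u_b = 1e-3, s_bar = 0.1, mu = 0.01)
cat("Minimal two-peak model: kappa =", spec$kappa, "\n")
ncrit <- n_crit_closed(spec$kappa, spec$epsilon, spec$n)
cat("Closed-form critical population size:", round(ncrit, 4), "\n")

occ <- do.call(rbind, lapply(c(2, 5, 10, 20, 30, 40, round(ncrit, 2), 60, 100, 200),
  function(N) {
    sol <- solve_markov(spec, fixation_model("kimura", N))
    data.frame(N = N, t(sol$x_star), R = sol$R)
}))
write.table(occ, file.path(out_dir, "occupancy_vs_N.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nOccupancy of the fragile top vs robust peak flips at N_crit:\n")
print(occ[, c("N", "fragile_2", "robust", "R")], digits = 4)

# N_crit across the fitness deficit of the robust peak, number of fragile
# steps, and beneficial-mutation supply, for both fixation kernels
sweep <- ncrit_sweep(kappa = 10^c(-4, -3, -2, -1),
                     epsilon = seq(0.01, 0.3, length.out = 30),
                     n = c(2L, 3L, 5L, 10L),
                     kinds = c("kimura", "sella_hirsh"))
write.table(sweep, file.path(out_dir, "ncrit_sweep.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
dev <- max(abs(sweep$ncrit_numeric / sweep$ncrit_closed - 1))
cat(sprintf("\nN_crit sweep over %d grid points: max |numeric/closed - 1| = %.2e\n",
            nrow(sweep), dev))
cat("Small populations prefer the drift-robust peak below N_crit;",
    "N_crit shrinks as the fitness deficit epsilon grows and grows with the",
    "number of fragile steps n.\n")
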