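#!/usr/bin/env Rscript
# Step 4 — condition-specific stability in the three sample subsets.
#
# The best reference genes depend on the experimental conditions, so the
# survey is repeated inside each subset (organ/tissue, abiotic stress,
# biotic stress). Relative quantities are re-derived within each subset
# (per-gene minimum Cp over the subset's observations); the stability
# statistics themselves are invariant to that choice.

suppressPackageStartupMessages(library(refstab))

ds <- read_cp_table("results/data/cp.csv")
meta <- read_sample_metadata("results/data/meta.csv")

for (s in c("organ_tissue", "abiotic", "biotic")) {
  res <- suppressMessages(suppressWarnings(
    run_stability(ds, meta, subset = s, cutoff = 0.15,
                  out_dir = file.path("results", s))))
  cat(sprintf("== subset %s (%d samples, %d observations) ==\n",
              s, length(samples_in_subset(meta, s)), ncol(res$q)))
  cat(sprintf("  geNorm best pair: %s (M = %.3f); least stable: %s\n",
              paste(res$genorm$best_pair, collapse = " / "),
              res$summary$genorm$best_pair_m,
              res$summary$genorm$least_stable))
  if (res$genorm$satisfiable) {
    cat(sprintf("  optimal gene number: %d\n", res$genorm$n_optimal))
  } else {
    cat(sprintf("  no V < %.2f; fall back to the three most stable genes\n",
                res$genorm$cutoff))
  }
  cat(sprintf("  NormFinder best gene: %s (rho = %.3f); least stable: %s\n\n",
              res$summary$normfinder$best_gene,
              res$summary$normfinder$best_stability,
              res$summary$normfinder$least_stable))
}
cat("wrote results/{organ_tissue,abiotic,biotic}/...\n")
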