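#!/usr/bin/env Rscript
# Step 1 — generate the synthetic reference-gene survey.
#
# The generator emulates a 15-candidate-gene qRT-PCR survey over 20 samples
# in three overlapping subsets (10 organ/tissue, 8 abiotic-stress, 6
# biotic-stress; the normal root and leaf samples double as stress
# controls), 3 biological x 2 technical replicates. Two genes (YLS8, PTB)
# are stable by construction; the rest carry biological noise >= 0.6 log2
# units and/or condition shifts >= 1 cycle. Ground truth is written next to
# the data so later steps can score themselves.

suppressPackageStartupMessages(library(refstab))

out_dir <- "results/data"
sim <- run_simulate(default_sim_config(), seed = 20140301, out_dir = out_dir)

report <- validate_dataset(sim$dataset, sim$metadata)
print(sim$dataset)
print(report)
write_validation_report(report, file.path(out_dir, "validation.json"))

cat("\nSubset sizes:\n")
for (s in c("organ_tissue", "abiotic", "biotic")) {
  cat(sprintf("  %-13s %2d samples\n", s,
              length(samples_in_subset(sim$metadata, s))))
}
cat("\nPer-gene mean Cp across all samples:\n")
mean_cp <- sort(apply(sim$dataset$cp, 1, mean))
print(round(mean_cp, 1))
cat("\nwrote", file.path(out_dir, c("cp.csv", "meta.csv", "truth.json")), "\n")
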