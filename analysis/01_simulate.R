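#!/usr/bin/env Rscript
# Step 1 — simulate the study's methylation workspace.
#
# Builds the default synthetic study: 200 CpG-island probe clusters with
# planted epigenotype classes, beta matrices for 4 androgenetic moles,
# 5 NLRP7-mutated moles, 7 normal placentas (3 first trimester + 4 term),
# 4 somatic tissues and 1 sperm sample, detection p-values, bisulfite
# clone panels for the maternal DMRs, and the ground-truth tables every
# later step scores itself against. All files are plain text under
# results/workspace/.

suppressPackageStartupMessages(library(moleimprint))

seed <- 20151106L
cfg <- sim_config(seed = seed)
sim <- simulate_workspace(cfg)
write_workspace(sim, "results/workspace")

cat("Simulated", nrow(sim$dataset$beta), "probes in", cfg$n_islands,
    "islands x", ncol(sim$dataset$beta), "samples (seed", seed, ")\n")
cat("Planted classes:\n")
print(table(sim$truth$class))
cat("Imprint-retention events (sample x maternal DMR):",
    nrow(sim$retained), "\n")
cat("Workspace written to results/workspace/\n")
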