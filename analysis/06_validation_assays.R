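#!/usr/bin/env Rscript
# Step 6 — orthogonal validation assays.
#
# Interprets the simulated bisulfite clone panels for the maternal DMRs
# (expecting allele-anchored bimodal patterns), demonstrates the
# methylation-sensitive HpaII genotyping logic on the canonical cases, and
# flags mole outliers against a placenta control panel the way
# pyrosequencing panels are read.

suppressPackageStartupMessages(library(moleimprint))

clonesets <- read_clonesets("results/workspace/clonesets.tsv",
                            conversion_error = 0.02)
clone_calls <- lapply(clonesets, call_clone_methylation)
tab <- table(vapply(clone_calls, `[[`, character(1), "call"))
cat("Bisulfite clone panels:", length(clonesets), "regions\n")
print(tab)

## HpaII methylation-sensitive genotyping, canonical informative case:
## heterozygous A/G, maternal allele G methylated -> digestion leaves G/G
assay <- simulate_hpa2(c("A", "G"), c(FALSE, TRUE), digestion_efficiency = 1,
                       maternal = c("G", "G"), paternal = c("A", "A"))
res <- call_hpa2(assay)
cat("HpaII het A/G with methylated G:", res$call,
    "- methylated allele", res$methylated_allele,
    "- origin", res$parental_origin, "\n")

## pyrosequencing-style outlier call: a mole with lost methylation against
## a 15-placenta control panel
ws <- "results/qc_dataset"
dataset <- read_dataset(file.path(ws, "manifest.tsv"),
                        file.path(ws, "beta.tsv"),
                        file.path(ws, "detection_p.tsv"),
                        file.path(ws, "samplesheet.csv"))
truth <- read.delim("results/workspace/ground_truth.tsv",
                    stringsAsFactors = FALSE)
mat_island <- truth$island_id[truth$class == "maternal_ubiquitous"][1]
probes <- strsplit(truth$probe_ids[truth$island_id == mat_island], ",")[[1]]
prof <- profile_region(dataset, probes, mat_island)
pl <- prof$per_sample_means[prof$sample_groups %in%
                              c("PLACENTA_FIRST", "PLACENTA_TERM")]
rhm <- prof$per_sample_means[prof$sample_groups == "NLRP7_RHM"][1]
py <- pyro_summary(pl, rhm)
cat(sprintf(
  "Pyro panel at %s: placenta median %.2f [%.2f, %.2f], RHM %.2f, outlier: %s\n",
  mat_island, py$median, py$p5, py$p95, rhm, py$outlier))

out <- data.frame(region_id = names(clone_calls),
                  call = vapply(clone_calls, `[[`, character(1), "call"),
                  methylated_allele = vapply(clone_calls, `[[`, character(1),
                                             "methylated_allele"))
write.table(out, "results/clone_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Clone calls written to results/clone_calls.tsv\n")
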