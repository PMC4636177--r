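#!/usr/bin/env Rscript
# Step 5 — epigenotype classification.
#
# Profiles each known imprinted DMR and each planted island across the
# sample groups and classifies its germline epigenotype: maternal germline
# DMR (ubiquitous or placenta-specific, split by the somatic group),
# paternal germline DMR, secondary DMR, or not imprinted. Mole samples
# retaining an imprint at an expected-LOM region are listed per region.

suppressPackageStartupMessages(library(moleimprint))

ws <- "results/qc_dataset"
dataset <- read_dataset(file.path(ws, "manifest.tsv"),
                        file.path(ws, "beta.tsv"),
                        file.path(ws, "detection_p.tsv"),
                        file.path(ws, "samplesheet.csv"))
known <- read_known_dmrs("results/workspace/known_dmrs.tsv")
truth <- read.delim("results/workspace/ground_truth.tsv",
                    stringsAsFactors = FALSE)

prof <- run_known_dmr_profile(dataset, known)
cat("Known-DMR profile:", nrow(prof$table), "DMRs,",
    sum(prof$table$n_probes), "probes mapped\n")
cat("  by category:\n")
print(table(prof$table$category, prof$table$label))
retained <- prof$table$retained_in[!is.na(prof$table$retained_in) &
                                     prof$table$retained_in != ""]
if (length(retained) > 0) {
  cat("Mole samples retaining an imprint:",
      paste(unique(unlist(strsplit(retained, ","))), collapse = ", "), "\n")
}

# all planted islands, scored against truth
region_probes <- lapply(strsplit(truth$probe_ids, ","), identity)
names(region_probes) <- truth$island_id
calls <- classify_regions(dataset, region_probes)
label_of <- c(maternal_ubiquitous = "MATERNAL_GDMR_UBIQUITOUS",
              maternal_placenta_specific = "MATERNAL_GDMR_PLACENTA_SPECIFIC",
              paternal = "PATERNAL_GDMR", secondary = "SECONDARY_DMR",
              not_imprinted_unmeth = "NOT_IMPRINTED_UNMETH",
              not_imprinted_meth = "NOT_IMPRINTED_METH")
acc <- mean(calls$label ==
              label_of[truth$class[match(calls$region_id, truth$island_id)]])
cat("Epigenotype accuracy over all", nrow(calls), "planted islands:",
    sprintf("%.3f", acc), "\n")

write.table(prof$table, "results/known_dmr_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(calls, "results/epigenotype_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(region_id = rownames(prof$matrix),
                       prof$matrix, check.names = FALSE),
            "results/known_dmr_heatmap_matrix.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Profiles, calls and heatmap matrix written under results/\n")
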