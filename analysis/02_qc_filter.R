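#!/usr/bin/env Rscript
# Step 2 — probe-level quality control.
#
# Reads the simulated workspace back through the text readers (so this
# step exercises the same path real GEO-style inputs would take), drops
# probes failing detection in any sample, probes with missing values and
# chrX probes, and records the filter report.

suppressPackageStartupMessages(library(moleimprint))

ws <- "results/workspace"
dataset <- read_dataset(file.path(ws, "manifest.tsv"),
                        file.path(ws, "beta.tsv"),
                        file.path(ws, "detection_p.tsv"),
                        file.path(ws, "samplesheet.csv"))
qc <- apply_qc(dataset)

cat("QC input:", qc$report$n_input, "probes\n")
cat("  failed detection (p > 0.01, any sample):",
    qc$report$n_fail_detection, "\n")
cat("  missing values:", qc$report$n_missing, "\n")
cat("  sex-chromosome probes:", qc$report$n_sex_chrom, "\n")
cat("Retained:", qc$report$n_retained, "probes\n")

dir.create("results", showWarnings = FALSE)
write_dataset(qc$dataset, "results/qc_dataset")
jsonlite::write_json(qc$report, "results/filter_report.json",
                     auto_unbox = TRUE, pretty = TRUE)
cat("Filtered dataset written to results/qc_dataset/\n")
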