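#' @importFrom utils read.delim read.csv write.table
#' @importFrom stats median quantile rnorm runif var setNames
NULL

#' Recognised sample groups
#'
#' The study design the screen assumes: androgenetic complete hydatidiform
#' moles (two paternal genomes, no maternal genome), biparental recurrent
#' moles from NLRP7-mutated mothers, normal placental biopsies (first
#' trimester and term), somatic tissues, sperm, and peripheral blood.
#'
#' @export
SAMPLE_GROUPS <- c("ANDRO_CHM", "NLRP7_RHM", "PLACENTA_FIRST", "PLACENTA_TERM",
                   "SOMATIC", "SPERM", "BLOOD")

PROBE_FEATURES <- c("promoter", "gene_body", "intergenic")

DMR_ORIGINS <- c("maternal", "paternal")
DMR_CATEGORIES <- c("ubiquitous", "placenta_specific")

#' Assemble a methylation dataset
#'
#' Bundles a probe manifest, a beta-value matrix, an optional detection
#' p-value matrix and a sample sheet into a single validated container, the
#' carrier used by every downstream stage. Probe order is the manifest
#' order; beta columns are reordered to the sample-sheet order.
#'
#' @param annotation data.frame with columns `probe_id`, `chrom`, `pos`
#'   (1-based bp), `cgi` (logical CpG-island membership) and `feature`
#'   (one of `promoter`, `gene_body`, `intergenic`). Extra columns are kept.
#' @param beta numeric matrix, probes x samples, values in \[0, 1\] or `NA`.
#'   Out-of-range values are rejected (never clipped), naming the offending
#'   probe.
#' @param detection_p optional numeric matrix of detection p-values with the
#'   same shape as `beta`.
#' @param samples data.frame with columns `sample_id` (unique, matching the
#'   beta column names as a set) and `group` (one of [SAMPLE_GROUPS]).
#' @return An object of class `MethylationDataset`: a list with elements
#'   `annotation`, `beta`, `detection_p`, `samples`.
#' @export
methylation_dataset <- function(annotation, beta, detection_p = NULL, samples) {
  stopifnot(is.data.frame(annotation), is.data.frame(samples))
  req <- c("probe_id", "chrom", "pos", "cgi", "feature")
  missing_cols <- setdiff(req, names(annotation))
  if (length(missing_cols) > 0) {
    stop("annotation is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(annotation$probe_id)) {
    stop("duplicated probe_id in annotation: ",
         annotation$probe_id[duplicated(annotation$probe_id)][1])
  }
  if (any(is.na(annotation$chrom) | annotation$chrom == "")) {
    stop("annotation contains empty chromosome values")
  }
  if (any(is.na(annotation$pos) | annotation$pos < 1)) {
    stop("annotation positions must be >= 1 (1-based coordinates)")
  }
  bad_feat <- setdiff(unique(annotation$feature), PROBE_FEATURES)
  if (length(bad_feat) > 0) {
    stop("unknown feature value(s): ", paste(bad_feat, collapse = ", "))
  }
  annotation$cgi <- as.logical(annotation$cgi)

  if (!all(c("sample_id", "group") %in% names(samples))) {
    stop("sample sheet needs columns sample_id, group")
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample_id in sample sheet")
  }
  bad_grp <- setdiff(unique(samples$group), SAMPLE_GROUPS)
  if (length(bad_grp) > 0) {
    stop("unknown sample group(s): ", paste(bad_grp, collapse = ", "))
  }

  beta <- as.matrix(beta)
  storage.mode(beta) <- "double"
  if (nrow(beta) != nrow(annotation)) {
    stop("beta has ", nrow(beta), " rows but annotation has ", nrow(annotation))
  }
  if (is.null(rownames(beta))) {
    rownames(beta) <- annotation$probe_id
  } else if (!identical(rownames(beta), annotation$probe_id)) {
    stop("beta row names do not match annotation probe order")
  }
  if (is.null(colnames(beta)) || !setequal(colnames(beta), samples$sample_id)) {
    stop("beta sample columns do not match the sample sheet")
  }
  beta <- beta[, samples$sample_id, drop = FALSE]
  .check_unit_range(beta, annotation$probe_id, "beta")

  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    storage.mode(detection_p) <- "double"
    if (!all(dim(detection_p) == dim(beta))) {
      stop("detection_p shape does not match beta")
    }
    if (!is.null(colnames(detection_p))) {
      detection_p <- detection_p[, samples$sample_id, drop = FALSE]
    }
    dimnames(detection_p) <- dimnames(beta)
    .check_unit_range(detection_p, annotation$probe_id, "detection_p")
  }

  structure(
    list(annotation = annotation, beta = beta, detection_p = detection_p,
         samples = samples),
    class = "MethylationDataset"
  )
}

.check_unit_range <- function(m, probe_ids, what) {
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(what, " value out of [0, 1] at probe ", probe_ids[bad[1, 1]],
         ", sample ", colnames(m)[bad[1, 2]], " (value ",
         m[bad[1, , drop = FALSE]], ")")
  }
  invisible(TRUE)
}

#' @export
print.MethylationDataset <- function(x, ...) {
  cat("MethylationDataset:", nrow(x$beta), "probes x", ncol(x$beta), "samples\n")
  cat("  detection p-values:", if (is.null(x$detection_p)) "absent" else "present", "\n")
  tab <- table(x$samples$group)
  cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.MethylationDataset <- function(x) dim(x$beta)

# Subset a dataset to a set of probes (logical mask or probe ids),
# preserving order. Internal.
#' @noRd
subset_probes <- function(dataset, keep) {
  if (is.character(keep)) keep <- dataset$annotation$probe_id %in% keep
  dataset$annotation <- dataset$annotation[keep, , drop = FALSE]
  rownames(dataset$annotation) <- NULL
  dataset$beta <- dataset$beta[keep, , drop = FALSE]
  if (!is.null(dataset$detection_p)) {
    dataset$detection_p <- dataset$detection_p[keep, , drop = FALSE]
  }
  dataset
}

samples_in_group <- function(dataset, groups) {
  dataset$samples$sample_id[dataset$samples$group %in% groups]
}

#' Read a methylation dataset from text files
#'
#' Reads a tab-separated probe manifest (`probe_id`, `chrom`, `pos`, `cgi`,
#' `feature`), a tab-separated beta matrix (first column probe id, remaining
#' columns samples; comment lines starting with `!` are skipped so a GEO
#' series-matrix body works after header stripping), an optional detection
#' p-value matrix in the same layout, and a CSV sample sheet
#' (`sample_id,group`).
#'
#' Probes with a missing chromosome or position are dropped with a logged
#' count (the screen is positional). Probes present in the manifest but
#' absent from the matrix (or vice versa) are dropped with a logged count;
#' retained probes keep manifest order. Beta values outside \[0, 1\] are a
#' fatal error naming the probe. Sample columns must match the sample sheet
#' exactly as a set.
#'
#' @param manifest_path,beta_path,samplesheet_path input file paths.
#' @param detection_path optional detection p-value matrix path.
#' @return A [methylation_dataset()].
#' @export
read_dataset <- function(manifest_path, beta_path, detection_path = NULL,
                         samplesheet_path) {
  manifest <- read.delim(manifest_path, stringsAsFactors = FALSE)
  req <- c("probe_id", "chrom", "pos", "cgi", "feature")
  if (!all(req %in% names(manifest))) {
    stop("manifest must have columns: ", paste(req, collapse = ", "))
  }
  bad_coord <- is.na(manifest$chrom) | manifest$chrom == "" | is.na(manifest$pos)
  if (any(bad_coord)) {
    message("Dropped ", sum(bad_coord), " probe(s) with missing coordinates")
    manifest <- manifest[!bad_coord, , drop = FALSE]
  }

  beta <- .read_matrix(beta_path)
  sheet <- read.csv(samplesheet_path, stringsAsFactors = FALSE)
  if (!setequal(colnames(beta), sheet$sample_id)) {
    stop("beta matrix sample columns do not match the sample sheet")
  }

  in_matrix <- manifest$probe_id %in% rownames(beta)
  if (any(!in_matrix)) {
    message("Dropped ", sum(!in_matrix),
            " manifest probe(s) absent from the beta matrix")
    manifest <- manifest[in_matrix, , drop = FALSE]
  }
  extra <- sum(!(rownames(beta) %in% manifest$probe_id))
  if (extra > 0) {
    message("Dropped ", extra, " matrix probe(s) absent from the manifest")
  }
  beta <- beta[manifest$probe_id, sheet$sample_id, drop = FALSE]

  detection <- NULL
  if (!is.null(detection_path)) {
    detection <- .read_matrix(detection_path)
    if (!all(manifest$probe_id %in% rownames(detection))) {
      stop("detection matrix is missing probes present in the beta matrix")
    }
    if (!setequal(colnames(detection), sheet$sample_id)) {
      stop("detection matrix sample columns do not match the sample sheet")
    }
    detection <- detection[manifest$probe_id, sheet$sample_id, drop = FALSE]
  }

  rownames(manifest) <- NULL
  methylation_dataset(manifest, beta, detection, sheet)
}

.read_matrix <- function(path) {
  df <- read.delim(path, comment.char = "!", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a methylation dataset as text files
#'
#' Writes `manifest.tsv`, `beta.tsv`, `detection_p.tsv` (if present) and
#' `samplesheet.csv` under `dir`, in the formats [read_dataset()] reads.
#' Numeric values are written with 17 significant digits so a read-back
#' reproduces the doubles bit-exactly.
#'
#' @param dataset a `MethylationDataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(manifest = file.path(dir, "manifest.tsv"),
             beta = file.path(dir, "beta.tsv"),
             samplesheet = file.path(dir, "samplesheet.csv"))
  ann <- dataset$annotation[, c("probe_id", "chrom", "pos", "cgi", "feature")]
  write.table(ann, paths[["manifest"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  .write_matrix(dataset$beta, paths[["beta"]])
  if (!is.null(dataset$detection_p)) {
    paths <- c(paths, detection = file.path(dir, "detection_p.tsv"))
    .write_matrix(dataset$detection_p, paths[["detection"]])
  }
  write.csv(dataset$samples[, c("sample_id", "group")], paths[["samplesheet"]],
            quote = FALSE, row.names = FALSE)
  invisible(paths)
}

.write_matrix <- function(m, path) {
  chr <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  chr[is.na(m)] <- "NA"
  df <- data.frame(probe_id = rownames(m), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("probe_id", colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a known imprinted-DMR table
#'
#' Tab-separated columns `name`, `chrom`, `start`, `end` (1-based inclusive),
#' `origin` (`maternal`/`paternal`) and `category`
#' (`ubiquitous`/`placenta_specific`).
#'
#' @param path input TSV path.
#' @return A validated data.frame.
#' @export
read_known_dmrs <- function(path) {
  known_dmr_table(read.delim(path, stringsAsFactors = FALSE))
}

#' Validate a known-DMR data.frame
#'
#' @param df data.frame with columns `name`, `chrom`, `start`, `end`,
#'   `origin`, `category`.
#' @return The validated data.frame.
#' @export
known_dmr_table <- function(df) {
  req <- c("name", "chrom", "start", "end", "origin", "category")
  if (!all(req %in% names(df))) {
    stop("known-DMR table must have columns: ", paste(req, collapse = ", "))
  }
  if (any(df$start > df$end)) stop("known DMR with start > end")
  bad <- setdiff(unique(df$origin), DMR_ORIGINS)
  if (length(bad) > 0) stop("unknown DMR origin: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$category), DMR_CATEGORIES)
  if (length(bad) > 0) stop("unknown DMR category: ", paste(bad, collapse = ", "))
  df
}

#' Map probes to known imprinted DMRs
#'
#' A probe maps to a DMR iff `start <= pos <= end` (1-based inclusive on
#' both sides, matching the manifest convention). A probe under several
#' overlapping DMRs is reported under each.
#'
#' @param dataset a `MethylationDataset`.
#' @param dmrs known-DMR data.frame (see [known_dmr_table()]).
#' @return Named list, one element per DMR `name`, each an ordered (by
#'   position, ties by probe id) character vector of probe ids; zero-probe
#'   DMRs get `character(0)`. An empty DMR table yields an empty list.
#' @export
map_probes_to_known_dmrs <- function(dataset, dmrs) {
  out <- setNames(rep(list(character(0)), nrow(dmrs)), dmrs$name)
  if (nrow(dmrs) == 0) return(out)
  ann <- dataset$annotation
  probe_gr <- GenomicRanges::GRanges(ann$chrom,
                                     IRanges::IRanges(ann$pos, width = 1))
  dmr_gr <- GenomicRanges::GRanges(dmrs$chrom,
                                   IRanges::IRanges(dmrs$start, dmrs$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(probe_gr, dmr_gr))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  for (j in unique(s)) {
    idx <- q[s == j]
    idx <- idx[order(ann$pos[idx], ann$probe_id[idx])]
    out[[j]] <- ann$probe_id[idx]
  }
  out
}

#' Write candidate regions as a BED file
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open, so `start_out = start - 1` and `end_out = end`. The BED name is
#' `direction:n_probes` and the score is `round(1000 * |mean_delta_beta|)`
#' capped at 1000. An empty region set produces a file with only the header
#' comment.
#'
#' @param regions region data.frame from [call_regions()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path) {
  header <- "# chrom\tstart\tend\tname\tscore  (BED: 0-based, half-open)"
  lines <- header
  if (!is.null(regions) && nrow(regions) > 0) {
    score <- pmin(1000L, as.integer(round(1000 * abs(regions$mean_delta_beta))))
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s:%d\t%d",
                              regions$chrom, regions$start - 1L, regions$end,
                              regions$direction, regions$n_probes, score))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a candidate-region table as TSV
#'
#' All region fields, with the probe-id list collapsed to a comma-separated
#' string.
#'
#' @param regions region data.frame from [call_regions()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_region_table <- function(regions, path) {
  df <- regions
  if (nrow(df) > 0) {
    df$probe_ids <- vapply(df$probe_ids, paste, character(1), collapse = ",")
  } else if ("probe_ids" %in% names(df)) {
    df$probe_ids <- character(0)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
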