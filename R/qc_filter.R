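# Probe-level quality filtering applied before any testing: drop probes
# failing detection, probes with missing values, and sex-chromosome probes.

.filter_report <- function(n_input, n_fail_detection = 0L, n_missing = 0L,
                           n_sex_chrom = 0L) {
  n_removed <- n_fail_detection + n_missing + n_sex_chrom
  list(n_input = as.integer(n_input),
       n_fail_detection = as.integer(n_fail_detection),
       n_missing = as.integer(n_missing),
       n_sex_chrom = as.integer(n_sex_chrom),
       n_retained = as.integer(n_input - n_removed))
}

.mask_detection <- function(dataset, p_max, max_fail_fraction) {
  rowMeans(dataset$detection_p > p_max) > max_fail_fraction
}

.mask_missing <- function(dataset) {
  rowSums(is.na(dataset$beta)) > 0
}

.mask_sex <- function(dataset, chroms) {
  dataset$annotation$chrom %in% chroms
}

#' Remove probes failing signal detection
#'
#' A probe is removed when its detection p-value exceeds `p_max` in more
#' than `max_fail_fraction` of samples. The default `max_fail_fraction = 0`
#' drops a probe that fails in any single sample — the strict reading,
#' consistent with also excluding probes lacking a signal value in one or
#' more samples. Probe order is preserved.
#'
#' @param dataset a `MethylationDataset`.
#' @param p_max detection p-value ceiling, in (0, 1\]; default 0.01.
#' @param max_fail_fraction leniency: maximum tolerated fraction of failing
#'   samples per probe (default 0).
#' @return `list(dataset = filtered dataset, report = FilterReport)`.
#' @export
filter_detection <- function(dataset, p_max = 0.01, max_fail_fraction = 0) {
  if (!is.numeric(p_max) || length(p_max) != 1 || p_max <= 0 || p_max > 1) {
    stop("p_max must be a single value in (0, 1]")
  }
  n <- nrow(dataset$beta)
  if (is.null(dataset$detection_p)) {
    warning("no detection p-values present; detection filter skipped")
    return(list(dataset = dataset, report = .filter_report(n)))
  }
  drop <- .mask_detection(dataset, p_max, max_fail_fraction)
  list(dataset = subset_probes(dataset, !drop),
       report = .filter_report(n, n_fail_detection = sum(drop)))
}

#' Remove probes with missing beta values
#'
#' A probe is removed iff any sample value is `NA`.
#'
#' @param dataset a `MethylationDataset`.
#' @return `list(dataset, report)` as in [filter_detection()].
#' @export
filter_missing <- function(dataset) {
  drop <- .mask_missing(dataset)
  list(dataset = subset_probes(dataset, !drop),
       report = .filter_report(nrow(dataset$beta), n_missing = sum(drop)))
}

#' Remove sex-chromosome probes
#'
#' Only chrX by default; chrY exclusion is opt-in via `chroms`.
#'
#' @param dataset a `MethylationDataset`.
#' @param chroms chromosomes to exclude (default `"chrX"`).
#' @return `list(dataset, report)` as in [filter_detection()].
#' @export
exclude_sex_chromosomes <- function(dataset, chroms = c("chrX")) {
  drop <- .mask_sex(dataset, chroms)
  list(dataset = subset_probes(dataset, !drop),
       report = .filter_report(nrow(dataset$beta), n_sex_chrom = sum(drop)))
}

#' Apply all probe-quality filters
#'
#' Applies the detection, missing-value and sex-chromosome filters (the
#' retained set is the same in any order since each is a per-probe
#' predicate) and reports each removed probe once, under its first failing
#' rule in the order detection, then missing, then sex chromosome. Probes on
#' a user-supplied `blocklist` (e.g. cross-reactive probes) are removed
#' first, counted separately.
#'
#' @param dataset a `MethylationDataset`.
#' @inheritParams filter_detection
#' @inheritParams exclude_sex_chromosomes
#' @param blocklist optional character vector of probe ids to drop up front.
#' @return `list(dataset, report)`; the report attributes each probe to one
#'   rule so the counts always sum: `n_retained = n_input - (failures)`.
#' @export
apply_qc <- function(dataset, p_max = 0.01, max_fail_fraction = 0,
                     chroms = c("chrX"), blocklist = NULL) {
  n_block <- 0L
  if (!is.null(blocklist)) {
    keep <- !(dataset$annotation$probe_id %in% blocklist)
    n_block <- sum(!keep)
    dataset <- subset_probes(dataset, keep)
  }
  n <- nrow(dataset$beta)
  det <- if (is.null(dataset$detection_p)) rep(FALSE, n) else
    .mask_detection(dataset, p_max, max_fail_fraction)
  mis <- .mask_missing(dataset)
  sex <- .mask_sex(dataset, chroms)
  report <- .filter_report(n,
                           n_fail_detection = sum(det),
                           n_missing = sum(mis & !det),
                           n_sex_chrom = sum(sex & !det & !mis))
  report$n_blocklist <- n_block
  list(dataset = subset_probes(dataset, !(det | mis | sex)), report = report)
}
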