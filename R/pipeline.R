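# Orchestration: read -> QC -> differential -> region calling ->
# annotation -> epigenotyping -> report. Every run is a pure function of
# (inputs, parameters): identical inputs give byte-identical summaries.

SCHEMA_VERSION <- "1.0"

#' Run the genome-wide imprinting-defect screen
#'
#' The full pipeline on an assembled dataset: probe QC ([apply_qc()]),
#' per-probe moderated differential methylation of the case group against
#' pooled controls ([probe_stats()]), run-based region calling
#' ([call_regions()]), annotation ([annotate_regions()]), epigenotype
#' classification of each candidate region ([classify_regions()]), and a
#' summary including the screen tallies and the per-category counts of
#' probes mapping to the known imprinted DMRs.
#'
#' Any stage failure aborts with the stage name and cause. An empty
#' post-QC dataset is a clean abort.
#'
#' @param dataset a `MethylationDataset`.
#' @param known_dmrs optional known-DMR data.frame for annotation and probe
#'   tallies.
#' @param case_group,control_groups groups compared per probe (defaults:
#'   NLRP7 moles vs pooled first-trimester + term placenta).
#' @param detection_p_max,max_fail_fraction,sex_chroms,blocklist QC
#'   parameters, see [apply_qc()].
#' @param min_probes,max_gap_bp,p_max,min_mean_abs_delta region-calling
#'   parameters, see [call_regions()].
#' @param thresholds epigenotype bands, see [epigenotype_thresholds()].
#' @param out_dir optional directory; when given, writes
#'   `probe_stats.tsv`, `regions.tsv`, `regions.bed`,
#'   `epigenotype_calls.tsv` and `screen_summary.json` (summary plus the
#'   resolved parameters).
#' @return list with `filter_report`, `ebayes_params`, `probe_stats`,
#'   `regions`, `calls` and `summary`.
#' @export
run_screen <- function(dataset, known_dmrs = NULL,
                       case_group = "NLRP7_RHM",
                       control_groups = c("PLACENTA_FIRST", "PLACENTA_TERM"),
                       detection_p_max = 0.01, max_fail_fraction = 0,
                       sex_chroms = c("chrX"), blocklist = NULL,
                       min_probes = 3L, max_gap_bp = 500L, p_max = 0.01,
                       min_mean_abs_delta = 0.2,
                       thresholds = epigenotype_thresholds(),
                       out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("screen aborted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  qc <- stage("qc_filter", apply_qc(dataset, p_max = detection_p_max,
                                    max_fail_fraction = max_fail_fraction,
                                    chroms = sex_chroms, blocklist = blocklist))
  if (nrow(qc$dataset$beta) == 0) {
    stop("screen aborted at stage 'qc_filter': no probes retained after QC",
         call. = FALSE)
  }

  mod <- stage("diffmeth",
               probe_stats(qc$dataset, case_group, control_groups))
  regions <- stage("dmr_caller",
                   call_regions(mod$stats, qc$dataset$annotation,
                                min_probes = min_probes,
                                max_gap_bp = max_gap_bp, p_max = p_max,
                                min_mean_abs_delta = min_mean_abs_delta))
  regions <- stage("annotate",
                   annotate_regions(regions, qc$dataset$annotation, known_dmrs))

  region_probes <- setNames(regions$probe_ids,
                            sprintf("region_%03d", seq_len(nrow(regions))))
  calls <- stage("epigenotype",
                 classify_regions(qc$dataset, region_probes, thresholds))

  rep <- screen_report(regions)
  summary <- list(
    schema_version = SCHEMA_VERSION,
    filter_report = qc$report,
    n_regions = rep$n_regions,
    n_cgi = rep$n_cgi,
    cgi_fraction = rep$cgi_fraction,
    promoter_fraction = rep$promoter_fraction,
    n_gain = rep$n_gain,
    n_loss = rep$n_loss,
    label_counts = as.list(table(calls$label)),
    ebayes = mod$params)
  if (!is.null(known_dmrs)) {
    mapping <- map_probes_to_known_dmrs(qc$dataset, known_dmrs)
    per_dmr <- lengths(mapping)
    summary$known_dmr_probe_counts <- list(
      n_known_dmrs = nrow(known_dmrs),
      n_probes_ubiquitous =
        sum(per_dmr[known_dmrs$category == "ubiquitous"]),
      n_probes_placenta_specific =
        sum(per_dmr[known_dmrs$category == "placenta_specific"]))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_probe_stats(mod$stats, file.path(out_dir, "probe_stats.tsv"))
    write_region_table(regions, file.path(out_dir, "regions.tsv"))
    write_regions_bed(regions, file.path(out_dir, "regions.bed"))
    write.table(calls, file.path(out_dir, "epigenotype_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    payload <- summary
    payload$parameters <- list(
      case_group = case_group, control_groups = control_groups,
      detection_p_max = detection_p_max,
      max_fail_fraction = max_fail_fraction, sex_chroms = sex_chroms,
      min_probes = min_probes, max_gap_bp = max_gap_bp, p_max = p_max,
      min_mean_abs_delta = min_mean_abs_delta, thresholds = thresholds)
    jsonlite::write_json(payload, file.path(out_dir, "screen_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(filter_report = qc$report, ebayes_params = mod$params,
       probe_stats = mod$stats, regions = regions, calls = calls,
       summary = summary, dataset_qc = qc$dataset)
}

#' Profile and classify the known imprinted DMRs
#'
#' Maps the dataset's probes onto a known-DMR list, profiles each DMR's
#' methylation per group and classifies its epigenotype. DMRs without any
#' probe get a row with probe count 0 and no call.
#'
#' @param dataset a `MethylationDataset` (typically post-QC).
#' @param known_dmrs known-DMR data.frame (see [known_dmr_table()]).
#' @param thresholds see [epigenotype_thresholds()].
#' @return list with `table` (one row per known DMR: name, origin,
#'   category, `n_probes`, label, retained samples and group summaries) and
#'   `matrix` (DMR x sample mean-beta heatmap export).
#' @export
run_known_dmr_profile <- function(dataset, known_dmrs,
                                  thresholds = epigenotype_thresholds()) {
  mapping <- map_probes_to_known_dmrs(dataset, known_dmrs)
  calls <- classify_regions(dataset, mapping[lengths(mapping) > 0], thresholds)
  base <- data.frame(name = known_dmrs$name, origin = known_dmrs$origin,
                     category = known_dmrs$category,
                     n_probes = as.integer(lengths(mapping)[known_dmrs$name]),
                     stringsAsFactors = FALSE)
  merged <- merge(base, calls, by.x = "name", by.y = "region_id",
                  all.x = TRUE, sort = FALSE)
  merged$n_probes.y <- NULL
  names(merged)[names(merged) == "n_probes.x"] <- "n_probes"
  merged <- merged[match(known_dmrs$name, merged$name), , drop = FALSE]
  rownames(merged) <- NULL
  list(table = merged, matrix = epigenotype_matrix(dataset, mapping))
}
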