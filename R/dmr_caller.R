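# Run-based candidate-DMR detection over positionally sorted probe
# statistics: maximal runs of consecutive qualifying probes with a
# consistent direction of change, close spacing and a large average shift.

#' Call candidate differentially methylated regions
#'
#' Scans probes per chromosome in positional order. A probe qualifies iff
#' its p-value is below `p_max` and its `delta_beta` is nonzero. A run
#' extends while the next probe qualifies, has the same sign of change, and
#' lies strictly closer than `max_gap_bp` to the previous run member
#' ("consecutive" means adjacent among the probes given, i.e. after QC, not
#' adjacent in the full manifest). A non-qualifying probe ends the run; a
#' qualifying probe with opposite sign, or at a gap of `max_gap_bp` or more,
#' ends it and seeds a new run at that probe. A maximal run is emitted iff
#' it has at least `min_probes` members and the absolute value of its
#' average `delta_beta` exceeds `min_mean_abs_delta` (the effect threshold
#' applies to the region average, not per probe). Emitted regions never
#' share a probe.
#'
#' Probes sharing a position are ordered deterministically by probe id
#' (lexical), with a logged count.
#'
#' @param stats data.frame with columns `probe_id`, `delta_beta`, `p_value`
#'   (e.g. the `stats` element of [probe_stats()]), restricted to
#'   QC-retained probes.
#' @param annotation probe annotation data.frame (`probe_id`, `chrom`,
#'   `pos`); only probes present in both `stats` and `annotation` are
#'   scanned.
#' @param min_probes minimum run length (default 3).
#' @param max_gap_bp strict upper bound on the distance between consecutive
#'   run members, in bp (default 500).
#' @param p_max per-probe p-value threshold for membership (default 0.01).
#' @param min_mean_abs_delta strict lower bound on the absolute region-mean
#'   beta change (default 0.2).
#' @return data.frame sorted by (chrom, start) with columns `chrom`,
#'   `start`, `end` (positions of the first/last probe), `n_probes`,
#'   `direction` (`gain`/`loss`), `mean_delta_beta`, `max_gap` (largest
#'   inter-probe distance inside the run) and list-column `probe_ids`.
#' @export
call_regions <- function(stats, annotation, min_probes = 3L, max_gap_bp = 500L,
                         p_max = 0.01, min_mean_abs_delta = 0.2) {
  idx <- match(stats$probe_id, annotation$probe_id)
  keep <- !is.na(idx)
  d <- data.frame(probe_id = stats$probe_id[keep],
                  delta = stats$delta_beta[keep],
                  p = stats$p_value[keep],
                  chrom = annotation$chrom[idx[keep]],
                  pos = annotation$pos[idx[keep]],
                  stringsAsFactors = FALSE)
  d <- d[order(d$chrom, d$pos, d$probe_id), , drop = FALSE]
  n_dup <- sum(duplicated(d[, c("chrom", "pos")]))
  if (n_dup > 0) {
    message(n_dup, " probe(s) share a position; ordered by probe id")
  }

  res <- list()
  for (chr in unique(d$chrom)) {
    dc <- d[d$chrom == chr, , drop = FALSE]
    q <- !is.na(dc$p) & !is.na(dc$delta) & dc$p < p_max & dc$delta != 0
    if (!any(q)) next
    s <- sign(dc$delta)
    gap <- c(Inf, diff(dc$pos))
    prev_q <- c(FALSE, q[-length(q)])
    prev_s <- c(0, s[-length(s)])
    new_run <- q & (!prev_q | s != prev_s | gap >= max_gap_bp)
    run_id <- cumsum(new_run)
    run_id[!q] <- NA_integer_
    for (r in split(seq_len(nrow(dc)), run_id)) {
      if (length(r) < min_probes) next
      mdelta <- mean(dc$delta[r])
      if (abs(mdelta) <= min_mean_abs_delta) next
      res[[length(res) + 1L]] <- data.frame(
        chrom = chr,
        start = dc$pos[r[1]],
        end = dc$pos[r[length(r)]],
        n_probes = length(r),
        direction = if (mdelta > 0) "gain" else "loss",
        mean_delta_beta = mdelta,
        max_gap = if (length(r) > 1) max(diff(dc$pos[r])) else 0L,
        stringsAsFactors = FALSE)
      res[[length(res)]]$probe_ids <- I(list(dc$probe_id[r]))
    }
  }
  if (length(res) == 0) return(.empty_regions())
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_regions <- function() {
  df <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                   n_probes = integer(0), direction = character(0),
                   mean_delta_beta = numeric(0), max_gap = numeric(0),
                   stringsAsFactors = FALSE)
  df$probe_ids <- I(list())
  df
}

#' Annotate candidate regions
#'
#' Adds three flags to each region: `cgi` (TRUE iff at least half its
#' probes are CpG-island members — majority rule), `promoter` (TRUE iff any
#' probe is annotated to a promoter), and `known_dmr_overlap`
#' (comma-separated names of known DMRs whose interval overlaps the
#' region's, empty string if none).
#'
#' @param regions region data.frame from [call_regions()].
#' @param annotation probe annotation with `probe_id`, `cgi`, `feature`.
#' @param dmrs optional known-DMR data.frame.
#' @return The region data.frame with `cgi`, `promoter` and
#'   `known_dmr_overlap` columns added.
#' @export
annotate_regions <- function(regions, annotation, dmrs = NULL) {
  if (nrow(regions) == 0) {
    regions$cgi <- logical(0)
    regions$promoter <- logical(0)
    regions$known_dmr_overlap <- character(0)
    return(regions)
  }
  idx_of <- function(ids) match(ids, annotation$probe_id)
  regions$cgi <- vapply(regions$probe_ids, function(ids) {
    mean(annotation$cgi[idx_of(ids)]) >= 0.5
  }, logical(1))
  regions$promoter <- vapply(regions$probe_ids, function(ids) {
    any(annotation$feature[idx_of(ids)] == "promoter")
  }, logical(1))
  regions$known_dmr_overlap <- ""
  if (!is.null(dmrs) && nrow(dmrs) > 0) {
    reg_gr <- GenomicRanges::GRanges(regions$chrom,
                                     IRanges::IRanges(regions$start, regions$end))
    dmr_gr <- GenomicRanges::GRanges(dmrs$chrom,
                                     IRanges::IRanges(dmrs$start, dmrs$end))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(reg_gr, dmr_gr))
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    for (i in unique(q)) {
      regions$known_dmr_overlap[i] <- paste(dmrs$name[s[q == i]], collapse = ",")
    }
  }
  regions
}

#' Summarise a screen's region calls
#'
#' @param regions annotated region data.frame (see [annotate_regions()]).
#' @return list with `n_regions`, `n_cgi`, `cgi_fraction`,
#'   `promoter_fraction`, `n_gain`, `n_loss`. Fractions are `NA` for an
#'   empty screen.
#' @export
screen_report <- function(regions) {
  n <- nrow(regions)
  n_cgi <- if (n > 0 && "cgi" %in% names(regions)) sum(regions$cgi) else 0L
  n_prom <- if (n > 0 && "promoter" %in% names(regions)) sum(regions$promoter) else 0L
  list(n_regions = n,
       n_cgi = as.integer(n_cgi),
       cgi_fraction = if (n > 0) n_cgi / n else NA_real_,
       promoter_fraction = if (n > 0) n_prom / n else NA_real_,
       n_gain = if (n > 0) sum(regions$direction == "gain") else 0L,
       n_loss = if (n > 0) sum(regions$direction == "loss") else 0L)
}
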