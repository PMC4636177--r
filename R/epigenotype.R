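# Classification of a region's germline epigenotype from its beta profile
# across sample groups. The biology the decision table encodes:
# a maternal germline DMR is half-methylated in biparental placenta, loses
# methylation in androgenetic moles (no maternal genome) and in
# NLRP7-mutated moles (failed oocyte imprint acquisition), and is
# unmethylated in sperm; its placenta-specific subtype additionally lacks
# methylation in somatic tissues. A paternal germline DMR gains full
# methylation in androgenetic moles (two sperm genomes) but stays allelic
# in NLRP7 moles, whose paternal imprints are intact. A secondary DMR,
# methylated post-fertilization on the paternal allele under the control of
# a maternal germline DMR, ends up fully methylated in both mole types.

EPIGENOTYPE_LABELS <- c("MATERNAL_GDMR_UBIQUITOUS",
                        "MATERNAL_GDMR_PLACENTA_SPECIFIC",
                        "PATERNAL_GDMR", "SECONDARY_DMR",
                        "NOT_IMPRINTED_UNMETH", "NOT_IMPRINTED_METH",
                        "AMBIGUOUS")

#' Default epigenotype thresholds
#'
#' Bands on mean beta separating the three canonical methylation states:
#' below `lo` is unmethylated (lack of methylation), `[part_lo, part_hi]`
#' is partial methylation consistent with one methylated allele, above `hi`
#' is full methylation. The values are package defaults chosen to separate
#' the states (about 0, about 0.5, about 1) with wide margins; they are not
#' measured constants.
#'
#' @param lo,part_lo,part_hi,hi band edges on the beta scale.
#' @return Named list of thresholds.
#' @export
epigenotype_thresholds <- function(lo = 0.15, part_lo = 0.30,
                                   part_hi = 0.70, hi = 0.85) {
  stopifnot(lo < part_lo, part_lo < part_hi, part_hi < hi)
  list(lo = lo, part_lo = part_lo, part_hi = part_hi, hi = hi)
}

#' Profile a region's methylation across groups
#'
#' Unweighted mean beta over the region's probes, per sample and per group.
#'
#' @param dataset a `MethylationDataset`.
#' @param probe_ids probes defining the region; probes absent from the
#'   dataset (e.g. removed by QC) are ignored. A region with no retained
#'   probe is skipped with a warning (returns `NULL`).
#' @param region_id identifier carried into the profile.
#' @return An `EpigenotypeProfile`: list with `region_id`, `n_probes`,
#'   `group_means`, `per_sample_means` and `sample_groups`.
#' @export
profile_region <- function(dataset, probe_ids, region_id = "region") {
  idx <- match(probe_ids, dataset$annotation$probe_id)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) {
    warning("region ", region_id, " has no retained probes; skipped")
    return(NULL)
  }
  sub <- dataset$beta[idx, , drop = FALSE]
  psm <- colMeans(sub, na.rm = TRUE)
  grp <- setNames(dataset$samples$group, dataset$samples$sample_id)[names(psm)]
  gm <- tapply(psm, grp, mean)
  structure(
    list(region_id = region_id,
         n_probes = length(idx),
         group_means = setNames(as.numeric(gm), names(gm)),
         per_sample_means = psm,
         sample_groups = grp),
    class = "EpigenotypeProfile"
  )
}

#' Classify a region's germline epigenotype
#'
#' Applies a closed decision table to a region's methylation profile. Each
#' group is summarised by the median of its per-sample region means —
#' the median, rather than the mean, so that a single mole retaining its
#' imprint (mosaic imprint retention, seen between consecutive moles of one
#' patient) does not flip the group call; the retaining samples are instead
#' reported in `retained_in`. The placenta summary pools first-trimester
#' and term samples.
#'
#' With `lo`, `part_lo`, `part_hi`, `hi` from `thresholds` and group
#' summaries placenta (pl), androgenetic mole (an), NLRP7 mole (rh),
#' sperm (sp), somatic (so) — conditions on absent groups are vacuous
#' except where stated:
#' * `MATERNAL_GDMR_*`: pl partial, an and rh below `lo` (whichever are
#'   present), sp below `lo` if present; subtype `PLACENTA_SPECIFIC` iff so
#'   present and below `lo`, else `UBIQUITOUS`.
#' * `PATERNAL_GDMR`: pl partial, an above `hi`, rh partial if present
#'   (paternal imprints survive the maternal-effect defect).
#' * `NOT_IMPRINTED_UNMETH` / `NOT_IMPRINTED_METH`: every available group
#'   summary below `lo` / above `hi` (checked ahead of the secondary rule,
#'   so a region fully methylated in every group is not-imprinted rather
#'   than secondary).
#' * `SECONDARY_DMR`: an and rh both present and above `hi`, pl partial or
#'   above `hi`.
#' * `AMBIGUOUS` otherwise (also when the placenta groups, or both mole
#'   groups, are absent).
#'
#' The table is evaluated in that order; it is total and deterministic, and
#' invariant to sample order.
#'
#' @param profile an `EpigenotypeProfile` from [profile_region()].
#' @param thresholds see [epigenotype_thresholds()].
#' @return An `EpigenotypeCall`: list with `region_id`, `label`,
#'   `retained_in` (CHM/RHM samples whose region mean sits in the partial
#'   band although the group call expects lack of methylation),
#'   `group_summary` and `reason` (non-`NA` only for forced AMBIGUOUS).
#' @export
classify_epigenotype <- function(profile, thresholds = epigenotype_thresholds()) {
  th <- thresholds
  psm <- profile$per_sample_means
  grp <- profile$sample_groups
  gsum <- function(groups) {
    v <- psm[grp %in% groups]
    if (length(v) == 0) NA_real_ else median(v)
  }
  pl <- gsum(c("PLACENTA_FIRST", "PLACENTA_TERM"))
  an <- gsum("ANDRO_CHM")
  rh <- gsum("NLRP7_RHM")
  sp <- gsum("SPERM")
  so <- gsum("SOMATIC")

  partial <- function(x) !is.na(x) && x >= th$part_lo && x <= th$part_hi
  low_if_present <- function(x) is.na(x) || x < th$lo
  avail <- c(pl = pl, an = an, rh = rh, sp = sp, so = so)
  avail <- avail[!is.na(avail)]

  call <- function(label, retained = character(0), reason = NA_character_) {
    structure(list(region_id = profile$region_id, label = label,
                   retained_in = retained,
                   group_summary = c(placenta = pl, andro_chm = an,
                                     nlrp7_rhm = rh, sperm = sp, somatic = so),
                   reason = reason),
              class = "EpigenotypeCall")
  }

  if (is.na(pl) || (is.na(an) && is.na(rh))) {
    return(call("AMBIGUOUS",
                reason = "missing required group (placenta and a mole group)"))
  }

  if (partial(pl) && low_if_present(an) && low_if_present(rh) &&
      low_if_present(sp)) {
    mole <- grp %in% c("ANDRO_CHM", "NLRP7_RHM")
    retained <- names(psm)[mole & psm >= th$part_lo & psm <= th$part_hi]
    subtype <- if (!is.na(so) && so < th$lo) "PLACENTA_SPECIFIC" else "UBIQUITOUS"
    return(call(paste0("MATERNAL_GDMR_", subtype), retained = retained))
  }
  if (partial(pl) && !is.na(an) && an > th$hi && (is.na(rh) || partial(rh))) {
    return(call("PATERNAL_GDMR"))
  }
  if (all(avail < th$lo)) return(call("NOT_IMPRINTED_UNMETH"))
  if (all(avail > th$hi)) return(call("NOT_IMPRINTED_METH"))
  if (!is.na(an) && an > th$hi && !is.na(rh) && rh > th$hi &&
      (pl > th$hi || partial(pl))) {
    return(call("SECONDARY_DMR"))
  }
  call("AMBIGUOUS")
}

#' Classify many regions at once
#'
#' @param dataset a `MethylationDataset`.
#' @param region_probes named list mapping region id to its probe ids (e.g.
#'   from [map_probes_to_known_dmrs()], or built from a region table's
#'   `probe_ids`).
#' @param thresholds see [epigenotype_thresholds()].
#' @return data.frame with one row per region that retained probes:
#'   `region_id`, `label`, `retained_in` (comma-separated) plus one
#'   `mean_<group>` column per group summary.
#' @export
classify_regions <- function(dataset, region_probes,
                             thresholds = epigenotype_thresholds()) {
  rows <- lapply(names(region_probes), function(id) {
    prof <- withCallingHandlers(
      profile_region(dataset, region_probes[[id]], id),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(prof)) return(NULL)
    cl <- classify_epigenotype(prof, thresholds)
    df <- data.frame(region_id = id, label = cl$label,
                     n_probes = prof$n_probes,
                     retained_in = paste(cl$retained_in, collapse = ","),
                     stringsAsFactors = FALSE)
    gs <- cl$group_summary
    for (g in names(gs)) df[[paste0("mean_", g)]] <- gs[[g]]
    df
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(region_id = character(0), label = character(0),
                      n_probes = integer(0), retained_in = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Region-by-sample mean-beta matrix
#'
#' Heatmap-ready export: one row per region, one column per sample, each
#' cell the unweighted mean beta of the region's retained probes in that
#' sample.
#'
#' @inheritParams classify_regions
#' @return Numeric matrix (regions x samples); regions without retained
#'   probes are rows of `NA`.
#' @export
epigenotype_matrix <- function(dataset, region_probes) {
  m <- matrix(NA_real_, nrow = length(region_probes),
              ncol = ncol(dataset$beta),
              dimnames = list(names(region_probes), colnames(dataset$beta)))
  for (id in names(region_probes)) {
    idx <- match(region_probes[[id]], dataset$annotation$probe_id)
    idx <- idx[!is.na(idx)]
    if (length(idx) > 0) {
      m[id, ] <- colMeans(dataset$beta[idx, , drop = FALSE], na.rm = TRUE)
    }
  }
  m
}
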