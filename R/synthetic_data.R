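# Seeded generator of complete synthetic fixtures: an island-structured
# probe manifest, group-wise beta matrices with planted DMR classes,
# detection p-values, ground truth, bisulfite clone sets and HpaII assays.
# The generator emulates the statistical structure the screen assumes:
# CpG-island-clustered probe spacing, the canonical beta states of each
# epigenotype class in each sample group, per-sample imprint-retention
# mosaicism at maternal DMRs, and sporadic detection failures.

MATERNAL_CLASSES <- c("maternal_ubiquitous", "maternal_placenta_specific")

#' Beta-state targets per region class and sample group
#'
#' The canonical states: `lom` (lack of methylation, about 0), `partial`
#' (one methylated allele, about 0.5) and `full` (about 1). A maternal
#' germline DMR is partial in placenta, loses methylation in androgenetic
#' and NLRP7 moles and in sperm, and is partial (ubiquitous subtype) or
#' unmethylated (placenta-specific subtype) in soma. A paternal germline
#' DMR is partial in placenta and NLRP7 moles but fully methylated in
#' androgenetic moles and sperm. A secondary DMR is fully methylated in
#' both mole types while partial in placenta and soma and unmethylated in
#' sperm. `balanced_partial` (partial everywhere, non-differential) is
#' available for null studies.
#'
#' @param lom,partial,full the three state levels. The defaults 0.05, 0.50
#'   and 0.95 put the differential classes at a beta change of 0.45
#'   between NLRP7 moles and placenta.
#' @return Numeric matrix, classes x groups.
#' @export
class_beta_targets <- function(lom = 0.05, partial = 0.5, full = 0.95) {
  groups <- c("ANDRO_CHM", "NLRP7_RHM", "PLACENTA_FIRST", "PLACENTA_TERM",
              "SOMATIC", "SPERM", "BLOOD")
  t <- rbind(
    maternal_ubiquitous        = c(lom,  lom,  partial, partial, partial, lom,  partial),
    maternal_placenta_specific = c(lom,  lom,  partial, partial, lom,     lom,  lom),
    paternal                   = c(full, partial, partial, partial, partial, full, partial),
    secondary                  = c(full, full, partial, partial, partial, lom,  partial),
    not_imprinted_unmeth       = c(lom,  lom,  lom,     lom,     lom,     lom,  lom),
    not_imprinted_meth         = c(full, full, full,    full,    full,    full, full),
    balanced_partial           = c(partial, partial, partial, partial, partial, partial, partial)
  )
  colnames(t) <- groups
  t
}

#' Simulation configuration
#'
#' Defaults mirror the study design the screen targets: 4 androgenetic
#' moles, 5 NLRP7-mutated moles, 7 normal placentas (3 first trimester,
#' 4 term), 4 somatic tissues and 1 sperm sample; islands of 3-8 probes
#' spaced 20-200 bp apart, separated by gaps larger than the region
#' caller's 500 bp rule so no called run can span two islands; beta noise
#' sd 0.05; 5% per-sample imprint retention at maternal DMRs.
#'
#' @param seed integer seed; all generator output is a pure function of the
#'   configuration.
#' @param n_islands number of probe islands.
#' @param probes_per_island inclusive range of probes per island.
#' @param intra_island_spacing inclusive bp range between island probes.
#' @param inter_island_gap minimum bp gap between islands (must exceed the
#'   caller's `max_gap_bp`).
#' @param class_proportions named fractions over the rows of
#'   [class_beta_targets()]; must sum to 1.
#' @param beta_noise_sd Gaussian noise sd on the beta scale (values clamped
#'   to \[0, 1\]).
#' @param group_sizes named sample counts per group.
#' @param detection_fail_rate fraction of matrix cells given a failing
#'   (> 0.01) detection p-value.
#' @param retention_rate per (sample x maternal-DMR island) probability
#'   that a mole sample keeps the partial imprint instead of losing it.
#' @param cgi_fraction fraction of islands flagged as CpG islands.
#' @param promoter_fraction fraction of islands annotated as promoters.
#' @param chrom chromosome name used for the synthetic manifest.
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(seed = 1L,
                       n_islands = 200L,
                       probes_per_island = c(3L, 8L),
                       intra_island_spacing = c(20L, 200L),
                       inter_island_gap = 600L,
                       class_proportions = c(maternal_ubiquitous = 0.15,
                                             maternal_placenta_specific = 0.10,
                                             paternal = 0.05,
                                             secondary = 0.05,
                                             not_imprinted_unmeth = 0.35,
                                             not_imprinted_meth = 0.30),
                       beta_noise_sd = 0.05,
                       group_sizes = c(ANDRO_CHM = 4L, NLRP7_RHM = 5L,
                                       PLACENTA_FIRST = 3L, PLACENTA_TERM = 4L,
                                       SOMATIC = 4L, SPERM = 1L),
                       detection_fail_rate = 0.001,
                       retention_rate = 0.05,
                       cgi_fraction = 0.92,
                       promoter_fraction = 0.88,
                       chrom = "chr1") {
  stopifnot(abs(sum(class_proportions) - 1) < 1e-8,
            all(class_proportions >= 0),
            all(names(class_proportions) %in% rownames(class_beta_targets())),
            probes_per_island[1] >= 1,
            intra_island_spacing[1] >= 1,
            inter_island_gap > 0,
            beta_noise_sd >= 0,
            retention_rate >= 0, retention_rate <= 1,
            detection_fail_rate >= 0, detection_fail_rate < 1,
            all(names(group_sizes) %in% SAMPLE_GROUPS))
  structure(list(seed = as.integer(seed), n_islands = as.integer(n_islands),
                 probes_per_island = as.integer(probes_per_island),
                 intra_island_spacing = as.integer(intra_island_spacing),
                 inter_island_gap = as.integer(inter_island_gap),
                 class_proportions = class_proportions,
                 beta_noise_sd = beta_noise_sd,
                 group_sizes = group_sizes,
                 detection_fail_rate = detection_fail_rate,
                 retention_rate = retention_rate,
                 cgi_fraction = cgi_fraction,
                 promoter_fraction = promoter_fraction,
                 chrom = chrom),
            class = "SimulationConfig")
}

#' Generate an island-structured probe manifest with ground truth
#'
#' Islands are laid left to right with inter-island gaps of at least
#' `inter_island_gap` bp, so a called run can never span two islands and
#' ground-truth matching is unambiguous. Island probes share the island's
#' CpG-island flag and feature annotation.
#'
#' @param config a [sim_config()].
#' @return list with `annotation` (probe manifest plus an `island` column)
#'   and `truth` (one row per island: `island_id`, `class`, coordinates,
#'   `n_probes`, `cgi`, `promoter`, and list-column `probe_ids`).
#' @export
generate_manifest <- function(config) {
  set.seed(config$seed)
  n <- config$n_islands
  classes <- sample(names(config$class_proportions), n, replace = TRUE,
                    prob = config$class_proportions)
  kmin <- config$probes_per_island[1]
  kmax <- config$probes_per_island[2]
  k <- kmin + sample.int(kmax - kmin + 1L, n, replace = TRUE) - 1L
  cgi <- runif(n) < config$cgi_fraction
  promoter <- runif(n) < config$promoter_fraction
  nonprom_feature <- sample(c("gene_body", "intergenic"), n, replace = TRUE)

  pos_list <- vector("list", n)
  cur <- 1000L
  smin <- config$intra_island_spacing[1]
  smax <- config$intra_island_spacing[2]
  for (i in seq_len(n)) {
    gaps <- if (k[i] > 1) {
      smin + sample.int(smax - smin + 1L, k[i] - 1, replace = TRUE) - 1L
    } else integer(0)
    pos_list[[i]] <- cur + c(0L, cumsum(gaps))
    cur <- pos_list[[i]][k[i]] + config$inter_island_gap +
      sample(0:1000, 1)
  }

  island_id <- sprintf("isl%04d", seq_len(n))
  probe_island <- rep(seq_len(n), k)
  annotation <- data.frame(
    probe_id = sprintf("cg%07d", seq_len(sum(k))),
    chrom = config$chrom,
    pos = unlist(pos_list),
    cgi = cgi[probe_island],
    feature = ifelse(promoter[probe_island], "promoter",
                     nonprom_feature[probe_island]),
    island = island_id[probe_island],
    stringsAsFactors = FALSE)

  truth <- data.frame(
    island_id = island_id, class = classes, chrom = config$chrom,
    start = vapply(pos_list, function(p) p[1], integer(1)),
    end = vapply(pos_list, function(p) p[length(p)], integer(1)),
    n_probes = k, cgi = cgi, promoter = promoter,
    stringsAsFactors = FALSE)
  truth$probe_ids <- I(split(annotation$probe_id, probe_island))
  names(truth$probe_ids) <- island_id
  list(annotation = annotation, truth = truth)
}

#' Generate beta and detection matrices for a synthetic manifest
#'
#' Every cell's beta value is its class-by-group target (see
#' [class_beta_targets()]) plus Gaussian noise of sd `beta_noise_sd`,
#' clamped to \[0, 1\] (truncation by clamping, giving point mass at the
#' bounds near 0 and 1). With probability `retention_rate`, a mole sample
#' retains the partial imprint at a maternal-DMR island (the whole island
#' for that sample) instead of losing it; retained pairs are recorded.
#' Detection p-values sit near 0 except for a `detection_fail_rate`
#' fraction of cells set above 0.01. Fully reproducible from the
#' configuration seed.
#'
#' @param annotation,truth output of [generate_manifest()].
#' @param config the same [sim_config()].
#' @return list with `dataset` (a `MethylationDataset`) and `retained`
#'   (data.frame `island_id`, `sample_id` of imprint-retention events).
#' @export
generate_betas <- function(annotation, truth, config) {
  set.seed(config$seed + 1L)
  gs <- config$group_sizes
  samples <- data.frame(
    sample_id = unlist(lapply(names(gs), function(g) {
      paste0(g, "_", seq_len(gs[[g]]))
    })),
    group = rep(names(gs), unlist(gs)),
    stringsAsFactors = FALSE)

  targets <- class_beta_targets()
  island_of_probe <- match(annotation$island, truth$island_id)
  class_idx <- match(truth$class, rownames(targets))[island_of_probe]
  group_idx <- match(samples$group, colnames(targets))
  np <- nrow(annotation); ns <- nrow(samples)

  tmat <- matrix(targets[cbind(rep(class_idx, times = ns),
                               rep(group_idx, each = np))], np, ns)

  # imprint-retention mosaicism at maternal DMRs in mole samples
  elig <- outer(truth$class %in% MATERNAL_CLASSES,
                samples$group %in% c("ANDRO_CHM", "NLRP7_RHM"), "&")
  retained_mat <- matrix(runif(length(elig)) < config$retention_rate,
                         nrow(elig), ncol(elig)) & elig
  partial_level <- class_beta_targets()["balanced_partial", 1]
  tmat[retained_mat[island_of_probe, , drop = FALSE]] <- partial_level

  beta <- tmat + rnorm(np * ns, 0, config$beta_noise_sd)
  beta <- matrix(pmin(1, pmax(0, beta)), np, ns,
                 dimnames = list(annotation$probe_id, samples$sample_id))

  det <- matrix(runif(np * ns, 0, 0.005), np, ns,
                dimnames = dimnames(beta))
  fails <- runif(np * ns) < config$detection_fail_rate
  det[fails] <- runif(sum(fails), 0.011, 0.5)

  ret_idx <- which(retained_mat, arr.ind = TRUE)
  retained <- data.frame(island_id = truth$island_id[ret_idx[, 1]],
                         sample_id = samples$sample_id[ret_idx[, 2]],
                         stringsAsFactors = FALSE)

  list(dataset = methylation_dataset(annotation, beta, det, samples),
       retained = retained)
}

#' Generate bisulfite clone sets for the planted maternal DMRs
#'
#' For each maternal-DMR island, half the clones come from the methylated
#' maternal allele (all CpGs methylated) and half from the unmethylated
#' paternal allele, with each CpG state flipped independently at the
#' conversion-error rate. The maternal allele label is drawn per region and
#' recorded in the returned truth table.
#'
#' @param truth truth table from [generate_manifest()].
#' @param config the same [sim_config()].
#' @param n_clones clones per set (half methylated, half not).
#' @param n_cpgs CpGs per clone.
#' @param conversion_error per-CpG state flip probability.
#' @return list with `clonesets` (named list of [bisulfite_cloneset()]) and
#'   `truth` (data.frame `region_id`, `methylated_allele`).
#' @export
generate_clonesets <- function(truth, config, n_clones = 12L, n_cpgs = 10L,
                               conversion_error = 0.02) {
  set.seed(config$seed + 2L)
  mat <- truth[truth$class %in% MATERNAL_CLASSES, , drop = FALSE]
  clonesets <- list()
  rows <- list()
  for (i in seq_len(nrow(mat))) {
    meth_allele <- sample(c("A", "B"), 1)
    unmeth_allele <- setdiff(c("A", "B"), meth_allele)
    n_meth <- n_clones %/% 2
    states <- rbind(
      matrix(runif(n_meth * n_cpgs) >= conversion_error, n_meth, n_cpgs),
      matrix(runif((n_clones - n_meth) * n_cpgs) < conversion_error,
             n_clones - n_meth, n_cpgs))
    clones <- data.frame(
      clone_id = paste0("clone", seq_len(n_clones)),
      allele = c(rep(meth_allele, n_meth),
                 rep(unmeth_allele, n_clones - n_meth)),
      cpg = apply(states, 1, function(x) paste(as.integer(x), collapse = "")),
      stringsAsFactors = FALSE)
    clonesets[[mat$island_id[i]]] <-
      bisulfite_cloneset(mat$island_id[i], clones, conversion_error)
    rows[[i]] <- data.frame(region_id = mat$island_id[i],
                            methylated_allele = meth_allele,
                            stringsAsFactors = FALSE)
  }
  list(clonesets = clonesets,
       truth = if (length(rows) == 0) {
         data.frame(region_id = character(0), methylated_allele = character(0))
       } else do.call(rbind, rows))
}

#' Simulate a complete analysis workspace
#'
#' Runs the manifest, beta and cloneset generators under one configuration
#' and derives a known-DMR list from the planted germline-DMR islands
#' (maternal and paternal classes; secondary DMRs are somatic, not
#' germline, so they are deliberately absent from the known list).
#'
#' @param config a [sim_config()].
#' @return list with `config`, `annotation`, `truth`, `dataset`,
#'   `retained`, `known_dmrs`, `clonesets`, `cloneset_truth`.
#' @export
simulate_workspace <- function(config = sim_config()) {
  man <- generate_manifest(config)
  bt <- generate_betas(man$annotation, man$truth, config)
  cl <- generate_clonesets(man$truth, config)
  germline <- man$truth$class %in% c(MATERNAL_CLASSES, "paternal")
  kd <- man$truth[germline, , drop = FALSE]
  known_dmrs <- data.frame(
    name = kd$island_id, chrom = kd$chrom, start = kd$start, end = kd$end,
    origin = ifelse(kd$class == "paternal", "paternal", "maternal"),
    category = ifelse(kd$class == "maternal_placenta_specific",
                      "placenta_specific", "ubiquitous"),
    stringsAsFactors = FALSE)
  list(config = config, annotation = man$annotation, truth = man$truth,
       dataset = bt$dataset, retained = bt$retained,
       known_dmrs = known_dmr_table(known_dmrs),
       clonesets = cl$clonesets, cloneset_truth = cl$truth)
}

#' Write a simulated workspace to disk
#'
#' Emits every fixture in the exact text formats the readers consume:
#' `manifest.tsv`, `beta.tsv`, `detection_p.tsv`, `samplesheet.csv`,
#' `known_dmrs.tsv`, `clonesets.tsv` and `ground_truth.tsv`.
#'
#' @param sim output of [simulate_workspace()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_workspace <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dataset(sim$dataset, dir)
  write.table(sim$known_dmrs, file.path(dir, "known_dmrs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_clonesets(sim$clonesets, file.path(dir, "clonesets.tsv"))
  truth <- sim$truth
  truth$probe_ids <- vapply(truth$probe_ids, paste, character(1),
                            collapse = ",")
  write.table(truth, file.path(dir, "ground_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
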