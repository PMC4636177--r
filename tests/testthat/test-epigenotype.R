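# Build a profile directly from one region mean per sample.
profile_from_means <- function(means, groups, region_id = "r") {
  names(means) <- paste0("s", seq_along(means))
  structure(list(region_id = region_id, n_probes = 3L,
                 group_means = tapply(means, groups, mean),
                 per_sample_means = means,
                 sample_groups = stats::setNames(groups, names(means))),
            class = "EpigenotypeProfile")
}

test_that("region profiles are unweighted means over probes and samples", {
  ds <- make_dataset(matrix(0.5, 4, 6),
                     groups = c("NLRP7_RHM", "NLRP7_RHM", "PLACENTA_TERM",
                                "PLACENTA_TERM", "SOMATIC", "SPERM"))
  prof <- profile_region(ds, ds$annotation$probe_id, "all")
  expect_true(all(prof$group_means == 0.5))
  expect_true(all(prof$per_sample_means == 0.5))
  expect_false("ANDRO_CHM" %in% names(prof$group_means))  # absent group absent
  expect_warning(expect_null(profile_region(ds, "cg_nonexistent")), "skipped")
})

test_that("the decision table reproduces the canonical epigenotypes", {
  groups5 <- c("PLACENTA_FIRST", "ANDRO_CHM", "NLRP7_RHM", "SPERM", "SOMATIC")

  # maternal, placenta-specific: soma has lost the mark too
  cl <- classify_epigenotype(profile_from_means(
    c(0.48, 0.04, 0.06, 0.02, 0.05), groups5))
  expect_equal(cl$label, "MATERNAL_GDMR_PLACENTA_SPECIFIC")

  # maternal, ubiquitous: soma keeps allelic methylation
  cl <- classify_epigenotype(profile_from_means(
    c(0.48, 0.04, 0.06, 0.02, 0.52), groups5))
  expect_equal(cl$label, "MATERNAL_GDMR_UBIQUITOUS")

  # paternal (H19-type): full gain in androgenetic mole, allelic in RHM
  cl <- classify_epigenotype(profile_from_means(
    c(0.50, 0.97, 0.52), c("PLACENTA_FIRST", "ANDRO_CHM", "NLRP7_RHM")))
  expect_equal(cl$label, "PATERNAL_GDMR")

  # secondary (ZDBF2/ZNF597-type): full in both mole types
  cl <- classify_epigenotype(profile_from_means(
    c(0.55, 0.95, 0.93), c("PLACENTA_TERM", "ANDRO_CHM", "NLRP7_RHM")))
  expect_equal(cl$label, "SECONDARY_DMR")

  cl <- classify_epigenotype(profile_from_means(
    c(0.03, 0.02, 0.05), c("PLACENTA_TERM", "ANDRO_CHM", "NLRP7_RHM")))
  expect_equal(cl$label, "NOT_IMPRINTED_UNMETH")

  # fully methylated everywhere (NNAT/GNAS-AS1-like promoters)
  cl <- classify_epigenotype(profile_from_means(
    c(0.95, 0.97, 0.96), c("PLACENTA_TERM", "ANDRO_CHM", "NLRP7_RHM")))
  expect_equal(cl$label, "NOT_IMPRINTED_METH")

  # missing required groups force AMBIGUOUS with a reason
  cl <- classify_epigenotype(profile_from_means(
    c(0.5, 0.5), c("SOMATIC", "SPERM")))
  expect_equal(cl$label, "AMBIGUOUS")
  expect_match(cl$reason, "missing required group")
})

test_that("samples retaining the imprint are listed without flipping the call", {
  groups <- c("PLACENTA_FIRST", "PLACENTA_TERM", "ANDRO_CHM", "ANDRO_CHM",
              "NLRP7_RHM", "NLRP7_RHM", "NLRP7_RHM")
  means <- c(0.5, 0.52, 0.03, 0.05, 0.04, 0.44, 0.06)
  cl <- classify_epigenotype(profile_from_means(means, groups))
  expect_match(cl$label, "^MATERNAL_GDMR")
  expect_equal(cl$retained_in, "s6")
})

test_that("classification is total, deterministic, and sample-order invariant", {
  set.seed(55)
  groups <- c("ANDRO_CHM", "ANDRO_CHM", "NLRP7_RHM", "NLRP7_RHM",
              "PLACENTA_FIRST", "PLACENTA_TERM", "SOMATIC", "SPERM")
  for (i in 1:200) {
    means <- round(runif(length(groups)), 2)
    prof <- profile_from_means(means, groups)
    cl <- classify_epigenotype(prof)
    expect_true(cl$label %in% c("MATERNAL_GDMR_UBIQUITOUS",
                                "MATERNAL_GDMR_PLACENTA_SPECIFIC",
                                "PATERNAL_GDMR", "SECONDARY_DMR",
                                "NOT_IMPRINTED_UNMETH", "NOT_IMPRINTED_METH",
                                "AMBIGUOUS"))
    perm <- sample(length(groups))
    cl2 <- classify_epigenotype(profile_from_means(means[perm], groups[perm]))
    expect_identical(cl2$label, cl$label)
  }
})

test_that("group means of simulated regions sit on the generator targets", {
  sim <- simulate_workspace(sim_config(seed = 21, n_islands = 60,
                                       retention_rate = 0))
  targets <- class_beta_targets()
  for (i in sample(nrow(sim$truth), 12)) {
    prof <- profile_region(sim$dataset, sim$truth$probe_ids[[i]],
                           sim$truth$island_id[i])
    want <- targets[sim$truth$class[i], names(prof$group_means)]
    # clamping pulls boundary targets slightly inward; 0.03 absorbs it
    expect_true(all(abs(prof$group_means - want) < 0.03 + 0.01))
  }
})

test_that("planted epigenotype labels are recovered on synthetic data", {
  sim <- simulate_workspace(sim_config(seed = 13, n_islands = 80))
  calls <- classify_regions(sim$dataset, sim$truth$probe_ids)
  expect_equal(nrow(calls), 80)
  acc <- mean(calls$label == expected_label(
    sim$truth$class[match(calls$region_id, sim$truth$island_id)]))
  expect_gte(acc, 0.95)

  # lower noise recovers labels almost perfectly
  sim2 <- simulate_workspace(sim_config(seed = 13, n_islands = 80,
                                        beta_noise_sd = 0.02,
                                        retention_rate = 0))
  calls2 <- classify_regions(sim2$dataset, sim2$truth$probe_ids)
  acc2 <- mean(calls2$label == expected_label(
    sim2$truth$class[match(calls2$region_id, sim2$truth$island_id)]))
  expect_gte(acc2, 0.99)
})

test_that("generator-recorded imprint retention is re-detected per sample", {
  sim <- simulate_workspace(sim_config(seed = 29, n_islands = 120,
                                       retention_rate = 0.1))
  calls <- classify_regions(sim$dataset, sim$truth$probe_ids)
  maternal_called <- calls$region_id[grepl("^MATERNAL", calls$label)]
  planted <- sim$retained[sim$retained$island_id %in% maternal_called, ]
  listed <- strsplit(stats::setNames(calls$retained_in, calls$region_id), ",")
  hit <- mapply(function(isl, smp) smp %in% listed[[isl]],
                planted$island_id, planted$sample_id)
  expect_gte(mean(hit), 0.9)
})

test_that("the heatmap matrix export matches direct per-sample means", {
  sim <- simulate_workspace(sim_config(seed = 2, n_islands = 10))
  m <- epigenotype_matrix(sim$dataset, sim$truth$probe_ids)
  expect_equal(dim(m), c(10L, ncol(sim$dataset$beta)))
  ids <- sim$truth$probe_ids[[4]]
  idx <- match(ids, sim$dataset$annotation$probe_id)
  expect_equal(m[4, ], colMeans(sim$dataset$beta[idx, ]))
})
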