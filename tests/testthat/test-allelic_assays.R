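make_clones <- function(alleles, fracs, n_cpgs = 10) {
  data.frame(clone_id = paste0("c", seq_along(alleles)), allele = alleles,
             cpg = vapply(fracs, function(f) {
               k <- round(f * n_cpgs)
               paste(c(rep("1", k), rep("0", n_cpgs - k)), collapse = "")
             }, character(1)),
             stringsAsFactors = FALSE)
}

test_that("clone panels with allele-anchored bimodality are called allelic", {
  cs <- bisulfite_cloneset("r1", make_clones(
    c(rep("A", 5), rep("B", 5)), c(rep(1, 5), rep(0, 5))))
  res <- call_clone_methylation(cs)
  expect_equal(res$call, "allelic")
  expect_equal(res$methylated_allele, "A")
  expect_equal(unname(res$allele_fractions["A"]), 1)

  all_un <- bisulfite_cloneset("r2", make_clones(rep("unknown", 10), rep(0, 10)))
  expect_equal(call_clone_methylation(all_un)$call, "unmethylated")

  all_me <- bisulfite_cloneset("r3", make_clones(rep("unknown", 8), rep(1, 8)))
  expect_equal(call_clone_methylation(all_me)$call, "methylated")

  # bimodal without allele anchoring: a strand mixture, not allelic
  mix <- bisulfite_cloneset("r4", make_clones(
    rep("unknown", 10), c(rep(1, 5), rep(0, 5))))
  expect_equal(call_clone_methylation(mix)$call, "strand_mixture")

  small <- bisulfite_cloneset("r5", make_clones(c("A", "B", "A"), c(1, 0, 1)))
  expect_equal(call_clone_methylation(small)$call, "inconclusive")
})

test_that("a bimodal panel on a single allele label is never called allelic", {
  # e.g. a homozygous amplicon: allele column present but uninformative
  one <- bisulfite_cloneset("r6", make_clones(
    rep("A", 10), c(rep(1, 5), rep(0, 5))))
  res <- call_clone_methylation(one)
  expect_false(res$call == "allelic")
  expect_equal(res$call, "strand_mixture")

  # poor purity of the methylated class blocks the allelic call
  impure <- bisulfite_cloneset("r7", make_clones(
    c("A", "B", "A", "B", "A", "B", "A", "B"),
    c(1, 1, 1, 1, 0, 0, 0, 0)))
  expect_equal(call_clone_methylation(impure)$call, "inconclusive")
})

test_that("simulated maternal-DMR clone sets identify the methylated allele", {
  cfg <- sim_config(seed = 17, n_islands = 40)
  man <- generate_manifest(cfg)
  cl <- generate_clonesets(man$truth, cfg, conversion_error = 0.02)
  expect_gt(length(cl$clonesets), 0)
  calls <- lapply(cl$clonesets, call_clone_methylation)
  ok <- mapply(function(call, truth_allele) {
    call$call == "allelic" && call$methylated_allele == truth_allele
  }, calls, cl$truth$methylated_allele[
    match(names(cl$clonesets), cl$truth$region_id)])
  expect_gte(mean(ok), 0.95)

  # with no conversion error the clones are perfectly bimodal and pure
  cl0 <- generate_clonesets(man$truth, cfg, conversion_error = 0)
  fr <- vapply(strsplit(cl0$clonesets[[1]]$clones$cpg, ""),
               function(x) mean(x == "1"), numeric(1))
  expect_true(all(fr %in% c(0, 1)))
  expect_equal(length(cl0$clonesets[[1]]$clones$clone_id), 12)
})

test_that("HpaII reduction to homozygosity is reproduced on all genotype cases", {
  # het -> hom: allelic methylation, surviving allele methylated, maternal
  a <- hpa2_assay("rs1", c("A", "G"), c("G", "G"),
                  maternal = c("G", "G"), paternal = c("A", "A"))
  res <- call_hpa2(a)
  expect_equal(res$call, "allelic_methylation")
  expect_equal(res$methylated_allele, "G")
  expect_equal(res$parental_origin, "maternal")

  # both parents could have transmitted the allele: origin stays NA
  b <- hpa2_assay("rs1", c("A", "G"), c("G", "G"),
                  maternal = c("A", "G"), paternal = c("A", "G"))
  expect_true(is.na(call_hpa2(b)$parental_origin))

  # het -> het: both alleles methylated (or incomplete digestion)
  res <- call_hpa2(hpa2_assay("rs2", c("A", "G"), c("A", "G")))
  expect_equal(res$call, "both_methylated")
  expect_match(res$note, "incomplete")

  # het -> no product: unmethylated
  expect_equal(call_hpa2(hpa2_assay("rs3", c("A", "G"), NULL))$call,
               "unmethylated")

  # homozygous undigested: uninformative
  expect_equal(call_hpa2(hpa2_assay("rs4", c("A", "A"), c("A", "A")))$call,
               "uninformative")

  # digested allele absent from the undigested pair: data integrity error
  expect_error(hpa2_assay("rs5", c("A", "G"), c("C", "C")), "not present")
})

test_that("complete digestion is deterministic; partial digestion is binomial", {
  set.seed(404)
  for (i in 1:20) {
    a <- simulate_hpa2(c("A", "G"), c(TRUE, FALSE), digestion_efficiency = 1)
    expect_equal(a$digested, c("A", "A"))
    b <- simulate_hpa2(c("A", "G"), c(TRUE, FALSE), digestion_efficiency = 0)
    expect_equal(b$digested, c("A", "G"))
  }
  # unmethylated allele escapes with probability 1 - efficiency
  het <- replicate(1000, {
    a <- simulate_hpa2(c("A", "G"), c(TRUE, FALSE), digestion_efficiency = 0.9)
    call_hpa2(a)$call == "both_methylated"
  })
  expect_lt(abs(mean(het) - 0.1), 3 * sqrt(0.1 * 0.9 / 1000))
})

test_that("pyrosequencing percentiles match a sort-and-interpolate oracle", {
  controls <- seq(0.40, 0.60, length.out = 21)
  res <- pyro_summary(controls, 0.05)
  expect_true(res$outlier)
  expect_false(pyro_summary(controls, res$median)$outlier)

  set.seed(31)
  for (n in c(5, 7, 12, 33, 64, 100)) {
    x <- runif(n)
    res <- pyro_summary(x, 0.5)
    expect_equal(res$p5, oracle_percentile(x, 0.05))
    expect_equal(res$p95, oracle_percentile(x, 0.95))
    expect_equal(res$median, oracle_percentile(x, 0.5))
  }
  expect_error(pyro_summary(runif(4), 0.5), "at least 5")
})

test_that("allelic-signal calls follow the mono and biallelic thresholds", {
  expect_equal(call_allelic_signal(c(0.98, 0.02)), "monoallelic")
  expect_equal(call_allelic_signal(c(0.5, 0.5)), "biallelic")
  expect_equal(call_allelic_signal(c(0.85, 0.15)), "inconclusive")
  expect_equal(call_allelic_signal(c(0, 0)), "inconclusive")
  # scale invariance of raw peak heights
  expect_equal(call_allelic_signal(c(490, 10)), "monoallelic")
})

test_that("clone sets round-trip through their TSV representation", {
  cfg <- sim_config(seed = 23, n_islands = 20)
  man <- generate_manifest(cfg)
  cl <- generate_clonesets(man$truth, cfg)
  path <- withr::local_tempfile()
  write_clonesets(cl$clonesets, path)
  back <- read_clonesets(path, conversion_error = 0.02)
  expect_equal(names(back), names(cl$clonesets))
  expect_equal(back[[1]]$clones$cpg, cl$clonesets[[1]]$clones$cpg)
})
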