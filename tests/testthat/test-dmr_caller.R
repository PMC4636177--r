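simple_stats <- function(pos, delta, p = 0.001) {
  ann <- make_annotation(pos)
  list(stats = data.frame(probe_id = ann$probe_id, delta_beta = delta,
                          p_value = p, stringsAsFactors = FALSE),
       annotation = ann)
}

test_that("a large gap terminates a run and the remainder is emitted", {
  inst <- simple_stats(c(100L, 200L, 300L, 900L), rep(0.3, 4))
  regions <- call_regions(inst$stats, inst$annotation)
  expect_equal(nrow(regions), 1)
  expect_equal(regions$start, 100L)
  expect_equal(regions$end, 300L)
  expect_equal(regions$n_probes, 3L)
  expect_equal(regions$direction, "gain")
})

test_that("a sign flip breaks a run below the length threshold", {
  inst <- simple_stats(c(100L, 200L, 300L), c(0.3, 0.3, -0.3))
  expect_equal(nrow(call_regions(inst$stats, inst$annotation)), 0)
})

test_that("nothing qualifies when every p-value misses the threshold", {
  inst <- simple_stats(c(100L, 200L, 300L), rep(0.3, 3), p = 0.5)
  expect_equal(nrow(call_regions(inst$stats, inst$annotation)), 0)
})

test_that("the 20% effect threshold applies to the region average", {
  # one probe at 0.15 is fine because the run mean 0.2067 clears 0.2
  inst <- simple_stats(c(100L, 200L, 300L), c(0.25, 0.15, 0.22))
  regions <- call_regions(inst$stats, inst$annotation)
  expect_equal(nrow(regions), 1)
  expect_equal(regions$mean_delta_beta, mean(c(0.25, 0.15, 0.22)))

  # while a run averaging exactly at the threshold is rejected (strict >)
  inst2 <- simple_stats(c(100L, 200L, 300L), c(0.2, 0.2, 0.2))
  expect_equal(nrow(call_regions(inst2$stats, inst2$annotation)), 0)
})

test_that("a gap of exactly max_gap_bp splits the run (strictly below rule)", {
  inst <- simple_stats(c(100L, 600L, 700L, 800L), rep(-0.3, 4))
  regions <- call_regions(inst$stats, inst$annotation)
  expect_equal(nrow(regions), 1)
  expect_equal(regions$start, 600L)
  expect_equal(regions$max_gap, 100L)
})

test_that("region calling equals the exhaustive enumeration oracle", {
  set.seed(123)
  for (i in 1:120) {
    inst <- random_region_instance()
    got <- call_regions(inst$stats, inst$annotation)
    want <- oracle_call_regions(inst$stats, inst$annotation)
    expect_equal(nrow(got), length(want))
    if (length(want) > 0) {
      expect_equal(unname(unclass(got$probe_ids)),
                   lapply(want, function(r) r$probe_ids))
      expect_equal(got$mean_delta_beta,
                   vapply(want, function(r) r$mean_delta_beta, numeric(1)))
      expect_equal(got$start, vapply(want, function(r) r$start, numeric(1)))
    }
  }
})

test_that("regions are sorted, disjoint, and shrink monotonically with p_max", {
  set.seed(321)
  for (i in 1:20) {
    inst <- random_region_instance()
    got <- call_regions(inst$stats, inst$annotation)
    if (nrow(got) > 1) {
      expect_true(all(diff(got$start) > 0))
      expect_equal(anyDuplicated(unlist(got$probe_ids)), 0)
    }
    member <- function(p_max) unlist(call_regions(
      inst$stats, inst$annotation, p_max = p_max)$probe_ids)
    qualifying <- inst$stats$probe_id[inst$stats$p_value < 0.01]
    expect_true(all(member(0.01) %in% qualifying))
    expect_true(all(member(0.001) %in% member(0.01)))
  }
})

test_that("probes sharing a position are ordered by probe id, logged", {
  ann <- make_annotation(c(100L, 100L, 200L),
                         probe_id = c("cg_b", "cg_a", "cg_c"))
  stats <- data.frame(probe_id = ann$probe_id, delta_beta = 0.3,
                      p_value = 0.001, stringsAsFactors = FALSE)
  expect_message(regions <- call_regions(stats, ann), "share a position")
  expect_equal(regions$probe_ids[[1]], c("cg_a", "cg_b", "cg_c"))
})

test_that("region annotation applies majority-CGI and any-promoter rules", {
  ann <- make_annotation(c(100L, 200L, 300L, 400L),
                         cgi = c(TRUE, TRUE, FALSE, FALSE),
                         feature = c("promoter", rep("gene_body", 3)))
  region <- data.frame(chrom = "chr1", start = 100L, end = 400L,
                       n_probes = 4L, direction = "gain",
                       mean_delta_beta = 0.3, max_gap = 100L,
                       stringsAsFactors = FALSE)
  region$probe_ids <- I(list(ann$probe_id))
  out <- annotate_regions(region, ann)
  expect_true(out$cgi)       # 2 of 4 is half: majority rule includes ties
  expect_true(out$promoter)

  region$probe_ids <- I(list(ann$probe_id[2:4]))  # 1 of 3 CGI
  out <- annotate_regions(region, ann)
  expect_false(out$cgi)
  expect_false(annotate_regions(region, ann[2:4, ])$promoter)

  dmrs <- known_dmr_table(data.frame(
    name = "K", chrom = "chr1", start = 350, end = 500,
    origin = "maternal", category = "ubiquitous"))
  out <- annotate_regions(region, ann, dmrs)
  expect_equal(out$known_dmr_overlap, "K")
})

test_that("screen summaries count planted regions exactly", {
  empty <- call_regions(data.frame(probe_id = "x", delta_beta = 0,
                                   p_value = 1), make_annotation(1L))
  rep0 <- screen_report(annotate_regions(empty, make_annotation(1L)))
  expect_equal(rep0$n_regions, 0)
  expect_equal(rep0$n_gain + rep0$n_loss, 0)

  sim <- simulate_workspace(sim_config(seed = 3, n_islands = 80,
                                       detection_fail_rate = 0))
  res <- run_screen(sim$dataset, sim$known_dmrs)
  differential <- sim$truth$class %in% c("maternal_ubiquitous",
                                         "maternal_placenta_specific",
                                         "secondary")
  rep <- screen_report(res$regions)
  expect_equal(rep$n_regions, sum(differential))
  expect_equal(rep$n_gain, sum(sim$truth$class == "secondary"))
  expect_equal(rep$n_loss, sum(differential) - rep$n_gain)
  # planted CGI flags recovered through the majority rule
  cgi_truth <- sim$truth$cgi[match(
    vapply(res$regions$probe_ids, function(ids) {
      sim$annotation$island[match(ids[1], sim$annotation$probe_id)]
    }, character(1)), sim$truth$island_id)]
  expect_equal(res$regions$cgi, cgi_truth)
})
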