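# Fixture builders and independent brute-force oracles shared across tests.

make_annotation <- function(pos, chrom = "chr1", cgi = TRUE,
                            feature = "gene_body",
                            probe_id = sprintf("cg%05d", seq_along(pos))) {
  data.frame(probe_id = probe_id, chrom = chrom, pos = pos,
             cgi = cgi, feature = feature, stringsAsFactors = FALSE)
}

make_samplesheet <- function(groups) {
  data.frame(sample_id = paste0("s", seq_along(groups)), group = groups,
             stringsAsFactors = FALSE)
}

# beta: matrix or vector-recycled value; groups: character vector per column
make_dataset <- function(beta, groups, pos = NULL, detection_p = NULL, ...) {
  beta <- as.matrix(beta)
  if (is.null(pos)) pos <- seq_len(nrow(beta)) * 1000L
  ann <- make_annotation(pos, ...)
  sheet <- make_samplesheet(groups)
  dimnames(beta) <- list(ann$probe_id, sheet$sample_id)
  if (!is.null(detection_p)) dimnames(detection_p) <- dimnames(beta)
  methylation_dataset(ann, beta, detection_p, sheet)
}

# O(n*m) brute-force probe-in-interval containment check.
oracle_map_probes <- function(annotation, dmrs) {
  out <- stats::setNames(rep(list(character(0)), nrow(dmrs)), dmrs$name)
  for (j in seq_len(nrow(dmrs))) {
    hit <- which(annotation$chrom == dmrs$chrom[j] &
                 annotation$pos >= dmrs$start[j] &
                 annotation$pos <= dmrs$end[j])
    hit <- hit[order(annotation$pos[hit], annotation$probe_id[hit])]
    out[[j]] <- annotation$probe_id[hit]
  }
  out
}

# Exhaustive region-caller oracle: enumerate every contiguous subsequence
# of the position-sorted probes on each chromosome, keep those whose probes
# all qualify, share one sign and sit closer than max_gap_bp pairwise,
# reduce to maximal ones (validity is hereditary, so maximal = not
# extendable by one probe on either side), then apply the length and
# average-effect thresholds.
oracle_call_regions <- function(stats, annotation, min_probes = 3,
                                max_gap_bp = 500, p_max = 0.01,
                                min_mean_abs_delta = 0.2) {
  idx <- match(stats$probe_id, annotation$probe_id)
  keep <- !is.na(idx)
  d <- data.frame(probe_id = stats$probe_id[keep],
                  delta = stats$delta_beta[keep],
                  p = stats$p_value[keep],
                  chrom = annotation$chrom[idx[keep]],
                  pos = annotation$pos[idx[keep]],
                  stringsAsFactors = FALSE)
  d <- d[order(d$chrom, d$pos, d$probe_id), , drop = FALSE]
  regions <- list()
  for (chr in unique(d$chrom)) {
    dc <- d[d$chrom == chr, , drop = FALSE]
    n <- nrow(dc)
    valid <- function(i, j) {
      if (i < 1 || j > n) return(FALSE)
      r <- i:j
      all(!is.na(dc$p[r]) & dc$p[r] < p_max & dc$delta[r] != 0) &&
        length(unique(sign(dc$delta[r]))) == 1 &&
        (length(r) == 1 || all(diff(dc$pos[r]) < max_gap_bp))
    }
    for (i in seq_len(n)) for (j in i:n) {
      if (!valid(i, j)) next
      if (valid(i - 1, j) || valid(i, j + 1)) next  # not maximal
      if (j - i + 1 < min_probes) next
      m <- mean(dc$delta[i:j])
      if (abs(m) <= min_mean_abs_delta) next
      regions[[length(regions) + 1]] <- list(
        chrom = chr, start = dc$pos[i], end = dc$pos[j],
        probe_ids = dc$probe_id[i:j], mean_delta_beta = m)
    }
  }
  regions
}

# Random small region-calling instance for property tests.
random_region_instance <- function(n_max = 25) {
  n <- sample(3:n_max, 1)
  gaps <- sample(c(30:200, 450:700), n - 1, replace = TRUE)
  pos <- cumsum(c(1000, gaps))
  ann <- make_annotation(pos)
  stats <- data.frame(
    probe_id = ann$probe_id,
    delta_beta = sample(c(-0.45, -0.25, -0.15, 0, 0.15, 0.25, 0.45),
                        n, replace = TRUE),
    p_value = sample(c(0.0005, 0.005, 0.05, 0.5), n, replace = TRUE),
    stringsAsFactors = FALSE)
  list(stats = stats, annotation = ann)
}

# Hand-rolled type-7 (linear interpolation) percentile, the oracle for
# pyro_summary.
oracle_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

expected_label <- function(class) {
  c(maternal_ubiquitous = "MATERNAL_GDMR_UBIQUITOUS",
    maternal_placenta_specific = "MATERNAL_GDMR_PLACENTA_SPECIFIC",
    paternal = "PATERNAL_GDMR",
    secondary = "SECONDARY_DMR",
    not_imprinted_unmeth = "NOT_IMPRINTED_UNMETH",
    not_imprinted_meth = "NOT_IMPRINTED_METH")[class]
}

# Mean of a normal(mu, sd) clamped to [0, 1] — closed form used when
# checking generator means against expectation.
clamped_normal_mean <- function(mu, sd) {
  if (sd == 0) return(min(1, max(0, mu)))
  a <- (0 - mu) / sd
  b <- (1 - mu) / sd
  mu * (stats::pnorm(b) - stats::pnorm(a)) +
    sd * (stats::dnorm(a) - stats::dnorm(b)) +
    0 * stats::pnorm(a) + 1 * (1 - stats::pnorm(b))
}
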