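# Interpreters for the orthogonal validation assays: bisulfite clone
# panels (allele-anchored methylation patterns), methylation-sensitive
# HpaII genotyping (reduction to homozygosity), pyrosequencing outlier
# summaries, and a generic allelic-signal caller.

#' Build a bisulfite clone set
#'
#' @param region_id region identifier.
#' @param clones data.frame with columns `clone_id`, `allele` (`A`, `B` or
#'   `unknown`; known only when the amplicon contains a heterozygous SNP)
#'   and `cpg` (string of 0/1 per CpG on the clone, at least one CpG).
#' @param conversion_error assumed bisulfite conversion error rate in
#'   \[0, 1).
#' @return A `BisulfiteCloneSet` list.
#' @export
bisulfite_cloneset <- function(region_id, clones, conversion_error = 0) {
  stopifnot(is.data.frame(clones),
            all(c("clone_id", "allele", "cpg") %in% names(clones)),
            conversion_error >= 0, conversion_error < 1)
  bad <- setdiff(unique(clones$allele), c("A", "B", "unknown"))
  if (length(bad) > 0) stop("allele must be A, B or unknown; got ", bad[1])
  if (any(nchar(clones$cpg) == 0)) stop("every clone needs at least one CpG")
  if (any(!grepl("^[01]+$", clones$cpg))) {
    stop("cpg strings must contain only 0 and 1")
  }
  structure(list(region_id = region_id, clones = clones,
                 conversion_error = conversion_error),
            class = "BisulfiteCloneSet")
}

.clone_fractions <- function(clones) {
  vapply(strsplit(clones$cpg, ""), function(x) mean(x == "1"), numeric(1))
}

#' Call the methylation pattern of a bisulfite clone set
#'
#' Each clone's methylation fraction classifies it as `hi`
#' (> `clone_meth_hi`), `lo` (< `clone_meth_lo`) or mixed. The set is called
#' `allelic` when both extreme classes each hold at least `min_fraction` of
#' clones and, where allele anchoring is available and discriminating, the
#' methylated clones concentrate on one allele (purity at least `purity`);
#' `strand_mixture` when bimodal but without discriminating allele
#' information (all clones unknown, or all on one allele); `methylated` /
#' `unmethylated` when at least 75% of clones sit in one extreme class; and
#' `inconclusive` otherwise, or with fewer than 4 clones.
#'
#' The thresholds are package defaults matching how clone diagrams are read
#' qualitatively; they are exposed, not measured constants.
#'
#' @param cloneset a [bisulfite_cloneset()].
#' @param clone_meth_hi,clone_meth_lo per-clone fraction bounds for the
#'   extreme classes.
#' @param min_fraction minimum fraction of clones in each extreme class for
#'   a bimodal (allelic) call.
#' @param purity minimum fraction of methylated clones on the majority
#'   allele for an `allelic` call.
#' @return list with `call`, `methylated_allele` (`NA` unless allelic),
#'   `allele_fractions` (mean clone methylation per allele label),
#'   `clone_classes` and `n_clones`.
#' @export
call_clone_methylation <- function(cloneset, clone_meth_hi = 0.7,
                                   clone_meth_lo = 0.3, min_fraction = 0.25,
                                   purity = 0.8) {
  clones <- cloneset$clones
  n <- nrow(clones)
  frac <- .clone_fractions(clones)
  af <- tapply(frac, clones$allele, mean)
  result <- function(call, methylated_allele = NA_character_) {
    list(call = call, methylated_allele = methylated_allele,
         allele_fractions = setNames(as.numeric(af), names(af)),
         clone_classes = cls, n_clones = n)
  }
  cls <- ifelse(frac > clone_meth_hi, "hi",
                ifelse(frac < clone_meth_lo, "lo", "mixed"))
  if (n < 4) return(result("inconclusive"))

  p_hi <- mean(cls == "hi")
  p_lo <- mean(cls == "lo")
  bimodal <- p_hi >= min_fraction && p_lo >= min_fraction
  known <- clones$allele[clones$allele != "unknown"]
  discriminating <- length(unique(known)) >= 2

  if (bimodal) {
    if (!discriminating) return(result("strand_mixture"))
    hi_alleles <- clones$allele[cls == "hi" & clones$allele != "unknown"]
    if (length(hi_alleles) == 0) return(result("strand_mixture"))
    tab <- table(hi_alleles)
    if (max(tab) / length(hi_alleles) >= purity) {
      return(result("allelic", methylated_allele = names(which.max(tab))))
    }
    return(result("inconclusive"))
  }
  if (p_hi >= 0.75) return(result("methylated"))
  if (p_lo >= 0.75) return(result("unmethylated"))
  result("inconclusive")
}

#' Build a methylation-sensitive HpaII genotyping assay record
#'
#' HpaII cuts only unmethylated CCGG sites, so after complete digestion
#' only methylated alleles amplify: a heterozygous SNP genotype reduced to
#' homozygosity proves single-allele methylation, the surviving allele
#' being the methylated chromosome.
#'
#' @param snp_id SNP identifier.
#' @param undigested unordered allele pair called on undigested DNA,
#'   e.g. `c("A", "G")`.
#' @param digested allele pair after digestion, or `NULL` for no product.
#' @param maternal,paternal optional parental allele pairs.
#' @return An `HpaIIAssay` list. Digested alleles outside the undigested
#'   pair are a data-integrity error.
#' @export
hpa2_assay <- function(snp_id, undigested, digested = NULL,
                       maternal = NULL, paternal = NULL) {
  stopifnot(length(undigested) == 2)
  if (!is.null(digested)) {
    if (!all(digested %in% undigested)) {
      stop("digested allele not present in the undigested genotype: ",
           paste(setdiff(digested, undigested), collapse = ","))
    }
    stopifnot(length(digested) == 2)
  }
  structure(list(snp_id = snp_id, undigested = sort(undigested),
                 digested = if (is.null(digested)) NULL else sort(digested),
                 maternal = maternal, paternal = paternal),
            class = "HpaIIAssay")
}

#' Call allelic methylation from an HpaII genotyping assay
#'
#' Reduction-to-homozygosity logic: a heterozygous undigested genotype that
#' becomes homozygous after digestion means `allelic_methylation` with the
#' surviving allele methylated; staying heterozygous means
#' `both_methylated` (or incomplete digestion — flagged in `note`);
#' yielding no product means `unmethylated`; a homozygous undigested sample
#' is `uninformative`. When parental genotypes are supplied and exactly one
#' parent could have transmitted the surviving allele, `parental_origin` is
#' set.
#'
#' @param assay an [hpa2_assay()].
#' @return list with `call`, `methylated_allele`, `parental_origin` and
#'   `note`.
#' @export
call_hpa2 <- function(assay) {
  out <- list(call = NA_character_, methylated_allele = NA_character_,
              parental_origin = NA_character_, note = NA_character_)
  und <- assay$undigested
  if (und[1] == und[2]) {
    out$call <- "uninformative"
    return(out)
  }
  dig <- assay$digested
  if (is.null(dig)) {
    out$call <- "unmethylated"
    return(out)
  }
  if (dig[1] != dig[2]) {
    out$call <- "both_methylated"
    out$note <- "heterozygous after digestion; cannot exclude incomplete digestion"
    return(out)
  }
  out$call <- "allelic_methylation"
  out$methylated_allele <- dig[1]
  if (!is.null(assay$maternal) && !is.null(assay$paternal)) {
    from_mother <- dig[1] %in% assay$maternal
    from_father <- dig[1] %in% assay$paternal
    if (from_mother && !from_father) out$parental_origin <- "maternal"
    if (from_father && !from_mother) out$parental_origin <- "paternal"
  }
  out
}

#' Simulate an HpaII genotyping assay
#'
#' Methylated allele copies always survive digestion and amplify;
#' unmethylated copies survive with probability `1 - digestion_efficiency`
#' (complete digestion is deterministic).
#'
#' @param alleles the two alleles of the genotype, e.g. `c("A", "G")`.
#' @param methylated logical pair: is each allele copy methylated?
#' @param digestion_efficiency probability an unmethylated copy is cut, in
#'   \[0, 1\].
#' @param snp_id identifier for the simulated assay.
#' @param maternal,paternal optional parental allele pairs passed through.
#' @return An [hpa2_assay()] with the simulated digested genotype.
#' @export
simulate_hpa2 <- function(alleles, methylated, digestion_efficiency = 1,
                          snp_id = "sim", maternal = NULL, paternal = NULL) {
  stopifnot(length(alleles) == 2, length(methylated) == 2,
            digestion_efficiency >= 0, digestion_efficiency <= 1)
  survives <- methylated | (runif(2) >= digestion_efficiency)
  surv <- alleles[survives]
  digested <- if (length(surv) == 0) NULL
              else if (length(surv) == 1) rep(surv, 2)
              else surv
  hpa2_assay(snp_id, alleles, digested, maternal = maternal,
             paternal = paternal)
}

#' Summarise a pyrosequencing control panel around one case value
#'
#' Empirical median and 5th/95th percentiles (linear interpolation) of the
#' control values; the case is an outlier iff it falls outside the closed
#' \[p5, p95\] interval.
#'
#' @param control_values numeric vector of at least 5 control measurements.
#' @param case_value single case measurement.
#' @return list with `median`, `p5`, `p95`, `outlier`.
#' @export
pyro_summary <- function(control_values, case_value) {
  if (length(control_values) < 5) stop("need at least 5 control values")
  qs <- quantile(control_values, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  list(median = qs[2], p5 = qs[1], p95 = qs[3],
       outlier = case_value < qs[1] || case_value > qs[3])
}

#' Call mono- versus biallelic signal from a pair of allele fractions
#'
#' Generic stand-in for reading an expression electropherogram: peak
#' heights are consumed as two nonnegative numbers. After normalising to
#' proportions, `monoallelic` iff the larger proportion reaches
#' `mono_threshold`; `biallelic` iff both proportions reach 0.25;
#' `inconclusive` otherwise (including zero total signal).
#'
#' @param allele_fractions numeric pair of nonnegative signals (sum at most 1
#'   when already proportions; any positive scale is accepted).
#' @param mono_threshold proportion above which the signal is monoallelic
#'   (default 0.9).
#' @return `"monoallelic"`, `"biallelic"` or `"inconclusive"`.
#' @export
call_allelic_signal <- function(allele_fractions, mono_threshold = 0.9) {
  stopifnot(length(allele_fractions) == 2, all(allele_fractions >= 0))
  s <- sum(allele_fractions)
  if (s == 0) return("inconclusive")
  p <- allele_fractions / s
  if (max(p) >= mono_threshold) return("monoallelic")
  if (min(p) >= 0.25) return("biallelic")
  "inconclusive"
}

#' Write bisulfite clone sets as TSV
#'
#' One row per clone: `region_id`, `clone_id`, `allele`, `cpg`.
#'
#' @param clonesets list of [bisulfite_cloneset()] objects.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_clonesets <- function(clonesets, path) {
  rows <- lapply(clonesets, function(cs) {
    data.frame(region_id = cs$region_id, cs$clones, stringsAsFactors = FALSE)
  })
  df <- if (length(rows) == 0) {
    data.frame(region_id = character(0), clone_id = character(0),
               allele = character(0), cpg = character(0))
  } else do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read bisulfite clone sets from TSV
#'
#' @param path TSV written by [write_clonesets()].
#' @param conversion_error assumed conversion error attached to every set.
#' @return Named list of [bisulfite_cloneset()] objects.
#' @export
read_clonesets <- function(path, conversion_error = 0) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(cpg = "character"))
  out <- lapply(split(df, df$region_id), function(d) {
    bisulfite_cloneset(d$region_id[1],
                       d[, c("clone_id", "allele", "cpg")],
                       conversion_error)
  })
  out[unique(df$region_id)]
}
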