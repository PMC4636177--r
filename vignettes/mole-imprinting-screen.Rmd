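---
title: "Screening hydatidiform-mole methylomes for imprinting defects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening hydatidiform-mole methylomes for imprinting defects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moleimprint)
```

## The problem

Genomic imprinting marks a small set of regulatory regions — germline
differentially methylated regions (DMRs) — with DNA methylation on only one
parental allele, set in the oocyte (maternal DMRs) or in sperm (paternal
DMRs). Hydatidiform moles are abnormal conceptions that distort this system
in two informative ways. An androgenetic complete mole carries two paternal
genomes and no maternal genome, so maternal DMRs appear unmethylated
(β ≈ 0) and paternal DMRs fully methylated (β ≈ 1). A biparental recurrent
mole from a mother with recessive *NLRP7* mutations has a normal genome, but
the defective oocyte fails to establish maternal imprints: maternal DMRs
lose methylation while paternal DMRs stay intact. Contrasting these two
epigenotypes against normal placenta, somatic tissue and sperm separates
germline maternal DMRs, germline paternal DMRs, and secondary DMRs (allelic
methylation acquired after fertilization under the control of a germline
DMR), and — because many maternal DMRs are methylated only in placenta —
splits the maternal class into ubiquitous and placenta-specific subtypes.

`moleimprint` implements that screen as a tested pipeline over
methylation-array beta values: probe quality control, per-probe moderated
differential methylation, run-based candidate-DMR calling, epigenotype
classification, and interpreters for the orthogonal validation assays
(bisulfite clone panels, methylation-sensitive HpaII genotyping,
pyrosequencing outlier panels, allelic-signal calls). A seeded synthetic
generator reproduces the statistical structure of such a study so the whole
analysis runs and is scored without any external data.

## The statistical model

### Per-probe differential methylation

For each probe the screen compares the *NLRP7*-mole group against pooled
normal placenta (first trimester plus term) on the beta scale. Tests run on
β directly, not on logit-transformed M-values, because the effect-size
threshold the region caller applies (a 20% methylation change) is defined
on β. For probe $g$ with case mean $\bar y_{1g}$ (size $n_1$) and control
mean $\bar y_{2g}$ (size $n_2$):

$$\Delta\beta_g = \bar y_{1g} - \bar y_{2g}, \qquad
s_g^2 = \frac{(n_1-1)s_{1g}^2 + (n_2-1)s_{2g}^2}{d}, \quad d = n_1+n_2-2.$$

With a handful of samples per group, per-probe variances are unstable, so
they are shrunk toward a prior shared across probes. The prior is the
standard scaled inverse-chi-square: $1/\sigma_g^2 \sim
\chi^2_{d_0}/(d_0 s_0^2)$. Its parameters are estimated by moment matching
on the log scale. Writing $e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$
(the additive bias of a log chi-square is removed by the digamma term),

$$\mathbb E[e_g] = \log s_0^2 - \psi(d_0/2) + \log(d_0/2), \qquad
\operatorname{Var}[e_g] = \psi'(d/2) + \psi'(d_0/2),$$

so $d_0$ is recovered by inverting the trigamma function on the excess
spread of $e_g$ (Newton iteration; if the observed spread does not exceed
$\psi'(d/2)$ the prior degrees of freedom are infinite and every probe
gets the common variance) and $s_0^2$ from the corrected mean. The
posterior variance and moderated statistic are

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d}, \qquad
t_g = \frac{\Delta\beta_g}{\sqrt{\tilde s_g^2 (1/n_1 + 1/n_2)}}
\;\sim\; t_{d_0 + d} \text{ under the null}.$$

The test suite verifies this implementation two ways: parameter recovery on
simulations with a known prior ($d_0 = 4$, $s_0^2 = 0.01$, 10,000 probes),
and agreement with an independent established implementation of the
moderated-t machinery on the same input.

### Region calling

Candidate DMRs are maximal runs of probes, scanned per chromosome in
positional order, in which every probe has moderated $p < 0.01$ and a
nonzero change, all changes share one direction, and consecutive run
members lie strictly closer than 500 bp. A run is reported when it has at
least 3 probes and its *average* $|\Delta\beta|$ exceeds 0.2 — the
threshold applies to the region mean, so a single 15% probe inside a
strong run does not break it. "Consecutive" means adjacent among the
QC-retained probes, because filtering precedes testing. An opposite-sign
qualifying probe terminates the current run and immediately seeds a new
one; no probe skipping is allowed. The implementation is checked
exhaustively against a brute-force enumeration of all contiguous probe
subsequences on hundreds of random instances.

### Epigenotype classification

Each region's per-sample mean β is summarised per group and pushed through
a closed decision table with four thresholds: `lo = 0.15` (below this a
mark is absent), `part_lo = 0.30` / `part_hi = 0.70` (the partial band of
one methylated allele), and `hi = 0.85` (full methylation). These bands
are package defaults chosen to separate the three canonical states
(≈ 0, ≈ 0.5, ≈ 1) with wide margins; the original interpretation of such
data argues qualitatively from heatmaps, so no measured constants exist to
inherit. All four are exposed as arguments.

Two design choices in the table were genuinely open:

* **Medians, not means, for group summaries.** Moles show mosaic imprint
  retention: a region otherwise lost can stay partially methylated in one
  individual sample (and consecutive moles of one patient can disagree).
  With four androgenetic samples, a single retaining sample at β ≈ 0.5
  drags the group *mean* to ≈ 0.16, past the `lo` band, and would flip a
  clear maternal DMR to ambiguous. The group condition is therefore
  evaluated on the median of per-sample means, which tolerates a minority
  of retaining samples; those samples are reported explicitly in
  `retained_in` rather than being allowed to veto the call. Plain group
  means are still computed and exported. (When half or more of a group
  retains the imprint the call honestly degrades to AMBIGUOUS — at that
  point the region's group-level state genuinely is not LOM.)
* **Rule order.** The not-imprinted rules are checked before the secondary
  rule, so a region fully methylated in *every* group is reported as not
  imprinted; the secondary call requires full methylation in both mole
  types alongside a partial or methylated placenta with some group
  breaking the all-high pattern. Fully methylated promoters that are known
  exceptions in normal placenta land in NOT_IMPRINTED_METH or AMBIGUOUS by
  design. The subtype split of maternal DMRs uses the somatic group alone:
  placenta-specific iff somatic tissue is below `lo`; if the somatic group
  is absent the ubiquitous subtype is reported, keeping the table total.

### Validation-assay interpreters

* **Bisulfite clone panels**: each clone's CpG string gives a methylation
  fraction; panels with at least 25% of clones in each extreme class
  (fraction > 0.7 / < 0.3) are bimodal. With a heterozygous SNP anchoring
  clones to alleles, a bimodal panel whose methylated clones concentrate
  (≥ 80%) on one allele is `allelic`; bimodal panels without discriminating
  allele information (all clones unknown or all one allele, as for a
  homozygous amplicon) are `strand_mixture`; 75% of clones in one extreme
  class gives a plain `methylated`/`unmethylated` call; fewer than four
  clones is always inconclusive. Thresholds mirror how clone diagrams are
  read by eye and are exposed as arguments.
* **HpaII genotyping**: the enzyme cuts only unmethylated CCGG sites, so
  after complete digestion only methylated alleles amplify. A heterozygous
  SNP reduced to homozygosity proves allelic methylation, with the
  surviving allele the methylated chromosome; parental genotypes, when
  informative, assign its origin. The simulator lets unmethylated copies
  escape digestion with probability $1 - \text{efficiency}$.
* **Pyrosequencing panels**: a case value is an outlier when it falls
  outside the empirical 5th–95th percentile band (linear interpolation) of
  at least five controls.
* **Allelic signal**: two peak heights are normalised to proportions;
  ≥ 0.9 on one allele is monoallelic, ≥ 0.25 on both is biallelic,
  anything else inconclusive.

## The synthetic study

The generator plants probe islands (3–8 probes, 20–200 bp apart) separated
by gaps of at least 600 bp — larger than the caller's 500 bp rule, so no
called run can ever span two islands and scoring against ground truth is
unambiguous. Default group sizes follow the motivating study design:
4 androgenetic moles, 5 *NLRP7* moles, 3 first-trimester and 4 term
placentas, 4 somatic tissues, 1 sperm sample. Island classes are drawn
with defaults of 15% ubiquitous-maternal, 10% placenta-specific-maternal,
5% paternal, 5% secondary and 65% non-imprinted — imprinted loci enriched
far above genomic reality so that a 200-island study carries enough
positives to estimate sensitivity, while the majority class still probes
specificity.

Beta values are the class-by-group target states (0.05 / 0.50 / 0.95)
plus Gaussian noise of sd 0.05, clamped to [0, 1]. The target levels put
the differential classes at Δβ = 0.45 between *NLRP7* moles and placenta;
clamping implements truncation and leaves point mass at the boundaries,
and the closed-form clamped-normal mean is used wherever tests check
generator output against expectation. Two realism features matter for the
pipeline's behaviour: per-(sample × maternal island) imprint retention at
rate 0.05, which creates exactly the mosaic pattern the classifier's
median rule and `retained_in` field handle; and sporadic detection-p
failures (rate 0.001 per cell), which exercise the any-sample-fails QC
rule. A `balanced_partial` class (β ≈ 0.5 everywhere) provides exact
global-null datasets — both groups share one Gaussian distribution with no
boundary truncation — for calibration studies.

What the generator does *not* emulate: Infinium probe-type chemistry bias,
raw-intensity normalisation artefacts, beta-distributed (heteroscedastic)
noise with variance shrinking near the boundaries (a beta-noise switch
would be the natural extension), cell-composition mixtures, or correlated
probe noise within an island. Passing the recovery tests therefore shows
the pipeline's logic is correct under its stated model, not that real
moles yield 98% sensitivity; on real arrays the effective noise is larger
and effect sizes at secondary DMRs smaller.

## Numerical choices and degenerate inputs

* Sample variances are floored at $10^{-8}$ before the log-moment fit so
  degenerate zero-variance probes cannot poison the prior; the posterior
  combination uses raw variances.
* A forced `d0_override = 0` reproduces the ordinary pooled t exactly;
  `d0 = Inf` (estimated or forced) uses the normal reference.
* Probes sharing a position are ordered by probe id, deterministically and
  with a logged count.
* β values outside [0, 1] are rejected at read time naming the probe —
  never clipped — since out-of-range betas indicate a corrupted matrix.
* The whole pipeline is a pure function of inputs and parameters; reruns
  produce byte-identical JSON summaries, and the generator is bit
  reproducible from its integer seed across platforms (R's default
  integer-state generator).

## Problem sizes used by the checks

The packaged checks run the screen at 200 islands (≈ 1,100 probes ×
21 samples), null-calibration studies at ≈ 20,000 probes with 20
replicate seeds, prior-parameter recovery at 10,000 probes, 500 random
region-calling instances against the exhaustive oracle, and 500 simulated
clone panels — sizes chosen so every distributional claim is measured with
comfortable binomial/standard-error margins while the full suite stays
fast on one CPU.

## Known limitations

* The per-probe p < 0.01 threshold is applied per probe within runs, the
  plainest reading of a run-based screen; no region-level multiple-testing
  correction is attempted (the screen's discoveries are meant to be
  validated orthogonally, and the validation interpreters are part of the
  package).
* Coordinates are consumed as given; the known-DMR list must share the
  manifest's assembly, and only containment of probe positions is used.
* Parent-of-origin is never inferred from array data alone — that is what
  the HpaII and clone interpreters are for.
* Regions retaining methylation in both mole types but partial in soma
  (rare protected loci) legitimately classify as AMBIGUOUS or SECONDARY;
  the decision table does not try to resolve what the underlying data
  cannot.
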