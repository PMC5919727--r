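---
title: "Quantifying genetic diversity and drift in isolated laboratory colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying genetic diversity and drift in isolated laboratory colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Laboratory colonies of non-model rodents are usually small, founded from a
handful of animals, and moved between institutions through repeated
bottlenecks. Even colonies derived recently from the same commercial stock
can therefore carry different subsets of the ancestral variation and drift
apart, with consequences for experimental reproducibility. `colonysift`
implements a genotyping-by-sequencing (GBS) analysis of this situation:
fixed-length sequence tags (92 bp by default) are assayed across sexed
individuals from several colonies, sex-linked tags are recognised from
read-depth ratios, genotypes are quality-filtered, and per-colony diversity
and between-colony differentiation are summarised. A Wright–Fisher colony
simulator generates data with the same statistical structure, so every
stage of the pipeline is exercised and tested without any sequencing data.

This repository is organised as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers that run the pipeline stage by
stage and write their tables under `results/`, while all computation lives
in the package functions documented here.

## Coverage-based sex-chromosome annotation

Each individual's per-tag read count is divided by that individual's total
read count (its sequencing effort) and multiplied by 10^6; these
counts-per-million are summed over females and over males
(`standardize_coverage()`). Because males carry one X and females two, an
X-linked tag shows male coverage near half its female coverage (slope 1/2
in the male-versus-female plane), autosomal tags near slope 1, and Y-linked
tags essentially zero female coverage. `classify_tags()` applies four rules
in a fixed order, with strict inequalities:

1. total standardized coverage < 10 → `unknown` (too little signal);
2. female coverage < 1 → `Y`;
3. male coverage < 3/4 × female coverage − 5 → `X`;
4. otherwise → `autosomal`.

The order matters for low-coverage tags (a tag with female coverage 0.5 but
total 5.5 is `unknown`, not `Y`) and is not configurable. The X rule's slope
of 3/4 sits between the X cluster (1/2) and the autosomal cluster (1); the
−5 intercept is deliberately conservative near the origin, preferring to
call a true X tag autosomal over the reverse. Consequently X-tag recovery
is depth-dependent by construction: tags whose standardized female coverage
is of the same order as the intercept fall below the line's reach. The
classification property suite therefore runs in the clearly separated
cluster regime (mean standardized totals of a few hundred) where the rule's
geometry, not noise, decides; at lower depth recovery degrades gracefully
and the `unknown` class absorbs the weakest tags. The four constants are
calibrated to a ~24-individual panel at several million reads each and are
exposed as arguments for other designs.

## Genotype QC

Two filters are applied before any statistic (`apply_genotype_qc()`):

* **Depth**: calls with per-cell depth below 10 are masked (set missing,
  never altered); sites left with no call are dropped. The threshold is
  inclusive — depth exactly 10 passes — matching the semantics of a
  minimum-stack-depth flag of 10 rather than a strict "more than 10"
  reading, which is what such a pipeline actually executes. Hemizygous
  calls pass the same rule as diploid calls.
* **Position**: SNPs beyond base 90 of the 92-base tag are removed. The
  "first 90 bases" restriction and the final-two-base blacklist coincide
  for 92-bp tags and are treated as one rule.

Both filters are idempotent and commute; the QC report checks that
per-filter removals account exactly for the total.

## Diversity statistics

**Per-site π** is the unbiased estimator `n/(n−1) (1 − Σ p_i²)` over the
group's called allele copies — equal to the mean pairwise difference rate
over all pairs of copies. **Group π** divides the summed per-site values by
the number of *evaluable bases*, counting invariant bases: a tag is
evaluable for a group when at least `min_copies` (default 2) allele copies
pass the same depth rule as the genotype filter (copies are sex-aware:
males contribute one X copy, females two and no Y), and each evaluable tag
contributes its first 90 bases. This makes the "bases" denominator an
explicit, testable definition.

**Polymorphic** sites segregate ≥ 2 alleles within the colony's called
copies; **private** alleles are observed in exactly one colony (F1 hybrids
excluded on both sides). Note that under this definition a fixed difference
is private without being polymorphic, so no inequality between the two
counts is asserted. **Heterozygosity at polymorphic sites** is the fraction
of called diploid individuals that are heterozygous, averaged over the
group's segregating sites; hemizygous calls are excluded, so the statistic
is undefined (reported `NA`) for Y markers, where only males carry a copy.
An alternative "haploid mismatch" convention exists in the literature but
is deliberately not computed.

**F_st** is Weir–Cockerham θ with ratio-of-sums aggregation across SNPs.
Autosomal sites use the diploid estimator (variance components a, b, c,
with the observed-heterozygosity correction); X/Y sites use the haploid
allele-copy estimator (no within-individual level). Negative per-site
components are retained — only the final ratio is clamped to [0, 1] for
reporting. Other pipelines report AMOVA-style F_st, which differs slightly;
exact numerical agreement with values computed by such tools is not
expected even on identical data.

## PCA and F1 intermediacy

`genotype_pca()` re-implements the standard genotype PCA directly: diploid
dosages (0/1/2) at polymorphic autosomal SNPs are centered by `2p̂` and
scaled by `sqrt(p̂(1−p̂))` with `p̂` estimated from called copies; missing
entries are mean-imputed; the sample–sample covariance is eigendecomposed.
Sex-linked SNPs are excluded by default (hemizygous dosages are not
exchangeable with diploid ones); a `haploid = "double"` option exists.
Determinacy up to eigenvector sign is resolved by orienting each
eigenvector so its largest-magnitude sample coordinate is positive.
Percent variance is defined over the positive eigenvalues and sums to 100;
this definition is self-consistent and documented rather than matched to
any particular external convention. `f1_intermediacy()` asks, per F1 and
per leading eigenvector, whether the F1 coordinate lies in the closed
interval between its two parental colony centroids.

## Tag-versus-genome divergence

Given alignments of the tag catalog against an assembly, only *primary,
full-length, ungapped* placements are kept: the CIGAR must be a single
match run covering all 92 bases. Indel-containing alignments are treated as
partial, because substitution counting over fixed tag coordinates is only
well-defined without indels. Substitutions are located from the MD string
when present (else by sequence comparison against a supplied genome),
mapped back to tag orientation on minus-strand placements, and counted
within the first 90 tag bases only. Ambiguity codes (`N`) on either side
never count. `naive_align()` is a test-scale exhaustive ungapped scanner
over both strands (built on `Biostrings::matchPattern`) used for demos and
for verifying the counting against planted truth; production alignments
from an external aligner are consumed as plain SAM.

## The synthetic-data generator

The generator defines the study conditions and is itself tested code:

* **Panel**: 12 animals (7 F, 5 M) in the youngest colony, two older
  colonies of 5 (2 F/3 M and 3 F/2 M), plus two F1 hybrids of a dam from
  the most-bottlenecked colony and a sire from the intermediate one — the
  sampling design of a small three-colony gerbil study.
* **Colony histories**: all three colonies derive from one base pool.
  Census sizes and generation counts during maintenance are not recorded
  for real colonies of this kind; the defaults (roughly two generations per
  year, breeding census 12–30, one extra transfer bottleneck for the oldest
  colony) are plausible guesses for university colonies, labelled as such,
  and chosen once. Drift is per-marker binomial Wright–Fisher on allele
  frequencies — an individual-based pedigree would add no signal any
  computed statistic can see. Copy numbers are class-aware (2N autosomal,
  1.5N X, 0.5N Y under a balanced sex ratio) and fixation is absorbing.
* **Markers**: 3,000 autosomal, 300 X and 300 Y tags by default; 97% of
  tags are monomorphic in the base pool, matching the SNP sparsity of real
  GBS catalogs (tens of thousands of SNP tags among hundreds of thousands)
  and stressing the invariant-base denominator in π. Polymorphic tags carry
  1–2 SNPs (mean 1.25) at uniform positions; alternate-allele frequencies
  are uniform on (0.05, 0.5) by default.
* **Coverage**: individual efforts are lognormal around 7.8 million reads.
  Depth overdispersion has two sources: a per-tag lognormal
  capture-efficiency multiplier (sdlog 0.6) shared by all individuals —
  the dominant, tag-driven component of GBS depth variance — and a
  residual per-cell negative-binomial dispersion (0.05, mild
  extra-Poisson). Expected depth scales with copy number over two, so X
  tags average half depth in males and Y tags are always zero in females.
  A dispersion of exactly 0 with the lognormal noise disabled yields
  deterministic rounded depths, which the tests use as a degenerate check.
  Efforts are not constrained to equal the column sums of the simulated
  tag-depth matrix (the real total includes reads outside the modelled
  catalog).

What the generator does **not** emulate: read-level errors and FASTQ
structure, restriction-site dropout and allele dropout correlated with
polymorphism, PCR duplicates, new mutation during colony history, linkage
between tags, and the heavy tail of repetitive-region coverage. Passing
tests therefore demonstrate correctness of the estimators and rules under
the stated sampling model, not robustness to every artifact of real GBS
libraries.

## Numerical choices and problem sizes

Seeds are mandatory and all runs are bit-reproducible. Filters only mask
or remove, never alter calls. Sites with fewer than two called copies are
excluded from both numerator and denominator of π; F_st sites need calls
in both colonies (and mean sample size > 1 diploid); the genome-wide θ is
a ratio of sums, not a mean of ratios. Ties in the naive aligner resolve
to the plus strand, then the first contig, then the lowest coordinate.

Test and demonstration problem sizes were chosen so the whole suite runs
in about a minute of CPU: classification recovery uses 5,000 markers per
class on a 12F/12M panel; drift recovery uses 5,000 loci, two replicate
colonies of census 25 drifting 10 generations (expected F_st
`1 − (1 − 1/50)^10 ≈ 0.183`, checked within three Monte-Carlo standard
errors estimated by loci blocking); π and F_st estimators are checked
against brute-force pair enumeration and an independently coded
nested-ANOVA oracle (the latter exhaustively over all 3^6 two-population
three-diploid configurations); PCA against a dense SVD solver at 10^-10.

## Known limitations

* The classifier constants reproduce one study's calibration; other
  sequencing designs need recalibration (arguments are exposed).
* Y-marker heterozygosity is undefined under the diploid-only convention.
* Private-allele counts depend on which colonies are co-analysed.
* The haploid F_st estimator ignores any within-individual structure by
  construction; mixed-ploidy sites (X) use all copies.
* `naive_align()` is exhaustive and intended for fixture-scale genomes;
  real assemblies should be aligned externally and imported as SAM.
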