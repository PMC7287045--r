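---
title: "Harmonizing multi-caller SV call sets: models and methods"
author: "SVHarmony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing multi-caller SV call sets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical machinery of the package: the
replication-rate model, the per-caller filtering rules, the graph
procedures for redundancy collapsing, stitching and unification, the cohort
QC tests, and the synthetic-data generator the test suite is built on. It
also records the numerical conventions and the design choices made where
the problem was genuinely open.

## Replication rate from genetic replicates

Two samples sharing one donor genome — monozygotic twins, or a fibroblast
line and the iPSC clone reprogrammed from it — must carry the same germline
genotype at every site. Genotype discordance between such a pair can only
come from genotyping error (or somatic change, see Limitations). The
replication rate of a site is therefore

$$\mathrm{RR} \;=\;
\frac{\#\{\text{pairs with matching non-reference genotypes}\}}
     {\#\{\text{pairs with at least one non-reference genotype}\}},$$

computed only over pairs with genotypes in both members. A pair with two
reference genotypes says nothing about sensitivity or genotyping of the
variant and is excluded from both counts.

Two readings of "matching" are implemented. The default, `strict`, demands
identical non-reference genotypes (a het/hom-alt pair is a mismatch); the
alternative `nonref_only` counts any doubly non-reference pair as a match.
Strict is the conservative reading and the package default; both are
exposed because the definition of concordance for the het/hom-alt case is a
genuine ambiguity. For multiallelic CNVs, genotype means integer copy
number and non-reference means different from the modal copy number across
samples — the non-mode framing that also underlies the NMAF frequency
measure (`nmaf()`).

A useful fact exploited by the test suite: conditional on a pair being
informative, matches are independent Bernoulli draws, so the expected
per-site RR under a symmetric genotype-error model with per-member error
$e$ equals $p_{\text{match}}/p_{\text{informative}}$, which can be
enumerated exactly over genotype × error outcomes. The suite checks the
empirical mean RR against this closed form at $e \in \{0, 0.02, 0.1\}$
(2,000 sites × 100 pairs) within three Monte-Carlo standard errors.

## Per-caller hard filters

Filters are deliberately literal translations of per-caller rules, with
every threshold in a single configurable object (`defaultFilterConfig()`):

* **SpeedSeq/LUMPY** — deletions under 418 bp need split-read support;
  non-BND events must span ≥ 50 bp; breakends need 25% of their supporting
  evidence (SU) from split or paired-end reads; inversions with QUAL > 100
  need ≥ 10% split/paired-end evidence; sites with > 10% missing genotypes
  are dropped; class-specific MSQ thresholds are strictly-greater
  comparisons (DEL/rMEI > 20, DUP > 100, INV/BND > 90).
* **Genome STRiP CNVDiscovery** — minimum GSCNQUAL (at-least comparisons)
  of 2/12/14 for DEL/mCNV/DUP; monoallelic sites removed; sites with > 10%
  low-quality (LQ) genotypes among non-iPSC samples removed. iPSC samples
  are excluded from the LQ fraction because they are genotyped outside the
  discovery runs.
* **LCNVDiscovery** — NBINS ≥ 10 and SCORE ≥ 1000; sites inside (or fully
  containing) a centromere removed; carrier copy number > 2.75 (DUP) or
  < 1.25 (DEL).
* **MELT** — any of the lc/s25/rSD/hDP flags excludes a record, and the
  ASSESS tranche must equal 5.
* **HipSTR** — five call-level thresholds (call quality ≥ 0.9, flank-indel
  and stutter fractions ≤ 0.15, allele and strand bias ≥ −2) convert
  failing genotypes to missing rather than dropping the site; the site then
  needs > 80% call rate within every genotyping subset.
* **wham/manta** — QUAL ≥ 250.

The comparison directions (strict `>` for MSQ, `≥` for GSCNQUAL and QUAL)
follow the wording of each rule and are covered by boundary tests (MSQ
exactly 20 fails, GSCNQUAL exactly 2 passes, QUAL exactly 250 passes, a
417 bp deletion without split reads fails while 418 bp passes).
Every filter returns a report that accounts for each input record exactly
once with an ordered list of failed-rule codes, and all filters are
idempotent.

## Graph procedures

All redundancy operations share two primitives: reciprocal overlap
(interval arithmetic delegated to IRanges) and genotype-evidence
correlation (Pearson, pairwise-complete). A correlation is *undefined* —
and treated as failing its threshold — when fewer than two complete
observations remain or either vector is constant: a monomorphic genotype
row carries no linking evidence, so it must not create an edge.

* `dedupSpeedseq`: edges need reciprocal overlap ≥ 0.5 **and**
  allele-balance correlation r > 0.25; nested calls additionally connect
  when allele balance correlates at r ≥ 0.5. Within each connected
  component the maximal-MSQ record is primary.
* `dedupGenomestrip`: cross-discovery-set pairs are redundant at RO ≥ 0.5,
  non-iPSC copy-number correlation > 0.95, and < 5% differing copy numbers
  among the union of non-mode samples. Exact-coordinate pairs are resolved
  first; the rest greedily by descending average percentage overlap.
* `stitchGenomestrip`: per chromosome, copy-number correlation > 0.9 builds
  components; position-sorted adjacent pairs merge when they additionally
  show ≥ 80% non-mode concordance and lie within 30 kb. The 30 kb gap is
  the published operating point of this trade-off and is a parameter
  (`maxGap`). A stitch spans the first constituent's start to the last
  one's end; `validateStitch` keeps it only if its genotypes correlate with
  the constituents at mean r ≥ 0.9, carry ≤ 10% LQ flags and are
  polymorphic. The pipeline genotypes new stitch breakpoints with the row
  of the highest-GSCNQUAL constituent — a documented stand-in for
  re-genotyping the new interval from reads, which is out of scope.
* `clusterLcnv`: per-sample long-CNV calls cluster at RO ≥ 0.8; the merged
  site spans min start to max end and copy numbers are rounded to integers.
* `buildUnifyGraph` (Genome STRiP × SpeedSeq): stage 1 connects
  type-compatible pairs (mCNV↔DEL/DUP, DEL↔rMEI allowed) with RO > 0.5 or
  full containment where the smaller spans ≥ 40% of the larger; stage 2
  re-tests all pairs within each stage-1 component on squared
  genotype-evidence correlation > 0.5, relaxed to > 0 for components
  pairing a SpeedSeq DUP and DEL with a Genome STRiP mCNV (the biallelic
  caller splits a multiallelic locus into complementary views whose
  evidence correlates weakly with copy number). Primary selection is
  degree-then-quality per caller, Genome STRiP by default (integer copy
  numbers, higher replication), SpeedSeq when its rMEI pairs with a
  read-depth deletion. The mixed-mCNV exemption is detected per stage-1
  component, not per pair.

Design choices worth recording: "genotype evidence" across callers is the
caller's native channel (copy number vs allele balance), so the stage-2
statistic is a squared cross-channel Pearson correlation over shared
samples — the sign is meaningless across channels, hence $R^2$.
Degree/quality ties break toward the lexicographically smaller site id, and
components are processed in (chrom, start, id) order, making all outputs
independent of input order. The threshold sweep
(`unifyParameterSweep`) varies the pure reciprocal-overlap rule with the
containment shortcut disabled, so merged counts are monotone in both
thresholds and a threshold above every overlap merges nothing.

## Cohort QC

Batch-effect testing compares per-site genotype (or copy-number) category
counts between the two collections with a contingency chi-squared test
without continuity correction; missing genotypes form their own category,
since differential missingness is itself a batch artifact. Categories with
zero total count are dropped (equivalent to pooling cells with zero
expectation). Hardy–Weinberg testing compares observed genotype counts at
biallelic sites to expectations at the estimated allele frequency
(chi-squared, 1 df), using unrelated blood/fibroblast samples only — iPSC
clones are excluded because reprogramming-associated somatic CNVs violate
the population model. Both flag at Bonferroni-corrected p < 0.05 with m =
number of sites actually tested, and both *annotate* rather than remove.
mCNVs are batch-tested on their full copy-number category distribution.

## The synthetic study

`simConfig()` defines the generator. Its defaults are the study design the
package targets: two collections (an iPSCORE-like collection with 25
monozygotic twin pairs of blood samples and a HipSci-like collection with
152 fibroblast–iPSC pairs), 300 donors in total, on a 3 × 10 Mb synthetic
genome; planted SV loci of every class with allele frequencies in
0.05–0.5; and per-caller views with:

* breakpoint jitter bounded by 20 bp (50× that for long CNVs);
* symmetric genotype error with probability
  $e(q) = e_{\max}\,\sigma((q_{\text{mid}} - q)/s)$, a logistic schedule in
  the site's simulated quality score ($e_{\max} = 0.3$,
  $q_{\text{mid}} = 40$, $s = 12$ on a 0–100 quality scale). This single
  mechanism produces the monotone RR-versus-quality curves that the
  threshold sweeps and filter selection rely on; it is deliberately steeper
  than real callers so that desk-scale cohorts still show the effect.
* read-depth fragmentation: 20% of sufficiently long CNVs are emitted as
  2–5 adjacent fragments with gaps up to 5 kb and identical genotype rows
  (stitching targets);
* within-caller duplicate emissions (10%) and mCNV loci seen by the
  split-read caller as DUP + DEL pairs (25%) — deduplication and
  unification targets;
* MELT flags drawn with the configured probabilities, flagged sites
  carrying 6-fold elevated error (so flag filtering visibly improves RR);
* planted false positives with low quality scores and random genotypes;
* probe intensities $\alpha(\mathrm{cn}-2) + \text{batch} + \text{plate} +
  N(0, \sigma)$ with ≥ 3 probes per testable CNV, and a SNP panel in which
  designated SVs have one tagging SNP within 50 kb equal to the SV dosage
  up to a per-sample flip probability.

Every emission is a deterministic function of (config, seed), and every
emitted record links to its truth site, enabling exact cluster-recovery
scoring. What the generator does **not** emulate: read-level evidence,
sequence content and repeat structure, realistic SV size/frequency spectra,
somatic variation between fibroblast and iPSC samples, and sex chromosomes
(the pipeline, like the RR analysis it supports, is autosomal). Passing
tests therefore demonstrate correctness of the harmonization logic under a
controlled error model, not caller-level performance on real genomes.

## Numerical conventions and degenerate inputs

* Intervals are `GRanges` (1-based, closed); VCF POS..END map directly to
  the internal interval, so `width()` equals the event length. Breakend and
  insertion classes are 1 bp point records matched by breakpoint distance
  (≤ 50 bp) rather than span; insertion co-discovery additionally requires
  a length ratio under 2.
* Undefined correlations never create edges (see above); all-missing pairs
  drop out of RR; an all-zero contingency table or an empty genotype vector
  yields NA statistics, never an error.
* The IRS per-site statistic sums carrier ranks over probes and treats the
  pooled sum as a rank-sum over probe-sample units: mean
  $\sum_p n_c(N+1)/2$ and variance $\sum_p n_c n_n (N+1)/12$ (sampling
  without replacement per probe), normal approximation with a 0.5
  continuity correction, one-sided in the class direction (deletion
  carriers lower, duplication carriers higher; mCNVs use the dominant
  direction of their non-modal copy numbers). The combination rule is this
  package's construction — the reference annotator does not publish its
  formula — and is validated by permutation calibration (KS uniformity at
  500 null sites) rather than by equation matching. The call-set FDR
  estimate is $2\,\Pr(p \ge 0.5)$, with both the factor and the cut point
  configurable.
* Sites are tested against array probes only with ≥ 3 probes and ≥ 1
  carrier; skipped sites carry a reason code.

## Problem sizes used by the checks

The suite exercises: RR against brute-force enumeration at 1,000 sites ×
50 pairs; the closed-form error model at 2,000 sites × 100 pairs;
clustering against hand-rolled union-find oracles on 20 random instances
per operation at 30–100 records; stitch recovery on 200 fragmented parents
plus 200 decoys; QC calibration on 500 null replicates of 40 sites × 370
unrelated samples; IRS calibration on 500 null sites; and two full
pipeline runs for byte-identity. These sizes make the whole suite run in a
few minutes while keeping Monte-Carlo margins meaningful.

## Known limitations

* Fibroblast–iPSC pairs carry genuine somatic differences in real data;
  the generator treats them as perfect replicates. Real RR in such pairs is
  a lower bound on genotyping reproducibility.
* Sex-chromosome handling (separate male/female correlation in
  deduplication) is not implemented; the pipeline is autosomes-only.
* New stitch breakpoints are genotyped by proxy (best constituent row)
  rather than re-genotyped from reads.
* The half-missing genotype states some callers emit are treated as
  missing for all counts.
* MELT's rSD/hDP flags are consumed as given; their internal denominators
  are not recomputed.
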