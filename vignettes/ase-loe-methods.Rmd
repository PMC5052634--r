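---
title: "Detecting extreme allele-specific expression and biallelic loss of expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting extreme allele-specific expression and biallelic loss of expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Disease genes can act through expression rather than protein sequence: one
allele of a heterozygous gene may be silenced or amplified (allele-specific
expression, ASE), or both alleles may be strongly downregulated (biallelic
loss of expression, LOE). Either can produce a functionally null gene in a
tissue even when the coding sequence looks intact. `cardase` implements a
discovery procedure for both phenomena from bulk RNA-seq of a case/control
cohort, given each subject's heterozygous SNPs (from DNA sequencing or
arrays) and per-gene read counts per tissue sample. It was designed with
cardiovascular tissue from congenital heart disease cohorts in mind, but
nothing in the machinery is heart-specific; the fetal-heart expression
reference is simply "the reference expression table for the tissue of
interest".

Permissive ASE definitions (any statistically unbalanced allele ratio) call
hundreds of events per tissue, most of them irrelevant or artifactual. The
procedure here is deliberately stringent: it targets *extreme* ASE — near-
monoallelic expression of genes that are normally biallelic — and couples
every statistical call to an aggressive quality-control cascade, because the
dominant failure mode of allele-specific read counting is not sampling noise
but reference-alignment bias.

## The compound allele-ratio statistic

Reads at each heterozygous SNP of a gene are assigned to one of four
categories, by inheritance and expression:

* maternal reads and paternal reads, for SNPs whose alternate-allele
  parental origin is known (trio phasing or phased genotypes);
* higher-allele reads and lower-allele reads, for unphased SNPs, under the
  assumption that the more highly expressed base at every SNP of a gene
  lies on the same haplotype.

With per-gene sums `mat`, `pat`, `higher`, `lower`, the compound allele
bias is

* `(higher + mat) / (lower + pat)` when `mat > pat`,
* `(higher + pat) / (lower + mat)` when `pat > mat`,
* `higher / lower` when there is no phased signal (`mat == pat`,
  including both zero).

A zero denominator with covered numerator is reported as an infinite bias
and treated as monoallelic. Significance uses a two-sided exact binomial
test on the numerator/denominator read totals with null probability 0.5,
Bonferroni-corrected by the number of genes containing covered heterozygous
SNPs in the same sample. A gene in a sample has **extreme ASE** when

* compound allele bias ≥ 7.2,
* corrected binomial P < 0.01, and
* the higher allele has ≥ 5 reads.

The 7.2-fold / 5-read operating point is validated in code on fully phased
synthetic cohorts (`evaluate_phasing_grid()`): because the higher-allele
assignment can only err by mixing haplotypes, a call made without phase is
checked against the fully phased recomputation, and the false-assignment
rate at the operating point is required to stay under 2% while being
monotone in both thresholds. `phased_unphased_concordance()` confirms that
strong events are called identically with and without phase.

### Numerical choices

* **Sidedness.** The binomial P is two-sided (doubled upper tail, capped
  at 1). The expression analysis pins the convention: its LOE threshold
  `P < 2.7e-3` is stated as equivalent to `z < -3`, which only holds for
  a two-sided normal tail.
* **Tied SNPs.** An unphased SNP with equal ref and alt reads carries no
  direction; it contributes to neither sum (any deterministic assignment,
  e.g. toward the reference base, would reintroduce reference bias) but
  still counts toward the SNPs used.
* **Tied parental sums.** When `mat == pat` with both nonzero, the
  statistic falls back to the unknown-inheritance form; the directional
  folding is defined only for strict inequality.
* **The Bonferroni divisor** is the count of genes with ≥ 1
  coverage-passing het SNP in the sample, taken *before* gene-level
  category filters — the earlier stage gives the larger, more
  conservative divisor.
* **Anti-conservatism.** Summing per-SNP maxima inflates the numerator on
  null genes with several low-depth SNPs, so the raw binomial P is
  anti-conservative by construction. The joint rule (bias ≥ 7.2 and
  corrected P < 0.01 and depth ≥ 5) is what controls false calls; the
  null-calibration test demonstrates this empirically over 20 seeded null
  cohorts rather than assuming the P value is honest on its own.

## The QC cascade

Filters run in a fixed order and only annotate; no filter modifies counts.
Every measurement carries the full list of filters it failed.

| Filter | Rule (defaults from `qc_config()`) |
|---|---|
| genotype quality | GQ ≥ 50 and DNA allele balance in [0.2, 0.8] (inclusive); records missing GQ/AB (array genotypes) are passed with a note |
| coverage | ≥ 5 RNA reads, or both alleles expressed |
| clustered | ≥ 2 other het SNPs within 30 bp |
| near indel | indel within 30 bp |
| repeat region | precomputed multi-alignment flag (consumed, not computed) |
| alt-spliced exon | SNP's exon present in only a subset of isoforms |
| complex allele | precomputed >2-alleles flag |
| gene structure | single het SNP, > 20 reads, 100% monoallelic (suspect genotype); or > 20% of the gene's other SNPs unexpressed / a coding SNP unexpressed (misalignment) |
| common biased | SNP biased in > 40% of informative subjects of either cohort, ≥ 3 biased subjects; LOF SNPs and known imprinted genes exempt |

Gene-level category filters remove sex-chromosome genes, the enumerated
HLA list, noncoding genes, genes below 2 r.p.m. in the fetal reference,
and "common ASE" genes (ASE in > 5% of subjects including ≥ 1 control) —
the last requires a first calling pass over the whole cohort, so
`run_pipeline()` is two-pass. Subject-level QC removes subjects whose
fraction of biallelically expressed, well-covered SNPs (≥ 10 reads,
ignoring chrX, imprinted genes and alt-spliced exons) falls below 75%.

Two definitions here are the package's own, because the procedure needs
them and no published definition exists at SNP level:

* a SNP measurement is **biased** when its higher/lower ratio is ≥ 7.2
  with ≥ 5 reads on the higher allele — the gene-level operating point
  applied per SNP, used by the common-bias and subject-QC rules;
* **informative subjects** for the common-bias denominator are subjects
  whose measurement at the site passes coverage (a denominator over all
  subjects would dilute rare genotypes), and a subject counts as biased
  if biased in any tissue.

Known imprinted genes are exempted from the common-biased-SNP filter:
under penetrant imprinting every informative subject is biased, so the
recurrence rule would delete exactly the genes the imprinting assessment
is supposed to measure. Their ASE calls are instead set aside from the
candidate (disease-relevant) call set after calling.

## Imprinting

Catalog genes (known imprinted, with fetal-reference expression ≥ 2
r.p.m.) are assessed for ASE with the same machinery. Per gene the
package reports ASE / informative subjects per cohort, the combined
percentage, the expressed parent (majority vote over phased ASE
subjects; conflicts produce "indeterminate" with a warning), and an
in-heart imprinting verdict at ≥ 50% ASE. The membership rule reads
"50% of cases and controls" as the combined-cohort fraction — the
reading consistent with published per-gene tables whose two cohorts have
very different denominators — with the stricter per-cohort reading
available behind `per_cohort = TRUE`. `parental_bias_tests()` then
cross-classifies maternally vs paternally expressed catalog genes by
their in-heart verdict with the package's own conditional Fisher exact
test (`fisher_exact_2x2()`, enumeration of the hypergeometric support;
verified in tests against `stats::fisher.test` and an independent
exhaustive oracle).

## Nonsense-mediated decay

For heterozygous LOF variants (nonsense, frameshift, splice — pooled, as
all three can trigger decay), `call_nmd()` tests whether the LOF-carrying
allele is under-expressed: normal/LOF ratio strictly > 4, two-sided
binomial P Bonferroni-corrected by the number of heterozygous LOF
variants in the subject (not the genome-wide gene count — decay of a
specific known variant is a targeted hypothesis), corrected P < 0.01.
Direction matters: an extreme ratio with the LOF allele higher is never
NMD.

## Expression analyses

Expression is quantified as reads per gene per million aligned reads
(r.p.m.; a gene is "expressed" at ≥ 2 r.p.m.). Each sample is compared
with all other samples of the same tissue type by leave-one-out mean and
standard deviation (n−1 estimator), giving fold change and z-score with
a two-sided normal P. Tissue groups need more than four other samples;
samples with more than 100 extreme differences (fold < 0.2 or > 5 at
P < 0.05) fail sample QC.

The classification thresholds are derived, not tuned, and the
derivations live in code (`ase_down_fold()` etc.) with tests asserting
the arithmetic: a silenced allele halves output, so downregulated ASE
expects fold ~0.5, relaxed 30% for cohort heterogeneity to
0.5 + 0.5×0.3 = 0.65; gained-allele expression mirrors the 7.2 ratio,
7.2 − 7.2×0.3 = 5.04, rounded to the integer threshold 5; the LOE
significance level is the two-sided tail at z = −3, 2·Φ(−3) ≈ 2.7e-3.

Biallelic LOE calls additionally require candidacy: the gene's
leave-one-out mean in the upper quartile of expressed genes for the
tissue group, and "tightly regulated" expression, implemented as
coefficient of variation ≤ 0.5 within the group — a modeling choice of
this package, since no quantitative definition of tight regulation is
standard. A polyadenylated-transcript restriction is available for
polyA-selected libraries. The LOE call itself is fold < 0.1 with
P < 2.7e-3.

`burden_fisher()` compares hit counts between cohorts with explicit
denominators; the caller must decide whether subjects or samples are the
unit, because collapsed published counts rarely state it.

## The synthetic cohort generator

`generate_cohort()` produces the study conditions every stage is tested
under: a default of 200 genes × 24 subjects (16 case, 8 control) × 2
tissues, so the full pipeline runs in seconds, with

* a panel of shared SNP sites per gene (8, heterozygous per subject with
  probability set by the 3-SNPs-per-gene mean), so that sites recur
  across subjects as real polymorphisms do — the cohort-level filters
  are meaningless otherwise;
* per-SNP read depth Poisson(50) per tissue, and allele counts drawn
  binomially: reference fraction 0.5 under the null, the configured
  fraction for event SNPs, with the over-expressed base placed
  consistently on one haplotype per gene (the cis structure the phasing
  heuristic exploits). Sampling is pure binomial because that is the
  model the test assumes; a beta-binomial overdispersion knob exists for
  robustness studies and is off by default;
* events injected with truth labels: extreme ASE (allele fraction
  ≥ 0.88, optionally with a total-expression fold for integration
  tests), imprinting (expressed parent with per-subject penetrance),
  NMD (a nonsense site whose allele is expressed at ≤ 0.2), and LOE
  (expression and SNP depth scaled by fold ≤ 0.1);
* mapping-bias contamination injected at SNP *sites*, not per subject,
  because alignment bias is a property of the locus; contaminated sites
  get positional artefact flags with probability 0.8, leaving the
  remainder for the cohort common-bias filter to catch — together they
  reproduce the signature of reference bias appearing before QC (~87%
  of biased SNPs expressing REF) and vanishing after (~50%);
* expression counts log-normal around gene × tissue means
  (within-group CV ~0.15, so leave-one-out z-scores are meaningful),
  with LOE event genes pinned to the 95th percentile of baseline
  expression so injected knockdowns genuinely satisfy the
  upper-quartile candidacy the LOE-recovery property is conditioned on;
* trio subjects (fraction 0.25 by default) with known parental origin
  of every alternate allele; haplotype A is maternal by convention.

Everything is a pure function of the config, including its seed; the
same config is byte-identical on regeneration.

What the generator does **not** emulate: raw reads and base-level
alignment artefacts (contamination is injected at the count level),
realistic splice structure (alt-spliced exons are a per-site flag),
linkage between sites, realistic sequencing-platform depth profiles
(the defaults are chosen for test power, not fidelity to any published
depth distribution at heterozygous SNPs), or
somatic variation. Passing the recovery tests therefore shows the
statistics and filters are implemented correctly and calibrated under
their own assumptions — not that the pipeline is robust to every failure
mode of real RNA-seq.

## Problem sizes and determinism

The test suite and the acceptance script use cohorts of 40–200 genes and
8–24 subjects, 20 seeded null cohorts for ASE calibration and 100 seeded
cohorts for LOE null behaviour; these sizes were chosen so each property
is measured on hundreds-to-thousands of gene × sample units while the
whole suite stays interactive. All randomness flows through
`simulation_config(seed = ...)`; the acceptance script derives every
cohort seed from its `--seed` argument.

## Known limitations

* The higher-allele phasing heuristic is anti-conservative for genes
  with many shallow SNPs; the joint calling rule compensates, but raw
  binomial P values should not be interpreted in isolation.
* Single-SNP genes cannot distinguish ASE from allele-specific splicing
  or genotyping error beyond the single-SNP-monoallelic filter.
* The common-ASE gene filter needs ≥ 1 control subject with the event;
  in cohorts without controls it never fires.
* Published fold/P values recomputed from rounded summary tables
  reproduce to the second decimal and to order of magnitude
  respectively; exact reproduction from rounded inputs is not possible.
* `expression_comparison()` treats the reported group mean/sd as exact;
  it does not propagate their rounding error.
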