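---
title: "Identifying m6A reader targets from editing and crosslink data: models and methods"
author: "tribeclip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying m6A reader targets from editing and crosslink data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

YTH-domain reader proteins bind N6-methyladenosine (m6A) in mRNA, and two
orthogonal technologies locate where. HyperTRIBE fuses the reader to a
hyperactive ADAR catalytic domain so that bound transcripts accumulate
A-to-I edits, read out as A-to-G mismatches in RNA-seq; targets are sites
edited significantly above a free-ADAR control. iCLIP UV-crosslinks the
reader to RNA and maps the contact at single-nucleotide resolution.
`tribeclip` implements the downstream computation for both assays —
differential-editing calling with the field's filters, crosslink-site
post-processing, PWM-based motif geography around methylation and
crosslink sites, gradient-boosted motif-window classification, and
cross-method target comparison — together with a seeded synthetic-data
generator so that every stage is testable without the deposited
sequencing data.

## The synthetic-data generator

`sim_config()` fixes the study conditions the package is tested under.
Each synthetic gene is a single-isoform transcript (contiguous 5'UTR, CDS,
3'UTR; uniform lengths 100–200, 600–1200 and 250–400 nt), placed on a
plus or minus strand with equal probability so that every strand-aware
code path is exercised. Transcript sequence is drawn from the base
frequencies used throughout the motif analysis (A 0.273, C 0.165, G
0.173, U 0.389). A configurable fraction of genes (default 0.4) are true
reader targets; each target 3'UTR receives on average two methylation
sites, each planted as the invariant A of a concrete DRACH (80%) or GGAU
(20%) instance, with UNUNU 15 nt upstream and YYYYY 8 nt downstream —
the "DRACH/GGAU island in a pyrimidine-rich neighbourhood" structure the
motif analyses are designed to detect. Planted sites keep at least 140 nt
apart so they survive the classifier's 120-nt redundancy reduction.
Crosslink sites are displaced from their methylation site by a normal
draw centred 11 nt 5' (sd 3 nt), matching the observed 5' shift of
reader crosslinks relative to methylation marks.

Editing counts are beta-binomial: at true sites the fusion samples edit
at `ep_target` (default 0.25, deliberately low — editing proportions in
this assay are small) over a sequencing-error background `ep_background`
(0.01) shared by control samples and null sites, with intra-class
correlation `bb_overdispersion` (0.01). The matrix mimics a mismatch
pileup: only positions with at least one mismatching read in at least
one sample are kept. SNP artifacts are planted at a rate of 0.05 per true
site: a position whose editing proportion is drawn in [0.9, 1] across
every sample of one randomly chosen line group, which is exactly the
signature the SNP filter must remove. A small fraction of null positions
carry non-A-to-G mismatches to exercise the base-identity filter. The
paper behind this design does not state a generative model for counts;
the beta-binomial and all rates above are this package's own choices,
made once. All randomness flows from a single integer seed, and
generation is bit-reproducible.

What the generator does *not* emulate: isoforms and splicing (one
transcript per gene), overlapping genes, read-level artifacts
(mapping bias, strand bleed-through), copy-number variation in
line-specific SNPs, and any coupling between expression level and
coverage. Passing tests therefore demonstrate correctness of the
computation under the stated statistical structure, not robustness to
every pathology of real libraries.

## Differential editing

Editing proportion is G/(A+G) on the sense strand (equivalently C/(U+C)
read from the minus strand), zero when there is no coverage. Per site
the test compares a pooled beta-binomial editing rate against separate
fusion/control rates by likelihood ratio, one-sided for fusion >
control. Two numerical choices matter at the counts this assay actually
produces (tens of reads, editing proportions of a few percent):

* **Shared overdispersion.** A per-site overdispersion estimate from ten
  samples with ~5 edited reads is essentially noise, and plugging it
  into the likelihood makes the chi-square test badly anticonservative
  (9% empirical type-I at nominal 5% in our calibration). Instead one
  overdispersion is estimated per matrix by a within-condition Pearson
  method of moments pooled across all sites — the same borrow-strength
  logic dispersion-moderating RNA-seq testers use.
* **Bootstrap calibration.** Even with a good dispersion value the
  chi-square reference is unreliable for statistics built from a handful
  of reads. P-values are therefore computed by a per-site parametric
  bootstrap (default 199 replicates) under the fitted null (pooled rate,
  shared overdispersion), with the signed likelihood-ratio statistic as
  the test statistic. The asymptotic tail is used only when the
  chi-square p-value is already below 1e-4 — far beyond the bootstrap's
  resolution, where the ranking rather than calibration is what matters.
  Type-I error sits at 5.3–6.1% across calibration seeds, inside the
  binomial 99% interval.

The replicate-support rule — a site must show at least one edited read
in at least four of five fusion replicates — screens sites before
testing. The type-I calibration is run with the screen disabled: the
rule deliberately selects sites with randomly elevated fusion editing,
so the p-value distribution of screened-in null sites is biased by
construction; it is a screening device, not part of the null model.
Benjamini-Hochberg adjustment runs across all tested sites; significance
requires adjusted p < 0.01 and log2 fold change > 1, where the fold
change is on condition-mean editing proportions with pseudocount 0.001
(the source analysis does not state its pseudocount).

Three post-filters mirror the published chain: (1) only A-to-G on the
plus strand or T-to-C on the minus strand survive; (2) sites with an
editing proportion at or above 0.9 in either condition are removed as
likely line-specific SNPs ("at or close to 1" is implemented as a
configurable 0.9); (3) sites with fewer than 10 reads of summed fusion
coverage are removed. Annotation assigns each site to the overlapping
gene with the highest TPM, breaking remaining ties lexicographically for
determinism, and records the gene-body feature and relative position.

## Crosslink-site post-processing

Directly adjacent called peaks (consecutive genomic positions, same
strand) collapse to the peak with the highest score; score ties keep the
5'-most position (the caller is silent on ties; this is the
deterministic choice). Collapsed peaks extend ±4 nt into 9-nt collapsed
crosslink sites. The IDR-dependence split compares full-length-protein
and truncated-protein libraries: a full-length site with a truncated
site within 10 nt is IDR-independent, otherwise IDR-dependent. All
nearest-neighbour distances here are unsigned positional differences
(|pos1 − pos2|), not inter-range gaps; signed, strand-oriented offsets
are used only in the motif distance profiles.

## Motif geography

PWMs are log2(p(b,j)/p(b)) with a small pseudo-frequency (default 0.001).
Catalogue PWMs are seeded from IUPAC patterns: partial ambiguity codes
expand to uniform frequencies over their allowed bases; a fully
degenerate N column is set to the background itself (log-odds exactly
0). The latter departs from uniform-over-allowed on purpose: uniform
0.25 at an uninformative position penalises U (log2(0.25/0.389) < 0) and
pushes exact UNUNU matches below the score-4 threshold, which would make
the catalogue's U-rich motifs invisible to their own scanner. "No
constraint" and "background composition" are the same statement in a
log-odds model. The packaged catalogue of 48 motifs is a synthetic
reconstruction (the curated list is not published in full): all motifs
named in the source literature plus systematic consensus variants and
U/Y-rich tracts, tagged by provenance.

The scanner scores every window on both strands and keeps scores ≥ 4; it
is tested to be identical to exhaustive window enumeration. The original
analysis ran a FIMO scan at p < 0.05 and then filtered to score ≥ 4; for
motifs this short the score filter is the binding constraint, so the
p-value stage is omitted.

Matched backgrounds sample, for each anchor site, one random position in
a non-target gene at the same gene-body feature and relative-position
bin (10 bins per feature), weighted by available positions per bin so
sampling is uniform over eligible nucleotides. The joint (feature, bin)
histogram is preserved exactly, and an unfillable stratum is an error
naming the stratum rather than a silent approximation.

Distance profiles count, at each signed strand-oriented offset d in
[−half_window, +half_window], the anchors whose shifted position overlaps
a motif match at any point, normalised per 1000 eligible anchors; an
anchor leaves the denominator at offsets where its shifted position no
longer overlaps any annotated gene ("any gene" rather than the anchor's
own, following the quoted edge rule). Because overlap is at-any-point, a
planted match of length L produces a plateau of L offsets at the profile
maximum — the tests assert the planted start offset attains that
maximum rather than a unique argmax. Gene-body O/E enrichment divides
the observed bin distribution of match midpoints by that of a seeded
random-position background over the transcript annotation; the default
background is 1e6 positions, a desk-scale version of the published 1e7
(the estimator is consistent, and the package verifies the scaled
version reproduces the same bin pattern).

## Classification

Features are counts of each catalogue motif overlapping three windows
around the anchor — at [−10, +10], up [−60, −11], down [+11, +60] on the
transcript strand (up = 5', negative offsets; the source's Results and
Methods disagree on the up/down interval labels and on the stated 120-nt
total where the windows sum to 121, so the package fixes this layout and
documents it). Counts truncate at 10, then standardise per feature using
training rows only; redundant anchors are reduced greedily (keep the
highest score, drop neighbours within 120 nt) before the matched
background is paired 1:1. One fifth of rows, stratified by label, form
the held-out split.

The learner is gradient boosting with shrinkage 0.05, interaction depth
6 and up to 2000 trees; 5-fold cross-validated AUC on the training rows
selects the tree count. Training is single-threaded, so a fixed seed
gives identical models, importances and AUCs. Importance is total gain
per feature, normalised to sum 100. AUC is the Mann-Whitney rank
statistic with midrank tie handling, verified against pair enumeration.
The bound-vs-unbound contrast labels methylation sites by presence of a
crosslink site within 10 nt and reuses the same feature machinery.

## Target comparison

Overlap tables enumerate every membership pattern over a declared
expressed-gene universe. Expression bins are equal-frequency on
log2(TPM+1) over expressed genes (TPM > 0; the source states no
expression floor), nine bins by default, ties broken by stable gene-id
order; per-bin target proportion is |set ∩ bin| / |bin|. The support
split partitions a target set by membership in the union of support
sets and reports each part's bin distribution.

## Problem sizes and determinism

The test-suite simulations use 30–150 genes for unit checks, a 1000-site
null and a ~520-true + 5000-null-site matrix for the calling
calibration, and a 1500-gene genome yielding 2000 anchors with 2000
matched negatives for the classifier; these sizes give stable
statistics while keeping the full suite to a few minutes. Every
stochastic step takes an explicit seed; internal coordinates are
1-based GRanges with BED emitted 0-based half-open (chosen over a
0-based internal convention because GRanges/IRanges is the idiom of the
toolchain this package composes with).

## Known limitations

* The differential-editing engine is not the published companion
  pipeline; it is a beta-binomial bootstrap-calibrated LRT designed to
  reproduce that pipeline's statistical behaviour (replicate awareness,
  overdispersion tolerance, power at low editing proportions), and
  p-values will not match it numerically.
* Bootstrap p-values have resolution 1/(B+1); far-tail significance
  relies on the chi-square branch.
* Gene annotation assumes one transcript per gene; expression-weighted
  isoform choice is out of scope.
* The motif catalogue is a reconstruction; analyses keyed to exact
  motifs outside the literature-named set reflect this package's
  catalogue, not the original curated list.
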