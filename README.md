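# tribeclip

Target identification for m6A reader proteins from HyperTRIBE editing
data and iCLIP crosslink data, as a tested, reusable R pipeline.

YTH-domain reader proteins bind N6-methyladenosine (m6A) in mRNA. Two
orthogonal assays locate their targets: **HyperTRIBE** fuses the reader
to a hyperactive ADAR catalytic domain so that bound transcripts pick up
A-to-I edits (read as A→G mismatches in RNA-seq over a free-ADAR
control), and **iCLIP** UV-crosslinks the reader to RNA at
single-nucleotide resolution. This package implements the downstream
computation for both, plus the sequence-motif geography that connects
them to the methylation machinery:

* **Differential editing** — per-site beta-binomial likelihood-ratio
  test of fusion vs control editing rates G/(A+G), with a matrix-wide
  overdispersion estimate and parametric-bootstrap p-value calibration;
  replicate-support screen (edit in ≥ 4 of 5 fusion replicates);
  post-filters for base identity (A→G / T→C by strand), SNP-like sites
  (editing proportion ≥ 0.9), and minimum fusion coverage (10 reads);
  BH adjustment, gene annotation by highest expression, PCA, ADAR-TPM
  correlations and single-cell coexpression.
* **Crosslink sites** — collapsing of directly adjacent peaks to the
  dominant one, 9-nt collapsed crosslink sites, IDR-dependence split
  (full-length vs truncated-protein libraries at 10 nt), nucleotide
  proportions, metagene profiles, distance-to-edit-site curves.
* **Motifs** — PWMs as log2(p(b,j)/p(b)) over the background
  (A 0.273, C 0.165, G 0.173, U 0.389), genome scanning at score ≥ 4
  (identical to exhaustive enumeration), exact location-matched
  backgrounds (10 bins per gene-body feature, non-target genes only),
  signed distance profiles per 1000 anchors with a gene-overlap edge
  rule, and gene-body observed/expected enrichment against a
  million-position background.
* **Classification** — motif × window (at ±10 nt / up / down 50 nt)
  count features truncated at 10, gradient boosting (shrinkage 0.05,
  depth 6, ≤ 2000 trees, 5-fold CV), rank-statistic AUC, gain
  importances, top-10 reduced models, and the bound-vs-unbound m6A
  contrast (crosslink within 10 nt).
* **Comparison** — overlap tables over an expressed-gene universe, nine
  equal-frequency expression bins of log2(TPM+1), per-bin target
  proportions, support splits.
* **Synthetic data** — a seeded generator producing annotated genomes
  whose target 3'UTRs carry methylation sites inside DRACH/GGAU islands
  flanked by UNUNU (−15 nt) and YYYYY (+8 nt), crosslink sites displaced
  ~11 nt 5', and beta-binomial editing counts with planted SNP
  artifacts — so the whole pipeline is testable without downloads.

## Worked example

```r
library(tribeclip)

cfg <- sim_config(n_genes = 400, genes_per_chrom = 100, seed = 2024)
sim <- simulate_genome(cfg)
mat <- simulate_editing_counts(sim)
mat
#> EditingMatrix: 2228 sites x 10 samples ( 5 fusion / 5 control )

calls <- test_differential_editing(mat, min_support = 4, seed = 2024)
kept  <- filter_calls(calls, mat)
sum(kept$significant)
#> [1] 246

ann <- annotate_sites(
  GenomicRanges::GRanges(kept$chrom[kept$significant],
                         IRanges::IRanges(kept$pos0[kept$significant] + 1,
                                          width = 1),
                         strand = kept$strand[kept$significant]),
  sim$bundle)
length(unique(na.omit(ann$gene_id)))
#> [1] 163
```

246 sites pass the significance thresholds (adjusted p < 0.01, log2FC >
1) and the three filters, in 163 genes — these are the editing-derived
reader targets. The simulation planted 243 methylation sites in 160
target genes: every planted site is recovered, and the handful of extra
calls are null mismatch positions crossing the threshold (the
false-positive rate over null positions stays below 1%). The motif stage then localises the planted sequence elements:

```r
ctl <- motif_catalogue()                       # 48 IUPAC motifs + PWMs
m   <- scan_genome(ctl$pwm[[which(ctl$name == "UNUNU")]],
                   sim$bundle, motif = "UNUNU")
anc <- annotate_sites(sim$m6a_sites, sim$bundle)
bg  <- matched_background(anc, sim$bundle,
                          setdiff(sim$bundle$genes$gene_id,
                                  sim$target_genes), seed = 1)
pr  <- motif_distance_profile(m, anc, bg, sim$bundle, half_window = 40)
pr$offset[which.max(pr$anchors)]
#> [1] -15
```

The UNUNU profile peaks exactly at the planted −15 nt offset (counts per
1000 methylation sites, with the location-matched background staying
flat).

The numbered scripts under `analysis/` run the same stages end to end —
`01_simulate.R` through `06_compare_targets.R` — each printing what it
found and writing its tables under `results/`.

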