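#!/usr/bin/env Rscript
# Post-process the simulated crosslink sites: collapse adjacent peaks,
# build 9-nt collapsed crosslink sites, split by IDR dependence against a
# thinned "truncated-protein" library, and compute site diagnostics
# (nucleotide identity, metagene location, distance to edit sites).

suppressMessages(library(tribeclip))

cfg <- sim_config(n_genes = 400, genes_per_chrom = 100, seed = 2024)
sim <- simulate_genome(cfg)
bundle <- sim$bundle
cl <- sim$crosslink_sites

collapsed <- collapse_adjacent(cl)
css <- make_css(collapsed)
message(sprintf("%d crosslink sites -> %d after collapsing; CSS width %d",
                length(cl), length(collapsed),
                unique(GenomicRanges::width(css))))

# emulate the truncated-protein library as a subsample of the full one
set.seed(2024)
trunc <- collapsed[sort(sample(length(collapsed),
                               round(0.3 * length(collapsed))))]
sp <- split_idr_dependence(collapsed, trunc, max_dist = 10)
message(sprintf("IDR split: %d independent / %d dependent",
                length(sp$idr_independent), length(sp$idr_dependent)))

nt_prop <- nucleotide_proportions(collapsed, bundle)
message("nucleotide identity at crosslink sites: ",
        paste(names(nt_prop), round(nt_prop, 3), collapse = " "))

curve <- distance_to_nearest(collapsed, sim$m6a_sites, max_d = 200)
message(sprintf("%.1f%% of crosslink sites within 200 nt of an edit site; %.1f%% within 25 nt",
                100 * curve$proportion[curve$distance == 200],
                100 * curve$proportion[curve$distance == 25]))

meta <- metagene_profile(collapsed, bundle, n_background = 1e5,
                         seed = 2024)

dir.create("results", showWarnings = FALSE)
write_sites_bed(collapsed, "results/crosslinks_collapsed.bed")
write_sites_bed(css, "results/crosslinks_css.bed")
write_sites_bed(sp$idr_dependent, "results/crosslinks_idr_dependent.bed")
write_sites_bed(sp$idr_independent,
                "results/crosslinks_idr_independent.bed")
utils::write.table(curve, "results/distance_to_edit_sites.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(meta, "results/crosslink_metagene.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("3'UTR O/E enrichment of crosslink sites: %.2f",
                max(meta$oe[meta$feature == "three_prime_UTR"],
                    na.rm = TRUE)))
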