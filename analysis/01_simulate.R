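#!/usr/bin/env Rscript
# Generate the synthetic study data every later step consumes: an
# annotated genome with planted methylation/crosslink sites, and
# fusion-vs-control editing count tables. Writes FASTA/GFF3/BED/TSV plus
# a JSON manifest under results/sim/.

suppressMessages(library(tribeclip))

cfg <- sim_config(n_genes = 400, genes_per_chrom = 100, seed = 2024)
sim <- simulate_genome(cfg)
mat <- simulate_editing_counts(sim)

dir.create("results", showWarnings = FALSE)
paths <- write_simulation(sim, "results/sim", mat)

message(sprintf(
  "simulated %d genes (%d targets) on %d contigs: %d m6A sites, %d crosslink sites",
  nrow(sim$bundle$genes), length(sim$target_genes),
  length(sim$bundle$genome), length(sim$m6a_sites),
  length(sim$crosslink_sites)))
message(sprintf("editing matrix: %d mismatch positions x %d samples",
                length(mat$sites), nrow(mat$samples)))
message("wrote: ", paste(basename(unname(paths)), collapse = ", "))
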