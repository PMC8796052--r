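# GenomeBundle: genome sequences plus single-isoform transcript models with
# 5'UTR / CDS / 3'UTR intervals. Internal coordinates are GRanges (1-based,
# closed); BED on disk is 0-based half-open via rtracklayer.

FEATURE_LEVELS <- c("five_prime_UTR", "CDS", "three_prime_UTR")

#' Construct a GenomeBundle
#'
#' @param genome a \code{DNAStringSet} of contigs.
#' @param features a \code{GRanges} with metadata columns \code{gene_id} and
#'   \code{feature} (one of \code{five_prime_UTR}, \code{CDS},
#'   \code{three_prime_UTR}); one contiguous range per gene per feature.
#' @param genes data.frame with one row per gene (\code{gene_id},
#'   \code{chrom}, \code{strand}, \code{start}, \code{end}).
#' @return an object of class \code{GenomeBundle}.
#' @export
genome_bundle <- function(genome, features, genes) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  stopifnot(all(features$feature %in% FEATURE_LEVELS))
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in%
                  names(genes)))
  GenomeInfoDb::seqlevels(features) <- names(genome)
  GenomeInfoDb::seqlengths(features) <- Biostrings::width(genome)
  structure(list(genome = genome, features = features, genes = genes),
            class = "GenomeBundle")
}

#' @export
print.GenomeBundle <- function(x, ...) {
  cat("GenomeBundle:", length(x$genome), "contig(s),",
      nrow(x$genes), "gene(s),",
      sum(Biostrings::width(x$genome)), "bp total\n")
  invisible(x)
}

#' Write a GenomeBundle to FASTA + GFF3
#'
#' Emits \code{genome.fa} and \code{annotation.gff3} (gene, mRNA and
#' UTR/CDS features) under \code{dir}.
#'
#' @param bundle a GenomeBundle
#' @param dir output directory (created if absent)
#' @return invisibly, the two file paths
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "annotation.gff3")
  Biostrings::writeXStringSet(bundle$genome, fa)

  g <- bundle$genes
  gene_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id, Parent = NA_character_
  )
  mrna_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start, g$end), strand = g$strand,
    type = "mRNA", ID = paste0(g$gene_id, ".1"), Parent = g$gene_id
  )
  feat <- bundle$features
  feat_gr <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(feat), IRanges::ranges(feat),
    strand = GenomicRanges::strand(feat),
    type = feat$feature,
    ID = paste0(feat$gene_id, ".1.", feat$feature),
    Parent = paste0(feat$gene_id, ".1")
  )
  all_gr <- c(gene_gr, mrna_gr, feat_gr)
  all_gr$phase <- ifelse(all_gr$type == "CDS", 0L, NA_integer_)
  all_gr <- GenomicRanges::sort(all_gr, ignore.strand = TRUE)
  rtracklayer::export(all_gr, gff, format = "gff3")
  invisible(c(fasta = fa, gff3 = gff))
}

#' Read a GenomeBundle from FASTA + GFF3
#'
#' @param fasta path to genome FASTA
#' @param gff3 path to GFF3 with five_prime_UTR/CDS/three_prime_UTR features
#' @return a GenomeBundle
#' @export
read_bundle <- function(fasta, gff3) {
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(gff3, format = "gff3")
  feat <- gr[gr$type %in% FEATURE_LEVELS]
  # parent mRNA id "GENE.1" -> gene id
  parent <- vapply(feat$Parent, function(p) p[[1]], character(1))
  features <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(feat), IRanges::ranges(feat),
    strand = GenomicRanges::strand(feat),
    gene_id = sub("\\.1$", "", parent),
    feature = as.character(feat$type)
  )
  genes_gr <- gr[gr$type == "gene"]
  genes <- data.frame(
    gene_id = genes_gr$ID,
    chrom = as.character(GenomeInfoDb::seqnames(genes_gr)),
    strand = as.character(GenomicRanges::strand(genes_gr)),
    start = GenomicRanges::start(genes_gr),
    end = GenomicRanges::end(genes_gr),
    stringsAsFactors = FALSE
  )
  genome_bundle(genome, features, genes)
}

#' Extract strand-aware sequences for ranges from a DNAStringSet genome
#'
#' Minus-strand ranges are reverse-complemented.
#'
#' @param genome a DNAStringSet
#' @param gr a GRanges within sequence bounds
#' @return a DNAStringSet, one sequence per range
#' @export
extract_seq <- function(genome, gr) {
  chroms <- as.character(GenomeInfoDb::seqnames(gr))
  bad <- setdiff(chroms, names(genome))
  if (length(bad) > 0) stop("unknown contig(s): ", paste(bad, collapse = ","))
  seqs <- Biostrings::subseq(genome[chroms], GenomicRanges::start(gr),
                             GenomicRanges::end(gr))
  minus <- as.character(GenomicRanges::strand(gr)) == "-"
  if (any(minus)) {
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  }
  unname(seqs)
}

#' Annotate single-nucleotide positions with gene, feature and relative
#' position
#'
#' Each position gains the gene it falls in, the gene-body feature
#' (5'UTR/CDS/3'UTR, or \code{intergenic} if outside every gene) and the
#' relative position within the feature in [0, 1), measured 5' to 3' on the
#' transcript strand. When a position is covered by several genes the one
#' with the highest expression wins; remaining ties break lexicographically
#' on gene id.
#'
#' @param sites a width-1 \code{GRanges} (strand is ignored for assignment;
#'   the assigned gene's strand is returned)
#' @param bundle a GenomeBundle
#' @param tpm optional named numeric vector of gene expression (TPM);
#'   missing genes count as 0
#' @return \code{sites} with metadata columns \code{gene_id},
#'   \code{feature}, \code{rel_pos} and \code{gene_strand}
#' @export
annotate_positions <- function(sites, bundle, tpm = NULL) {
  feat <- bundle$features
  hits <- GenomicRanges::findOverlaps(sites, feat, ignore.strand = TRUE)
  gene_id <- rep(NA_character_, length(sites))
  feature <- rep("intergenic", length(sites))
  rel_pos <- rep(NA_real_, length(sites))
  gene_strand <- rep("*", length(sites))

  if (length(hits) > 0) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    cand_gene <- feat$gene_id[sh]
    cand_tpm <- if (is.null(tpm)) rep(0, length(sh)) else {
      v <- tpm[cand_gene]
      v[is.na(v)] <- 0
      as.numeric(v)
    }
    # order: by query, then decreasing tpm, then gene id; keep first per query
    ord <- order(qh, -cand_tpm, cand_gene)
    first <- !duplicated(qh[ord])
    pick <- ord[first]
    qi <- qh[pick]
    si <- sh[pick]
    gene_id[qi] <- feat$gene_id[si]
    feature[qi] <- feat$feature[si]
    fstart <- GenomicRanges::start(feat)[si]
    fend <- GenomicRanges::end(feat)[si]
    flen <- fend - fstart + 1
    pos <- GenomicRanges::start(sites)[qi]
    minus <- as.character(GenomicRanges::strand(feat))[si] == "-"
    rel <- ifelse(minus, (fend - pos), (pos - fstart)) / flen
    rel_pos[qi] <- rel
    gene_strand[qi] <- as.character(GenomicRanges::strand(feat))[si]
  }
  S4Vectors::mcols(sites)$gene_id <- gene_id
  S4Vectors::mcols(sites)$feature <- feature
  S4Vectors::mcols(sites)$rel_pos <- rel_pos
  S4Vectors::mcols(sites)$gene_strand <- gene_strand
  sites
}

#' Map (feature, relative position) to a global gene-body bin
#'
#' Bins 1..k are the 5'UTR, k+1..2k the CDS, 2k+1..3k the 3'UTR.
#'
#' @param feature character vector of feature labels
#' @param rel_pos numeric relative positions in [0, 1)
#' @param bins_per_feature bins per feature (default 10)
#' @return integer bin index (NA for intergenic)
#' @export
genebody_bin <- function(feature, rel_pos, bins_per_feature = 10) {
  fi <- match(feature, FEATURE_LEVELS)
  within <- pmin(floor(rel_pos * bins_per_feature), bins_per_feature - 1)
  ifelse(is.na(fi), NA_integer_,
         as.integer((fi - 1) * bins_per_feature + within + 1))
}

#' Sample uniform random single-nucleotide positions from transcripts
#'
#' Positions are drawn uniformly over all transcript (feature) nucleotides
#' of the selected genes, so longer features receive proportionally more.
#'
#' @param bundle a GenomeBundle
#' @param n number of positions
#' @param genes optional character vector restricting to these gene ids
#' @return width-1 \code{GRanges} on the genes' strands
#' @export
sample_transcript_positions <- function(bundle, n, genes = NULL) {
  feat <- bundle$features
  if (!is.null(genes)) {
    feat <- feat[feat$gene_id %in% genes]
  }
  if (length(feat) == 0) stop("no features to sample from")
  w <- GenomicRanges::width(feat)
  idx <- sample.int(length(feat), n, replace = TRUE, prob = w)
  offs <- floor(stats::runif(n) * w[idx])
  pos <- GenomicRanges::start(feat)[idx] + offs
  GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(feat)[idx],
    IRanges::IRanges(pos, width = 1),
    strand = GenomicRanges::strand(feat)[idx],
    gene_id = feat$gene_id[idx]
  )
}

#' Read / write single-nucleotide site tables as BED6
#'
#' BED is 0-based half-open on disk; in memory sites are width-1 GRanges
#' with a \code{score} column. Site names are preserved via the BED name
#' field.
#'
#' @param sites width-1 GRanges with optional \code{score}
#' @param path output path
#' @return invisibly, \code{path}
#' @export
write_sites_bed <- function(sites, path) {
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(sites)),
    start = GenomicRanges::start(sites) - 1L,
    end = GenomicRanges::end(sites),
    name = if (!is.null(sites$name)) sites$name else ".",
    score = if (!is.null(sites$score)) sites$score else 0,
    strand = as.character(GenomicRanges::strand(sites))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_sites_bed
#' @param path BED6 path
#' @export
read_sites_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "numeric", "character"))
  GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start + 1L, df$end),
    strand = df$strand, name = df$name, score = df$score
  )
}
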