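# Seeded synthetic genomes, annotations, m6A/crosslink sites and
# fusion-vs-control base-count tables with the statistical structure the
# downstream analysis assumes: methylation sites sit inside DRACH/GGAU
# matches in 3'UTRs, flanked by planted U/Y-rich elements; crosslink sites
# are displaced 5' of the methylation site; editing counts follow a
# beta-binomial with low editing proportions in the fusion lines and
# sequencing-error background elsewhere; a fraction of positions carry
# line-group-specific SNP artifacts with editing proportion near 1.

#' Simulation configuration
#'
#' Defaults describe the study conditions the generator emulates: a compact
#' plant-like transcriptome (uniform UTR/CDS length ranges), transcript
#' base composition matching the A/C/G/U background frequencies used for
#' motif scanning, roughly two methylation sites per target 3'UTR inside a
#' DRACH (80\%) or GGAU (20\%) island with UNUNU planted 15 nt upstream and
#' YYYYY 8 nt downstream, crosslink sites centred 11 nt 5' of the
#' methylation site, five fusion and five control replicates, mean coverage
#' 50, true editing proportion 0.25 over a 0.01 sequencing-error
#' background, and beta-binomial overdispersion 0.01.
#'
#' @param n_genes number of genes
#' @param target_fraction fraction of genes that are true reader targets
#' @param utr5_len,cds_len,utr3_len integer length ranges \code{c(min,max)}
#' @param gc_background named per-base frequencies over A/C/G/T (sum 1)
#' @param m6a_rate expected methylation sites per target 3'UTR (>= 1 drawn)
#' @param at_motifs named probabilities of the at-site motif (names are
#'   IUPAC patterns with the methylated A at \code{at_offset})
#' @param at_offset 1-based index of the methylated A within each at-motif
#' @param flank_motifs data.frame(motif, offset): IUPAC elements planted at
#'   a signed transcript offset (negative = 5') from the methylated A
#' @param crosslink_offset_mean,crosslink_offset_sd normal displacement of
#'   the crosslink site from the methylation site (negative = 5')
#' @param n_fusion,n_control replicate counts per condition
#' @param coverage_mean Poisson mean read coverage per site per sample
#' @param ep_target true editing proportion at planted sites (fusion)
#' @param ep_background sequencing-error editing proportion
#' @param bb_overdispersion beta-binomial rho
#' @param snp_fraction expected SNP-artifact sites per true site; each
#'   artifact has editing proportion >= 0.9 across one whole line group
#' @param n_null_sites background mismatch positions carried in the matrix
#' @param nonag_fraction fraction of null sites whose mismatch is not an
#'   A-to-G change (exercises the base-identity filter)
#' @param adar_coupling exponent coupling per-sample editing proportion to
#'   the sample's ADAR TPM (0 = off)
#' @param genes_per_chrom genes placed per synthetic chromosome
#' @param intergenic_len spacer length between genes
#' @param seed integer seed; all randomness flows from it
#' @return a validated list of class \code{SimConfig}
#' @export
sim_config <- function(n_genes = 120,
                       target_fraction = 0.4,
                       utr5_len = c(100, 200),
                       cds_len = c(600, 1200),
                       utr3_len = c(250, 400),
                       gc_background = c(A = 0.273, C = 0.165,
                                         G = 0.173, T = 0.389),
                       m6a_rate = 2,
                       at_motifs = c(DRACH = 0.8, GGAU = 0.2),
                       at_offset = c(DRACH = 3, GGAU = 3),
                       flank_motifs = data.frame(
                         motif = c("UNUNU", "YYYYY"),
                         offset = c(-15L, 8L)),
                       crosslink_offset_mean = -11,
                       crosslink_offset_sd = 3,
                       n_fusion = 5,
                       n_control = 5,
                       coverage_mean = 50,
                       ep_target = 0.25,
                       ep_background = 0.01,
                       bb_overdispersion = 0.01,
                       snp_fraction = 0.05,
                       n_null_sites = 2000,
                       nonag_fraction = 0.05,
                       adar_coupling = 0,
                       genes_per_chrom = 60,
                       intergenic_len = 200,
                       seed = 1) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "SimConfig")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1)
  if (abs(sum(cfg$gc_background) - 1) > 1e-9) {
    stop("gc_background frequencies must sum to 1")
  }
  if (any(cfg$gc_background < 0 | cfg$gc_background > 1)) {
    stop("gc_background frequencies must be in [0,1]")
  }
  if (!(cfg$ep_background >= 0 && cfg$ep_background < cfg$ep_target &&
          cfg$ep_target <= 1) && cfg$ep_target != cfg$ep_background) {
    stop("require 0 <= ep_background < ep_target <= 1")
  }
  if (cfg$coverage_mean <= 0) stop("coverage_mean must be positive")
  if (abs(sum(cfg$at_motifs) - 1) > 1e-9) {
    stop("at_motifs probabilities must sum to 1")
  }
  # every planted element must fit inside the shortest possible 3'UTR,
  # leaving room for classifier windows downstream of the site
  span_lo <- min(0L, cfg$flank_motifs$offset)
  span_hi <- max(vapply(names(cfg$at_motifs), nchar, integer(1))) +
    max(0L, max(cfg$flank_motifs$offset +
                  nchar(as.character(cfg$flank_motifs$motif)) - 1L))
  if (cfg$utr3_len[1] < (span_hi - span_lo + 140)) {
    stop("motif plan cannot fit in the drawn 3'UTR lengths; ",
         "increase utr3_len")
  }
  invisible(cfg)
}

#' Simulate an annotated genome with planted methylation and crosslink
#' sites
#'
#' Every gene carries a contiguous 5'UTR, CDS and 3'UTR on a declared
#' strand (50/50 plus/minus). Target genes receive methylation sites in
#' their 3'UTR; each site sits at the methylated A of a concrete DRACH or
#' GGAU instance, with flanking elements planted at the configured signed
#' offsets, and a crosslink site displaced by a normal draw (negative =
#' 5'). Truth tables are returned alongside; emitted FASTA/GFF3 never
#' encode labels.
#'
#' @param config a \code{SimConfig}
#' @return list with \code{bundle} (GenomeBundle), \code{m6a_sites},
#'   \code{crosslink_sites} (width-1 GRanges with \code{gene_id};
#'   crosslinks carry a \code{score}), \code{target_genes} (character) and
#'   \code{config}
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n <- config$n_genes
  u5 <- sample(config$utr5_len[1]:config$utr5_len[2], n, replace = TRUE)
  cds <- sample(config$cds_len[1]:config$cds_len[2], n, replace = TRUE)
  u3 <- sample(config$utr3_len[1]:config$utr3_len[2], n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gene_id <- sprintf("SYNG%04d", seq_len(n))
  is_target <- seq_len(n) %in%
    sample.int(n, round(n * config$target_fraction))

  txlen <- u5 + cds + u3
  bases <- names(config$gc_background)

  m6a_rec <- list()
  cl_rec <- list()
  tx_seqs <- character(n)

  flanks <- config$flank_motifs
  flanks$motif <- to_dna(as.character(flanks$motif))
  at_names <- names(config$at_motifs)

  # margins inside the 3'UTR so planted elements and downstream feature
  # windows stay within the transcript
  margin_lo <- max(20L, -min(0L, min(flanks$offset)))
  margin_hi <- 70L
  # spacing exceeds the 120-nt classifier redundancy window so planted
  # sites survive redundancy reduction
  min_spacing <- 140L

  for (i in seq_len(n)) {
    s <- sample(bases, txlen[i], replace = TRUE,
                prob = as.numeric(config$gc_background))
    if (is_target[i]) {
      k <- if (config$m6a_rate == 0) 0L else {
        max(1L, stats::rpois(1, config$m6a_rate))
      }
      lo <- u5[i] + cds[i] + margin_lo
      hi <- txlen[i] - margin_hi
      cand <- lo:hi
      pos <- integer(0)
      for (j in seq_len(k)) {
        ok <- cand[vapply(cand, function(p) {
          length(pos) == 0 || all(abs(p - pos) >= min_spacing)
        }, logical(1))]
        if (length(ok) == 0) break
        pos <- c(pos, if (length(ok) == 1) ok else sample(ok, 1))
      }
      pos <- sort(pos)
      for (p in pos) {
        at_name <- if (length(at_names) == 1) at_names else {
          sample(at_names, 1, prob = as.numeric(config$at_motifs))
        }
        inst <- strsplit(iupac_instance(at_name), "")[[1]]
        a_idx <- config$at_offset[[at_name]]
        start_at <- p - a_idx + 1
        s[start_at:(start_at + length(inst) - 1)] <- inst
        for (fi in seq_len(nrow(flanks))) {
          finst <- strsplit(iupac_instance(flanks$motif[fi]), "")[[1]]
          fs <- p + flanks$offset[fi]
          s[fs:(fs + length(finst) - 1)] <- finst
        }
        d <- round(stats::rnorm(1, config$crosslink_offset_mean,
                                config$crosslink_offset_sd))
        clpos <- min(max(p + d, 1L), txlen[i])
        m6a_rec[[length(m6a_rec) + 1]] <-
          list(gene = i, tpos = p)
        cl_rec[[length(cl_rec) + 1]] <-
          list(gene = i, tpos = clpos, score = stats::runif(1, 1, 10))
      }
    }
    tx_seqs[i] <- paste(s, collapse = "")
  }

  # lay genes onto chromosomes with intergenic spacers
  chrom_of <- ceiling(seq_len(n) / config$genes_per_chrom)
  n_chrom <- max(chrom_of)
  chrom_names <- sprintf("chr%d", seq_len(n_chrom))
  gstart <- integer(n)
  gend <- integer(n)
  chrom_seq <- character(n_chrom)
  for (ci in seq_len(n_chrom)) {
    idx <- which(chrom_of == ci)
    parts <- character(0)
    cursor <- 0L
    for (i in idx) {
      spacer <- paste(sample(bases, config$intergenic_len, replace = TRUE,
                             prob = as.numeric(config$gc_background)),
                      collapse = "")
      parts <- c(parts, spacer)
      cursor <- cursor + config$intergenic_len
      gseq <- if (strand[i] == "+") tx_seqs[i] else revcomp_chr(tx_seqs[i])
      gstart[i] <- cursor + 1L
      gend[i] <- cursor + txlen[i]
      parts <- c(parts, gseq)
      cursor <- cursor + txlen[i]
    }
    parts <- c(parts, paste(sample(bases, config$intergenic_len,
                                   replace = TRUE,
                                   prob = as.numeric(config$gc_background)),
                            collapse = ""))
    chrom_seq[ci] <- paste(parts, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(chrom_seq)
  names(genome) <- chrom_names

  tx_to_genomic <- function(i, t) {
    if (strand[i] == "+") gstart[i] + t - 1L else gend[i] - t + 1L
  }

  # feature intervals (genomic)
  feat_list <- lapply(seq_len(n), function(i) {
    bounds <- list(
      five_prime_UTR = c(1L, u5[i]),
      CDS = c(u5[i] + 1L, u5[i] + cds[i]),
      three_prime_UTR = c(u5[i] + cds[i] + 1L, txlen[i])
    )
    do.call(rbind, lapply(names(bounds), function(f) {
      b <- bounds[[f]]
      g1 <- tx_to_genomic(i, b[1])
      g2 <- tx_to_genomic(i, b[2])
      data.frame(chrom = chrom_names[chrom_of[i]],
                 start = min(g1, g2), end = max(g1, g2),
                 strand = strand[i], gene_id = gene_id[i], feature = f)
    }))
  })
  fdf <- do.call(rbind, feat_list)
  features <- GenomicRanges::GRanges(
    fdf$chrom, IRanges::IRanges(fdf$start, fdf$end), strand = fdf$strand,
    gene_id = fdf$gene_id, feature = fdf$feature
  )
  genes <- data.frame(gene_id = gene_id, chrom = chrom_names[chrom_of],
                      strand = strand, start = gstart, end = gend,
                      target = is_target, stringsAsFactors = FALSE)
  bundle <- genome_bundle(genome, features, genes)

  site_gr <- function(rec, with_score = FALSE) {
    if (length(rec) == 0) {
      gr <- GenomicRanges::GRanges()
      S4Vectors::mcols(gr)$gene_id <- character(0)
      S4Vectors::mcols(gr)$score <- numeric(0)
      return(gr)
    }
    gi <- vapply(rec, `[[`, numeric(1), "gene")
    tp <- vapply(rec, `[[`, numeric(1), "tpos")
    gp <- mapply(tx_to_genomic, gi, tp)
    gr <- GenomicRanges::GRanges(
      chrom_names[chrom_of[gi]], IRanges::IRanges(gp, width = 1),
      strand = strand[gi], gene_id = gene_id[gi]
    )
    gr$score <- if (with_score) {
      vapply(rec, `[[`, numeric(1), "score")
    } else rep(0, length(gr))
    GenomeInfoDb::seqlevels(gr) <- chrom_names
    GenomeInfoDb::seqlengths(gr) <- Biostrings::width(genome)
    GenomicRanges::sort(gr, ignore.strand = TRUE)
  }

  list(bundle = bundle,
       m6a_sites = site_gr(m6a_rec),
       crosslink_sites = site_gr(cl_rec, with_score = TRUE),
       target_genes = gene_id[is_target],
       config = config)
}

#' Simulate fusion-vs-control base counts at true, null and artifact sites
#'
#' At true sites, fusion-sample edited-base counts follow a beta-binomial
#' with mean \code{ep_target} and overdispersion \code{bb_overdispersion};
#' control samples and null sites follow \code{ep_background}. SNP
#' artifacts receive an editing proportion drawn in [0.9, 1] across every
#' sample of one randomly chosen line group. Only positions with at least
#' one mismatch in at least one sample are kept, mirroring a pileup of
#' mismatch positions.
#'
#' @param sim result of \code{\link{simulate_genome}}
#' @param config a \code{SimConfig} (defaults to \code{sim$config})
#' @param seed RNG seed for the count draws (default derived from the
#'   config seed)
#' @return an \code{EditingMatrix}: list with \code{sites} (width-1 GRanges
#'   with \code{ref}), \code{counts} (site x sample x base integer array)
#'   and \code{samples} (data.frame: sample, condition, line, adar_tpm)
#' @export
simulate_editing_counts <- function(sim, config = sim$config,
                                    seed = config$seed + 1L) {
  stopifnot(inherits(config, "SimConfig"))
  if (config$coverage_mean <= 0) stop("coverage_mean must be positive")
  set.seed(seed)
  bundle <- sim$bundle
  truth <- sim$m6a_sites
  genome <- bundle$genome

  # extract_seq is strand-aware, so this is the transcript-sense base
  sense_base <- function(gr) {
    as.character(extract_seq(genome, GenomicRanges::granges(gr)))
  }
  stopifnot(all(sense_base(truth) == "A"))

  draw_positions <- function(n_want, sense) {
    # rejection-sample transcript positions until n_want have the wanted
    # sense base and do not collide with truth sites
    out <- GenomicRanges::GRanges()
    guard <- 0L
    while (length(out) < n_want && guard < 50L) {
      cand <- sample_transcript_positions(bundle, 3L * n_want)
      keep <- sense_base(cand) %in% sense
      cand <- cand[keep]
      if (length(truth) > 0) {
        cand <- cand[!IRanges::overlapsAny(cand, truth, ignore.strand = TRUE)]
      }
      out <- c(out, cand)
      if (length(out) > 0) {
        key <- paste0(as.character(GenomeInfoDb::seqnames(out)), ":",
                      GenomicRanges::start(out))
        out <- out[!duplicated(key)]
      }
      guard <- guard + 1L
    }
    out[seq_len(min(n_want, length(out)))]
  }

  n_nonag <- round(config$n_null_sites * config$nonag_fraction)
  n_null <- config$n_null_sites - n_nonag
  null_gr <- draw_positions(n_null, "A")
  nonag_gr <- if (n_nonag > 0) draw_positions(n_nonag, "C") else
    GenomicRanges::GRanges()
  n_snp <- round(config$snp_fraction * length(truth))
  snp_gr <- if (n_snp > 0) draw_positions(n_snp, "A") else
    GenomicRanges::GRanges()

  kinds <- c(rep("true", length(truth)), rep("null", length(null_gr)),
             rep("nonag", length(nonag_gr)), rep("snp", length(snp_gr)))
  all_gr <- c(GenomicRanges::granges(truth), GenomicRanges::granges(null_gr),
              GenomicRanges::granges(nonag_gr), GenomicRanges::granges(snp_gr))
  n_sites <- length(all_gr)

  n_f <- config$n_fusion
  n_c <- config$n_control
  samples <- data.frame(
    sample = c(sprintf("fusion_%d", seq_len(n_f)),
               sprintf("control_%d", seq_len(n_c))),
    condition = c(rep("fusion", n_f), rep("control", n_c)),
    line = c(sprintf("LF%d", seq_len(n_f)), sprintf("LC%d", seq_len(n_c))),
    adar_tpm = stats::rlnorm(n_f + n_c, log(50), 0.3),
    stringsAsFactors = FALSE
  )
  n_samp <- nrow(samples)

  # per-site per-sample editing proportion
  ep <- matrix(config$ep_background, n_sites, n_samp)
  is_fusion <- samples$condition == "fusion"
  ep[kinds == "true", is_fusion] <- config$ep_target
  if (config$adar_coupling > 0) {
    w <- (samples$adar_tpm / mean(samples$adar_tpm[is_fusion]))^
      config$adar_coupling
    ep[kinds == "true", is_fusion] <-
      pmin(1, outer(rep(config$ep_target, sum(kinds == "true")),
                    w[is_fusion]))
  }
  if (sum(kinds == "snp") > 0) {
    for (r in which(kinds == "snp")) {
      grp <- sample(c("fusion", "control"), 1)
      ep[r, samples$condition == grp] <- stats::runif(1, 0.9, 1.0)
    }
  }

  unstranded <- all_gr
  GenomicRanges::strand(unstranded) <- "*"
  ref <- as.character(extract_seq(genome, unstranded))  # plus-strand base
  minus <- as.character(GenomicRanges::strand(all_gr)) == "-"
  # edited base as read on the genomic plus strand
  alt <- ifelse(kinds == "nonag",
                ifelse(minus, "A", "T"),   # C->T sense change, not A->G
                ifelse(minus, "C", "G"))   # A->G sense change

  counts <- array(0L, dim = c(n_sites, n_samp, 4),
                  dimnames = list(NULL, samples$sample, BASES))
  cov <- matrix(stats::rpois(n_sites * n_samp, config$coverage_mean),
                n_sites, n_samp)
  altc <- matrix(0L, n_sites, n_samp)
  for (s in seq_len(n_samp)) {
    for (lev in unique(ep[, s])) {
      rows <- which(ep[, s] == lev)
      altc[rows, s] <- rbetabinom(length(rows), cov[rows, s], lev,
                                  config$bb_overdispersion)
    }
  }
  refc <- cov - altc
  ri <- match(ref, BASES)
  ai <- match(alt, BASES)
  for (s in seq_len(n_samp)) {
    counts[cbind(seq_len(n_sites), s, ri)] <- refc[, s]
    counts[cbind(seq_len(n_sites), s, ai)] <-
      counts[cbind(seq_len(n_sites), s, ai)] + altc[, s]
  }

  keep <- rowSums(altc) >= 1L
  sites <- all_gr[keep]
  S4Vectors::mcols(sites)$ref <- ref[keep]
  # `kind` is in-memory simulation truth (true/null/nonag/snp); it is
  # never written to disk by write_editing_tsv
  structure(list(sites = sites,
                 counts = counts[keep, , , drop = FALSE],
                 samples = samples,
                 kind = kinds[keep]),
            class = "EditingMatrix")
}

#' Write a full simulation to disk
#'
#' Emits the genome FASTA, GFF3 annotation, BED6 truth tables for
#' methylation and crosslink sites, the count TSV and a JSON manifest of
#' the configuration and file inventory. The FASTA/GFF3/count files alone
#' never encode truth labels; truth lives only in the BED/manifest files
#' written alongside.
#'
#' @param sim result of \code{\link{simulate_genome}}
#' @param mat optional \code{EditingMatrix} for the count TSV
#' @param dir output directory
#' @return invisibly, the named vector of paths
#' @export
write_simulation <- function(sim, dir, mat = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_bundle(sim$bundle, dir)
  m6a <- sim$m6a_sites
  m6a$name <- sprintf("m6a_%04d", seq_along(m6a))
  cl <- sim$crosslink_sites
  cl$name <- sprintf("cl_%04d", seq_along(cl))
  p_m6a <- file.path(dir, "truth_m6a.bed")
  p_cl <- file.path(dir, "truth_crosslinks.bed")
  write_sites_bed(m6a, p_m6a)
  write_sites_bed(cl, p_cl)
  paths <- c(paths, truth_m6a = p_m6a, truth_crosslinks = p_cl)
  if (!is.null(mat)) {
    p_cnt <- file.path(dir, "counts.tsv")
    write_editing_tsv(mat, p_cnt)
    paths <- c(paths, counts = p_cnt)
  }
  manifest <- list(
    config = unclass(sim$config)[!vapply(unclass(sim$config), is.data.frame,
                                         logical(1))],
    target_genes = sim$target_genes,
    files = as.list(paths)
  )
  p_man <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, p_man, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, manifest = p_man))
}

#' @export
print.EditingMatrix <- function(x, ...) {
  cat("EditingMatrix:", length(x$sites), "sites x",
      nrow(x$samples), "samples (",
      sum(x$samples$condition == "fusion"), "fusion /",
      sum(x$samples$condition == "control"), "control )\n")
  invisible(x)
}

#' Write / read an EditingMatrix as the on-disk count TSV
#'
#' Schema: chrom, pos0 (0-based), strand, ref, then four base-count columns
#' per sample named \code{<sample>.A} etc.
#'
#' @param mat an EditingMatrix
#' @param path TSV path
#' @export
write_editing_tsv <- function(mat, path) {
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(mat$sites)),
    pos0 = GenomicRanges::start(mat$sites) - 1L,
    strand = as.character(GenomicRanges::strand(mat$sites)),
    ref = mat$sites$ref
  )
  for (s in seq_len(nrow(mat$samples))) {
    for (b in seq_along(BASES)) {
      df[[paste0(mat$samples$sample[s], ".", BASES[b])]] <-
        mat$counts[, s, b]
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_editing_tsv
#' @param samples sample metadata data.frame (sample, condition, line,
#'   adar_tpm) matching the TSV's sample columns
#' @export
read_editing_tsv <- function(path, samples) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  sites <- GenomicRanges::GRanges(df$chrom,
                                  IRanges::IRanges(df$pos0 + 1L, width = 1),
                                  strand = df$strand, ref = df$ref)
  n <- nrow(df)
  counts <- array(0L, dim = c(n, nrow(samples), 4),
                  dimnames = list(NULL, samples$sample, BASES))
  for (s in seq_len(nrow(samples))) {
    for (b in seq_along(BASES)) {
      counts[, s, b] <- df[[paste0(samples$sample[s], ".", BASES[b])]]
    }
  }
  structure(list(sites = sites, counts = counts, samples = samples),
            class = "EditingMatrix")
}
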