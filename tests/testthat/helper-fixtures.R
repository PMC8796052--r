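# Shared fixtures built in code: a tiny hand-made genome bundle with known
# sequences for exact-position tests, and small seeded simulations.

# Two genes on one 500-nt contig, one per strand, with simple feature
# layouts. Gene A (+): 51..250 (5'UTR 51..100, CDS 101..200, 3'UTR
# 201..250). Gene B (-): 281..420 (5'UTR 401..420, CDS 321..400, 3'UTR
# 281..320).
make_toy_bundle <- function(seed = 42) {
  set.seed(seed)
  seq_chars <- sample(c("A", "C", "G", "T"), 500, replace = TRUE,
                      prob = c(0.273, 0.165, 0.173, 0.389))
  genome <- Biostrings::DNAStringSet(paste(seq_chars, collapse = ""))
  names(genome) <- "c1"
  feat <- GenomicRanges::GRanges(
    "c1",
    IRanges::IRanges(start = c(51, 101, 201, 401, 321, 281),
                     end = c(100, 200, 250, 420, 400, 320)),
    strand = c("+", "+", "+", "-", "-", "-"),
    gene_id = c("gA", "gA", "gA", "gB", "gB", "gB"),
    feature = c("five_prime_UTR", "CDS", "three_prime_UTR",
                "five_prime_UTR", "CDS", "three_prime_UTR")
  )
  genes <- data.frame(
    gene_id = c("gA", "gB"), chrom = "c1", strand = c("+", "-"),
    start = c(51, 281), end = c(250, 420), stringsAsFactors = FALSE
  )
  genome_bundle(genome, feat, genes)
}

# a toy bundle whose contig carries a chosen sequence (for exact motif /
# base-identity tests); the single gene spans the whole contig on `strand`
make_seq_bundle <- function(seq, strand = "+") {
  genome <- Biostrings::DNAStringSet(seq)
  names(genome) <- "c1"
  len <- nchar(seq)
  third <- len %/% 3
  feat <- GenomicRanges::GRanges(
    "c1",
    IRanges::IRanges(start = c(1, third + 1, 2 * third + 1),
                     end = c(third, 2 * third, len)),
    strand = strand,
    gene_id = "g1",
    feature = if (strand == "+") {
      c("five_prime_UTR", "CDS", "three_prime_UTR")
    } else {
      c("three_prime_UTR", "CDS", "five_prime_UTR")
    }
  )
  genes <- data.frame(gene_id = "g1", chrom = "c1", strand = strand,
                      start = 1L, end = len, stringsAsFactors = FALSE)
  genome_bundle(genome, feat, genes)
}

# hand-built EditingMatrix: counts is a list of per-sample named vectors
# of length 4 (A, C, G, T) per site
make_editing_matrix <- function(chrom, pos, strand, ref, counts_list,
                                samples) {
  n_sites <- length(pos)
  sites <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1),
                                  strand = strand, ref = ref)
  counts <- array(0L, dim = c(n_sites, nrow(samples), 4),
                  dimnames = list(NULL, samples$sample,
                                  c("A", "C", "G", "T")))
  for (i in seq_len(n_sites)) {
    for (s in seq_len(nrow(samples))) {
      counts[i, s, ] <- counts_list[[i]][[s]]
    }
  }
  structure(list(sites = sites, counts = counts, samples = samples),
            class = "EditingMatrix")
}

make_samples <- function(n_fusion = 5, n_control = 5, tpm = NULL) {
  n <- n_fusion + n_control
  data.frame(
    sample = c(sprintf("fusion_%d", seq_len(n_fusion)),
               sprintf("control_%d", seq_len(n_control))),
    condition = c(rep("fusion", n_fusion), rep("control", n_control)),
    line = sprintf("L%d", seq_len(n)),
    adar_tpm = if (is.null(tpm)) rep(50, n) else tpm,
    stringsAsFactors = FALSE
  )
}

# site key helper for truth comparisons
site_key <- function(x) {
  if (methods::is(x, "GRanges")) {
    paste0(GenomeInfoDb::seqnames(x), ":", GenomicRanges::start(x) - 1)
  } else {
    paste0(x$chrom, ":", x$pos0)
  }
}

# brute-force PWM window scores via embedding matrix (independent of the
# scanner's shift-and-accumulate loop)
oracle_scan <- function(pwm, seq_str, min_score) {
  L <- ncol(pwm)
  score_all <- function(s) {
    codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    nwin <- length(codes) - L + 1
    if (nwin < 1) return(numeric(0))
    idx <- outer(seq_len(nwin), 0:(L - 1), "+")
    v <- pwm[cbind(as.vector(codes[idx]), rep(seq_len(L), each = nwin))]
    v[is.na(v)] <- -Inf
    rowSums(matrix(v, nwin, L))
  }
  fwd <- score_all(seq_str)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq_str)))
  rev_sc <- score_all(rc)
  len <- nchar(seq_str)
  hit_f <- which(fwd >= min_score)
  hit_r <- which(rev_sc >= min_score)
  out <- rbind(
    data.frame(start = hit_f, strand = rep("+", length(hit_f)),
               score = fwd[hit_f]),
    data.frame(start = len - (hit_r + L - 1) + 1,
               strand = rep("-", length(hit_r)), score = rev_sc[hit_r])
  )
  out[order(out$start, out$strand), , drop = FALSE]
}
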