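# PWM construction (closed-form log-odds), scanner equivalence with an
# exhaustive window oracle, reverse-complement symmetry, exact matched
# backgrounds, distance profiles with the gene-overlap edge rule, and
# gene-body O/E enrichment.

test_that("PWM entries follow log2(p(b,j)/p(b)) with the packaged
          background", {
  bg <- default_background()
  # column all-U: entry approx log2(1/0.389) = 1.362 as pseudo -> 0
  m <- build_pwm(c("T", "T", "T"), bg, pseudo = 1e-9)
  expect_equal(unname(m["T", 1]), log2(1 / 0.389), tolerance = 1e-5)
  expect_equal(unname(round(m["T", 1], 3)), 1.362)
  # frequency exactly at background: entry 0
  w <- c(rep("A", 273), rep("C", 165), rep("G", 173), rep("T", 389))
  m0 <- build_pwm(w, bg, pseudo = 1e-9)
  expect_true(all(abs(m0[, 1]) < 1e-5))
  # A frequency 0.546 = 2x background: entry 1
  w2 <- c(rep("A", 546), rep("C", 165), rep("G", 100), rep("T", 189))
  m1 <- build_pwm(w2, bg, pseudo = 1e-9)
  expect_equal(unname(m1["A", 1]), 1, tolerance = 1e-3)
  expect_error(build_pwm(c("AC", "A")), "length")
})

test_that("IUPAC-seeded PWMs are finite, exact-match-positive and
          N-neutral", {
  ctl <- motif_catalogue()
  expect_equal(nrow(ctl), 48)
  expect_true(all(vapply(ctl$pwm, function(m) all(is.finite(m)),
                         logical(1))))
  # an exact DRACH instance always reaches the score-4 filter
  pwm <- iupac_pwm("DRACH")
  allowed <- list(c("A","G","T"), c("A","G"), "A", "C", c("A","C","T"))
  worst <- sum(vapply(seq_len(5), function(j) {
    min(pwm[allowed[[j]], j])
  }, numeric(1)))
  expect_gte(worst, 4)
  # N columns are exactly zero
  pun <- iupac_pwm("UNUNU")
  expect_true(all(pun[, c(2, 4)] == 0))
})

test_that("scan_genome equals exhaustive window enumeration", {
  ctl <- motif_catalogue()
  set.seed(91)
  for (rep in 1:3) {
    seq_str <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE,
                            prob = c(0.273, 0.165, 0.173, 0.389)),
                     collapse = "")
    seqs <- Biostrings::DNAStringSet(seq_str)
    names(seqs) <- "s1"
    for (nm in c("DRACH", "UNUNU", "YYYYY", "GGAU", "URUAY")) {
      pwm <- ctl$pwm[[which(ctl$name == nm)]]
      got <- scan_genome(pwm, seqs, min_score = 4)
      want <- oracle_scan(pwm, seq_str, 4)
      expect_equal(length(got), nrow(want))
      ord <- order(GenomicRanges::start(got),
                   as.character(GenomicRanges::strand(got)))
      expect_equal(GenomicRanges::start(got)[ord], want$start)
      expect_equal(as.character(GenomicRanges::strand(got))[ord],
                   want$strand)
      expect_equal(got$score[ord], want$score, tolerance = 1e-9)
    }
  }
})

test_that("a permissive threshold returns every window and empty input
          returns nothing", {
  pwm <- iupac_pwm("GGAU")
  seqs <- Biostrings::DNAStringSet("ACGTACGTAC")
  names(seqs) <- "s"
  all_hits <- scan_genome(pwm, seqs, min_score = -Inf)
  expect_equal(length(all_hits), 2 * (10 - 4 + 1))
  expect_length(scan_genome(pwm, Biostrings::DNAStringSet(), 4), 0)
  # sequence shorter than the motif yields no windows
  short <- Biostrings::DNAStringSet("AC")
  names(short) <- "t"
  expect_length(scan_genome(pwm, short, -Inf), 0)
})

test_that("scanning the reverse-complemented genome flips match strands", {
  sim <- simulate_genome(sim_config(n_genes = 10, genes_per_chrom = 10,
                                    seed = 3))
  pwm <- iupac_pwm("DRACH")
  fwd <- scan_genome(pwm, sim$bundle$genome, 4)
  rc_genome <- Biostrings::reverseComplement(sim$bundle$genome)
  names(rc_genome) <- names(sim$bundle$genome)
  rc <- scan_genome(pwm, rc_genome, 4)
  len <- Biostrings::width(sim$bundle$genome)[1]
  L <- ncol(pwm)
  # a plus-strand match at s maps to a minus-strand match at
  # len - (s + L - 1) + 1 in the reverse-complemented genome
  mapped <- sort(len - (GenomicRanges::start(fwd) + L - 1) + 1)
  expect_equal(sort(GenomicRanges::start(rc)), mapped)
  expect_equal(sum(GenomicRanges::strand(fwd) == "+"),
               sum(GenomicRanges::strand(rc) == "-"))
})

test_that("matched backgrounds preserve the (feature, bin) histogram
          exactly and avoid target genes", {
  sim <- simulate_genome(sim_config(n_genes = 60, genes_per_chrom = 60,
                                    seed = 29))
  anc <- annotate_sites(sim$m6a_sites, sim$bundle)
  nt <- setdiff(sim$bundle$genes$gene_id, sim$target_genes)
  for (seed in 1:3) {
    bg <- matched_background(anc, sim$bundle, nt, seed = seed)
    expect_equal(length(bg), length(anc))
    h_a <- table(anc$feature, genebody_bin(anc$feature, anc$rel_pos))
    h_b <- table(bg$feature, genebody_bin(bg$feature, bg$rel_pos))
    expect_identical(h_a, h_b)
    expect_length(intersect(bg$gene_id, sim$target_genes), 0)
  }
  # identical seed, identical draw
  b1 <- matched_background(anc, sim$bundle, nt, seed = 7)
  b2 <- matched_background(anc, sim$bundle, nt, seed = 7)
  expect_identical(GenomicRanges::start(b1), GenomicRanges::start(b2))
  # an unfillable stratum names itself in the error
  expect_error(matched_background(anc, sim$bundle, character(0)),
               "non-target")
})

test_that("distance profiles peak at the planted offsets with a flat
          matched background", {
  sim <- simulate_genome(sim_config(n_genes = 120, genes_per_chrom = 120,
                                    seed = 31))
  b <- sim$bundle
  ctl <- motif_catalogue()
  anc <- annotate_sites(sim$m6a_sites, b)
  nt <- setdiff(b$genes$gene_id, sim$target_genes)
  bg <- matched_background(anc, b, nt, seed = 11)

  m_un <- scan_genome(ctl$pwm[[which(ctl$name == "UNUNU")]], b,
                      motif = "UNUNU")
  pr <- motif_distance_profile(m_un, anc, bg, b, half_window = 30)
  span <- pr$offset >= -15 & pr$offset <= -11  # planted match footprint
  expect_gte(pr$anchors[pr$offset == -15], max(pr$anchors) * 0.95)
  expect_gt(min(pr$anchors[span]), max(pr$anchors[!span]))
  expect_lt(max(pr$background),
            mean(pr$background) + 4 * stats::sd(pr$background))

  # motif absent from the genome: all-zero profile
  none <- m_un[0]
  pr0 <- motif_distance_profile(none, anc, bg, b, half_window = 10)
  expect_true(all(pr0$anchors == 0))
})

test_that("anchors shifted beyond gene ends leave the denominator", {
  # single gene on a long contig; anchor 20 nt from the gene end
  b <- make_seq_bundle(strrep("A", 300))
  gene_end <- 300
  anc <- GenomicRanges::GRanges("c1",
                                IRanges::IRanges(gene_end - 20, width = 1),
                                strand = "+")
  m <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 5), strand = "+",
                              score = 5, motif = "X")
  pr <- motif_distance_profile(m, anc, NULL, b, half_window = 30)
  expect_true(all(is.na(pr$anchors[pr$offset > 20])))
  expect_false(anyNA(pr$anchors[pr$offset <= 20]))
})

test_that("gene-body O/E is near 1 for uniform matches and elevated for
          3'UTR-planted ones", {
  sim <- simulate_genome(sim_config(n_genes = 60, genes_per_chrom = 60,
                                    seed = 41))
  b <- sim$bundle
  set.seed(6)
  uni <- sample_transcript_positions(b, 20000)
  prof <- genebody_enrichment(uni, b, n_background = 1e5, seed = 3)
  expect_true(all(prof$oe > 0.85 & prof$oe < 1.18))

  # matches only in 3'UTRs
  utr3 <- b$features[b$features$feature == "three_prime_UTR"]
  set.seed(7)
  idx <- sample(length(utr3), 3000, replace = TRUE)
  pos <- GenomicRanges::start(utr3)[idx] +
    floor(stats::runif(3000) * GenomicRanges::width(utr3)[idx])
  planted <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(utr3)[idx],
                                    IRanges::IRanges(pos, width = 1),
                                    strand = GenomicRanges::strand(utr3)[idx])
  prof3 <- genebody_enrichment(planted, b, n_background = 1e5, seed = 3)
  expect_true(all(prof3$oe[prof3$feature == "three_prime_UTR"] > 1.5))
  expect_true(all(prof3$observed[prof3$feature != "three_prime_UTR"] == 0))

  expect_error(genebody_enrichment(planted, b, n_background = 100), "100x")
})

test_that("anchor strata split by target genes and crosslink proximity", {
  sim <- simulate_genome(sim_config(n_genes = 60, genes_per_chrom = 60,
                                    seed = 47))
  b <- sim$bundle
  anc <- annotate_sites(sim$m6a_sites, b)
  m <- scan_genome(iupac_pwm("UNUNU"), b, motif = "UNUNU")

  # crosslink exactly 25 nt away: near; 26 nt: far
  a1 <- anc[1]
  cl25 <- GenomicRanges::shift(GenomicRanges::granges(a1), 25)
  cl26 <- GenomicRanges::shift(GenomicRanges::granges(a1), 26)
  pr_near <- split_anchor_profiles(a1, sim$target_genes, cl25, m, b,
                                   half_window = 5)
  expect_named(pr_near, "target_near")
  pr_far <- split_anchor_profiles(a1, sim$target_genes, cl26, m, b,
                                  half_window = 5)
  expect_named(pr_far, "target_far")

  # all anchors on non-targets: only that stratum is emitted
  suppressMessages(
    pr_nt <- split_anchor_profiles(anc, character(0), sim$crosslink_sites,
                                   m, b, half_window = 5))
  expect_named(pr_nt, "non_target")
})
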