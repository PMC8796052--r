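# Differential-editing calls: the replicate-support screen, the three
# post-filters, rank agreement with an exact conditional test, BH
# monotonicity, strand symmetry, and the diagnostic summaries.

test_that("editing_proportion follows G/(A+G) with a zero-coverage
          convention", {
  expect_equal(editing_proportion(2, 8), 0.2)
  expect_equal(editing_proportion(0, 5), 0)
  expect_equal(editing_proportion(7, 0), 1)
  expect_equal(editing_proportion(0, 0), 0)
  expect_error(editing_proportion(-1, 3), "non-negative")
})

test_that("sites without a putative edit in enough fusion replicates are
          not tested", {
  samples <- make_samples()
  cnt <- function(a, g) c(A = a, C = 0L, G = g, T = 0L)
  # site 1: edits in only 3 of 5 fusion samples; site 2: in all 5
  c1 <- c(lapply(c(3L, 5L, 4L, 0L, 0L), function(g) cnt(50L - g, g)),
          rep(list(cnt(50L, 0L)), 5))
  c2 <- c(lapply(c(3L, 5L, 4L, 2L, 2L), function(g) cnt(50L - g, g)),
          rep(list(cnt(50L, 0L)), 5))
  mat <- make_editing_matrix("c1", c(10, 20), "+", c("A", "A"),
                             list(c1, c2), samples)
  calls <- test_differential_editing(mat, min_support = 4)
  expect_false(calls$tested[1])
  expect_true(is.na(calls$p[1]))
  expect_true(calls$tested[2])
  expect_equal(calls$n_support, c(3, 5))
})

test_that("post-filters remove non-A-to-G changes, SNP-like sites and
          low-coverage sites", {
  samples <- make_samples()
  cnt <- function(ref_n, alt_n, ref_b, alt_b) {
    v <- c(A = 0L, C = 0L, G = 0L, T = 0L)
    v[ref_b] <- ref_n
    v[alt_b] <- alt_n
    v
  }
  rows <- list(
    # C->T on plus strand: wrong change
    c(lapply(1:5, function(i) cnt(40L, 10L, "C", "T")),
      lapply(1:5, function(i) cnt(49L, 1L, "C", "T"))),
    # SNP-like: control editing proportion ~0.98
    c(lapply(1:5, function(i) cnt(2L, 48L, "A", "G")),
      lapply(1:5, function(i) cnt(1L, 49L, "A", "G"))),
    # low coverage: fusion total 9 < 10
    c(lapply(c(1L, 1L, 1L, 1L, 0L), function(g) cnt(1L, g, "A", "G")),
      lapply(1:5, function(i) cnt(2L, 0L, "A", "G"))),
    # clean positive: A->G, moderate EP, good coverage
    c(lapply(1:5, function(i) cnt(35L, 15L, "A", "G")),
      lapply(1:5, function(i) cnt(50L, 0L, "A", "G"))),
    # minus strand T->C is the valid orientation
    c(lapply(1:5, function(i) cnt(35L, 15L, "T", "C")),
      lapply(1:5, function(i) cnt(50L, 0L, "T", "C")))
  )
  mat <- make_editing_matrix("c1", c(10, 20, 30, 40, 50),
                             c("+", "+", "+", "+", "-"),
                             c("C", "A", "A", "A", "T"), rows, samples)
  calls <- test_differential_editing(mat, min_support = 0)
  kept <- filter_calls(calls, mat)
  expect_setequal(kept$pos0, c(39, 49))
  removed <- attr(kept, "removed")
  expect_equal(removed$filter[removed$pos0 == 9], "not_A_to_G")
  expect_equal(removed$filter[removed$pos0 == 19], "snp_like")
  expect_equal(removed$filter[removed$pos0 == 29], "low_coverage")
})

test_that("p-values agree in rank with a one-sided exact conditional test
          on pooled counts", {
  set.seed(31)
  samples <- make_samples()
  # 40 sites with editing effects spanning null to strong
  rows <- list()
  eff <- seq(0, 0.3, length.out = 40)
  for (i in seq_along(eff)) {
    g_f <- rbinom(5, 50, 0.01 + eff[i])
    g_c <- rbinom(5, 50, 0.01)
    rows[[i]] <- c(lapply(g_f, function(g) c(A = 50L - g, C = 0L, G = g,
                                             T = 0L)),
                   lapply(g_c, function(g) c(A = 50L - g, C = 0L, G = g,
                                             T = 0L)))
  }
  mat <- make_editing_matrix("c1", seq(10, length.out = 40, by = 10), "+",
                             rep("A", 40), rows, samples)
  calls <- test_differential_editing(mat, min_support = 0, n_boot = 999,
                                     seed = 5)
  is_f <- samples$condition == "fusion"
  fisher_p <- vapply(seq_len(40), function(i) {
    af <- sum(mat$counts[i, is_f, "G"])
    ac <- sum(mat$counts[i, !is_f, "G"])
    nf <- sum(mat$counts[i, is_f, c("A", "G")])
    nc <- sum(mat$counts[i, !is_f, c("A", "G")])
    stats::phyper(af - 1, nf, nc, af + ac, lower.tail = FALSE)
  }, numeric(1))
  rho <- stats::cor(calls$p, fisher_p, method = "spearman")
  expect_gte(rho, 0.95)
})

test_that("adjusted p-values are BH-monotone and bounded below by raw p", {
  set.seed(77)
  cfg <- sim_config(n_genes = 40, genes_per_chrom = 40, n_null_sites = 300,
                    seed = 19)
  mat <- simulate_editing_counts(simulate_genome(cfg))
  calls <- test_differential_editing(mat, min_support = 2)
  tt <- calls[calls$tested, ]
  expect_true(all(tt$padj >= tt$p - 1e-12))
  ord <- order(tt$p)
  cummax_adj <- cummax(tt$padj[ord])
  expect_true(all(tt$padj[ord] >= cummax_adj - 1e-12))
})

test_that("reverse-complementing the genome and flipping strands yields
          the same calls", {
  cfg <- sim_config(n_genes = 20, genes_per_chrom = 20, n_null_sites = 100,
                    seed = 23)
  sim <- simulate_genome(cfg)
  mat <- simulate_editing_counts(sim)

  # mirror the matrix: positions reflected, strands flipped, base counts
  # complemented
  len <- Biostrings::width(sim$bundle$genome)[1]
  flip <- mat
  pos <- len - GenomicRanges::start(mat$sites) + 1L
  str <- ifelse(as.character(GenomicRanges::strand(mat$sites)) == "+",
                "-", "+")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip$sites <- GenomicRanges::GRanges("c1r",
                                       IRanges::IRanges(pos, width = 1),
                                       strand = str,
                                       ref = unname(comp[mat$sites$ref]))
  flip$counts <- mat$counts[, , c("T", "G", "C", "A")]
  dimnames(flip$counts)[[3]] <- c("A", "C", "G", "T")

  c1 <- test_differential_editing(mat, seed = 4)
  c2 <- test_differential_editing(flip, seed = 4)
  expect_equal(c1$p, c2$p)
  expect_equal(c1$ep_fusion, c2$ep_fusion)
  expect_equal(c1$significant, c2$significant)
})

test_that("sites annotate to the highest-expressed overlapping gene", {
  bundle <- make_toy_bundle()
  # overlapping-gene tie: add a second gene covering gA's 3'UTR
  feat2 <- c(bundle$features, GenomicRanges::GRanges(
    "c1", IRanges::IRanges(c(181, 211, 241), c(210, 240, 260)),
    strand = "+", gene_id = "gC",
    feature = c("five_prime_UTR", "CDS", "three_prime_UTR")))
  genes2 <- rbind(bundle$genes,
                  data.frame(gene_id = "gC", chrom = "c1", strand = "+",
                             start = 181, end = 260))
  b2 <- genome_bundle(bundle$genome, feat2, genes2)

  sites <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(230, 5), width = 1),
                                  strand = "+")
  ann <- annotate_sites(sites, b2, tpm = c(gA = 5, gC = 50))
  expect_equal(ann$gene_id[1], "gC")
  ann2 <- annotate_sites(sites, b2, tpm = c(gA = 50, gC = 5))
  expect_equal(ann2$gene_id[1], "gA")
  expect_equal(ann2$feature[1], "three_prime_UTR")
  expect_equal(ann$feature[2], "intergenic")
  # tie on TPM: lexicographic gene id
  ann3 <- annotate_sites(sites, b2, tpm = c(gA = 5, gC = 5))
  expect_equal(ann3$gene_id[1], "gA")
})

test_that("the edit-site context matrix is strand-aware with an all-A
          centre", {
  # plus-strand site at 11 preceded by T, minus-strand site over genomic T
  seqstr <- paste0(strrep("C", 9), "TAG", strrep("C", 8),
                   "CTA", strrep("C", 7))  # minus site: sense UAG reversed
  b <- make_seq_bundle(seqstr)
  sites <- GenomicRanges::GRanges("c1",
                                  IRanges::IRanges(c(11, 22), width = 1),
                                  strand = c("+", "-"))
  m <- edit_site_logo_matrix(sites, b, flank = 1)
  expect_equal(colnames(m), c("-1", "0", "1"))
  expect_equal(unname(colSums(m)), rep(1, 3))
  expect_equal(m["A", "0"], 1)   # centre all-A on the sense strand
  expect_equal(m["U", "-1"], 1)  # both sites preceded by U in sense terms
  # near-edge site is skipped with a message
  edge <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(1, 11), width = 1),
                                 strand = "+")
  expect_message(m2 <- edit_site_logo_matrix(edge, b, flank = 2), "skipped")
})

test_that("PCA separates conditions with planted editing and collapses
          without", {
  cfg <- sim_config(n_genes = 40, genes_per_chrom = 40, n_null_sites = 100,
                    seed = 37)
  sim <- simulate_genome(cfg)
  mat <- simulate_editing_counts(sim)
  calls <- test_differential_editing(mat)
  sc <- pca_editing(calls, mat)
  f <- sc$PC1[sc$condition == "fusion"]
  c <- sc$PC1[sc$condition == "control"]
  # between-condition separation exceeds within-condition spread
  gap <- abs(mean(f) - mean(c))
  expect_gt(gap, 2 * max(stats::sd(f), stats::sd(c)))
  expect_lt(abs(mean(sc$PC1)), 1e-8)  # centred scores
})

test_that("editing proportions proportional to ADAR TPM give r = 1 and a
          centred shuffled background", {
  tpm <- c(10, 20, 30, 40, 50, 10, 20, 30, 40, 50)
  samples <- make_samples(tpm = tpm)
  rows <- lapply(1:12, function(i) {
    lapply(seq_len(10), function(s) {
      g <- as.integer(round(tpm[s]))  # EP exactly proportional to TPM
      c(A = 1000L - g, C = 0L, G = g, T = 0L)
    })
  })
  mat <- make_editing_matrix("c1", seq(10, length.out = 12, by = 200), "+",
                             rep("A", 12), rows, samples)
  calls <- test_differential_editing(mat, min_support = 0, alpha = 1,
                                     lfc_min = -Inf)
  calls$significant <- TRUE
  res <- adar_correlation(calls, mat, shuffles = 200, seed = 2)
  expect_true(all(abs(res$correlations$r_fusion - 1) < 1e-9))
  se <- stats::sd(res$background) / sqrt(length(res$background))
  expect_lt(abs(mean(res$background)), 3 * se + 0.02)

  # constant TPM: correlation undefined, reported missing
  mat2 <- mat
  mat2$samples$adar_tpm <- rep(5, 10)
  res2 <- adar_correlation(calls, mat2, shuffles = 5, seed = 2)
  expect_true(all(is.na(res2$correlations$r_fusion)))
})

test_that("coexpression proportion follows its defining ratio", {
  set.seed(11)
  sc <- matrix(0L, 4, 10,
               dimnames = list(c("READER", "t1", "t2", "t3"), NULL))
  sc["READER", 1:6] <- 1L
  sc["t1", c(1:4, 7:12 * 0 + 7)] <- 1L  # cells 1..4 and 7: 10 expressing? no
  sc["t1", ] <- 0L
  sc["t1", c(1, 2, 3, 4, 7, 8, 9, 10)] <- 1L  # 8 cells, 4 with reader
  sc["t2", c(1, 2)] <- 1L                     # subset of reader cells
  res <- coexpression_editing(c("t1", "t2", "t3"), sc, "READER")
  expect_equal(res$coexpr[res$gene == "t1"], 0.5)
  expect_equal(res$coexpr[res$gene == "t2"], 1.0)
  expect_true(is.na(res$coexpr[res$gene == "t3"]))  # expressed nowhere
  expect_error(coexpression_editing("t1", sc, "ABSENT"), "absent")
})
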