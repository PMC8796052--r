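# Differential-editing calling from fusion-vs-control base counts:
# beta-binomial likelihood-ratio test per site with a replicate-support
# screen, post-filters (base identity, SNP-like proportions, minimum
# coverage), gene annotation, and the diagnostic summaries (sequence
# context matrix, PCA, ADAR-expression correlation, single-cell
# coexpression).

#' Editing proportion
#'
#' The fraction of reads carrying the edited base: alt/(alt + ref),
#' i.e. G/(A+G) on the sense strand (C/(U+C) read from the minus strand).
#' Returns 0 when both counts are 0 (no coverage).
#'
#' @param alt_count,ref_count non-negative counts (vectorised)
#' @return proportion in [0, 1]
#' @export
editing_proportion <- function(alt_count, ref_count) {
  if (any(alt_count < 0) || any(ref_count < 0)) {
    stop("counts must be non-negative")
  }
  tot <- alt_count + ref_count
  ifelse(tot == 0, 0, alt_count / tot)
}

# per-site alt base = the non-reference base with the highest total count;
# returns list of site x sample matrices (alt, ref) plus the alt base
extract_alt_ref <- function(mat) {
  n_sites <- length(mat$sites)
  totals <- apply(mat$counts, c(1, 3), sum)  # site x base
  ri <- match(mat$sites$ref, BASES)
  totals[cbind(seq_len(n_sites), ri)] <- -1L
  ai <- max.col(totals, ties.method = "first")
  alt <- matrix(0L, n_sites, nrow(mat$samples))
  ref <- matrix(0L, n_sites, nrow(mat$samples))
  for (s in seq_len(nrow(mat$samples))) {
    alt[, s] <- mat$counts[cbind(seq_len(n_sites), s, ai)]
    ref[, s] <- mat$counts[cbind(seq_len(n_sites), s, ri)]
  }
  list(alt = alt, ref = ref, alt_base = BASES[ai])
}

# shared overdispersion for the whole matrix: within-condition Pearson
# method of moments pooled across all sites (per-site estimates are far
# too noisy at the low editing counts typical of this data)
estimate_rho_matrix <- function(alt, size, cond) {
  chi <- 0
  df <- 0
  nsum <- 0
  k <- 0
  for (g in unique(cond)) {
    sel <- cond == g
    xg <- alt[, sel, drop = FALSE]
    ng <- size[, sel, drop = FALSE]
    p_i <- rowSums(xg) / pmax(1, rowSums(ng))
    ok_site <- p_i > 0 & p_i < 1 & rowSums(ng > 0) >= 2
    if (!any(ok_site)) next
    xg <- xg[ok_site, , drop = FALSE]
    ng <- ng[ok_site, , drop = FALSE]
    p_i <- p_i[ok_site]
    contrib <- (xg - ng * p_i)^2 / (ng * p_i * (1 - p_i))
    contrib[ng == 0] <- 0
    chi <- chi + sum(contrib)
    df <- df + sum(rowSums(ng > 0) - 1)
    nsum <- nsum + sum(ng)
    k <- k + sum(ng > 0)
  }
  if (df <= 0 || k == 0) return(0)
  nbar <- nsum / k
  if (nbar <= 1) return(0)
  min(max((chi / df - 1) / (nbar - 1), 0), 0.95)
}

#' Test for differential editing between fusion and control samples
#'
#' Per site, compares a pooled beta-binomial editing rate against separate
#' per-condition rates by likelihood ratio, with a single overdispersion
#' shared across the matrix (within-condition method of moments pooled
#' over all sites). Because editing counts are typically tiny, p-values
#' are calibrated by a per-site parametric bootstrap under the fitted
#' null; the chi-square tail approximation is used only for statistics
#' already far beyond the bootstrap's resolution. The reported p-value is
#' one-sided for fusion > control. Sites lacking a putative edit (alt >=
#' 1) in at least \code{min_support} fusion samples are screened out and
#' not tested. P-values are BH-adjusted across all tested sites.
#'
#' @param mat an \code{EditingMatrix}
#' @param min_support minimum number of fusion samples with alt >= 1 for a
#'   site to be tested (default 4); 0 disables the screen
#' @param alpha significance level on the adjusted p-value (default 0.01)
#' @param lfc_min minimum log2 fold change of condition-mean editing
#'   proportions (default 1); log2FC uses pseudocount 0.001
#' @param n_boot bootstrap replicates per site (default 199)
#' @param seed RNG seed for the bootstrap
#' @param chi2_tail one-sided chi-square p below which the asymptotic tail
#'   replaces the bootstrap (default 1e-4)
#' @return data.frame of editing calls: site key columns, per-condition
#'   editing proportions, log2fc, p, padj, support count, \code{tested}
#'   and \code{significant} flags; one row per matrix site
#' @export
test_differential_editing <- function(mat, min_support = 4, alpha = 0.01,
                                      lfc_min = 1, n_boot = 199, seed = 1,
                                      chi2_tail = 1e-4) {
  stopifnot(inherits(mat, "EditingMatrix"))
  cond <- mat$samples$condition
  if (length(unique(cond)) < 2) {
    stop("need both fusion and control samples")
  }
  if (sum(cond == "fusion") < 2 || sum(cond == "control") < 2) {
    stop("need >= 2 samples per condition")
  }
  if (min_support > sum(cond == "fusion")) {
    stop("min_support exceeds the number of fusion samples")
  }
  ar <- extract_alt_ref(mat)
  n_sites <- length(mat$sites)
  is_f <- cond == "fusion"

  size <- ar$alt + ar$ref
  epm <- ar$alt / pmax(size, 1L)
  epm[size == 0] <- NA
  ep_f <- rowMeans(epm[, is_f, drop = FALSE], na.rm = TRUE)
  ep_c <- rowMeans(epm[, !is_f, drop = FALSE], na.rm = TRUE)
  ep_f[is.nan(ep_f)] <- 0
  ep_c[is.nan(ep_c)] <- 0
  eps <- 0.001
  log2fc <- log2((ep_f + eps) / (ep_c + eps))
  n_support <- rowSums(ar$alt[, is_f, drop = FALSE] >= 1L)
  tested <- n_support >= min_support & rowSums(size) > 0

  rho <- estimate_rho_matrix(ar$alt, size, cond)
  set.seed(seed)
  p <- rep(NA_real_, n_sites)
  for (i in which(tested)) {
    x <- ar$alt[i, ]
    n <- size[i, ]
    s_obs <- bb_lrt_stat(x, n, is_f, rho)
    p_chi <- stats::pchisq(abs(s_obs), df = 1, lower.tail = FALSE) / 2
    if (s_obs > 0 && p_chi < chi2_tail) {
      p[i] <- p_chi
    } else {
      sb <- bb_boot_stats(n, is_f, sum(x) / max(1, sum(n)), rho, n_boot)
      p[i] <- (1 + sum(sb >= s_obs)) / (n_boot + 1)
    }
  }
  padj <- rep(NA_real_, n_sites)
  padj[tested] <- stats::p.adjust(p[tested], method = "BH")

  data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(mat$sites)),
    pos0 = GenomicRanges::start(mat$sites) - 1L,
    strand = as.character(GenomicRanges::strand(mat$sites)),
    ref = mat$sites$ref,
    alt = ar$alt_base,
    ep_fusion = ep_f,
    ep_control = ep_c,
    log2fc = log2fc,
    p = p,
    padj = padj,
    n_support = n_support,
    tested = tested,
    significant = tested & !is.na(padj) & padj < alpha & log2fc > lfc_min,
    site_idx = seq_len(n_sites),
    stringsAsFactors = FALSE
  )
}

#' Apply the post-calling filters to editing calls
#'
#' Retains only calls that (1) correspond to an A-to-G change on the plus
#' strand or a T-to-C change on the minus strand, (2) are not SNP-like
#' (editing proportion in either condition at or above
#' \code{snp_threshold}), and (3) have summed fusion-sample coverage at
#' the edited base of at least \code{min_coverage} reads.
#'
#' @param calls data.frame from \code{\link{test_differential_editing}}
#' @param mat the \code{EditingMatrix} the calls came from
#' @param snp_threshold editing proportion treated as "at or close to 1"
#'   (default 0.9)
#' @param min_coverage minimum summed fusion coverage (default 10)
#' @return the filtered calls, with a \code{filter} column recording why
#'   removed rows were dropped attached as attribute \code{"removed"}
#' @export
filter_calls <- function(calls, mat, snp_threshold = 0.9,
                         min_coverage = 10) {
  ar <- extract_alt_ref(mat)
  is_f <- mat$samples$condition == "fusion"
  cov_f <- rowSums((ar$alt + ar$ref)[, is_f, drop = FALSE])
  idx <- calls$site_idx

  ag_ok <- (calls$ref == "A" & calls$strand == "+" & calls$alt == "G") |
    (calls$ref == "T" & calls$strand == "-" & calls$alt == "C")
  snp_bad <- calls$ep_fusion >= snp_threshold |
    calls$ep_control >= snp_threshold
  cov_ok <- cov_f[idx] >= min_coverage

  keep <- ag_ok & !snp_bad & cov_ok
  reason <- rep(NA_character_, nrow(calls))
  reason[!ag_ok] <- "not_A_to_G"
  reason[ag_ok & snp_bad] <- "snp_like"
  reason[ag_ok & !snp_bad & !cov_ok] <- "low_coverage"
  removed <- cbind(calls[!keep, , drop = FALSE],
                   filter = reason[!keep])
  out <- calls[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Annotate sites to genes and gene-body features
#'
#' Thin wrapper over \code{\link{annotate_positions}} that applies the
#' highest-expression tie-break: overlapping-gene ties go to the gene with
#' the higher TPM, then lexicographic gene id. Intergenic sites are kept
#' with feature \code{"intergenic"}.
#'
#' @param sites width-1 GRanges
#' @param bundle a GenomeBundle
#' @param tpm named numeric vector of gene TPMs (missing genes count 0)
#' @return annotated GRanges
#' @export
annotate_sites <- function(sites, bundle, tpm = NULL) {
  annotate_positions(sites, bundle, tpm)
}

#' Nucleotide-frequency matrix around edit sites
#'
#' Extracts the sense-strand sequence at and +/- \code{flank} nt of each
#' site and tabulates per-column base frequencies. After the base-identity
#' filter the centre column is all-A by construction.
#'
#' @param sites width-1 GRanges with strand
#' @param bundle a GenomeBundle
#' @param flank nt either side (default 2)
#' @return 4 x (2*flank+1) matrix of frequencies (rows A/C/G/U, columns
#'   offsets -flank..flank); columns sum to 1
#' @export
edit_site_logo_matrix <- function(sites, bundle, flank = 2) {
  lens <- Biostrings::width(bundle$genome)[
    match(as.character(GenomeInfoDb::seqnames(sites)),
          names(bundle$genome))]
  pos <- GenomicRanges::start(sites)
  ok <- pos - flank >= 1 & pos + flank <= lens
  if (any(!ok)) {
    message(sum(!ok), " site(s) too close to a contig edge; skipped")
    sites <- sites[ok]
    pos <- pos[ok]
  }
  if (length(sites) == 0) stop("no sites within sequence bounds")
  win <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(sites),
                                IRanges::IRanges(pos - flank, pos + flank),
                                strand = GenomicRanges::strand(sites))
  seqs <- extract_seq(bundle$genome, win)  # strand-aware
  m <- Biostrings::consensusMatrix(seqs, as.prob = TRUE)[BASES, , drop = FALSE]
  rownames(m) <- c("A", "C", "G", "U")
  colnames(m) <- as.character(seq(-flank, flank))
  m
}

# per-sample editing-proportion matrix (sites x samples)
ep_per_sample <- function(mat, site_idx = NULL) {
  ar <- extract_alt_ref(mat)
  size <- ar$alt + ar$ref
  epm <- ar$alt / pmax(size, 1L)
  epm[size == 0] <- 0
  if (!is.null(site_idx)) epm <- epm[site_idx, , drop = FALSE]
  colnames(epm) <- mat$samples$sample
  epm
}

#' PCA of per-sample editing proportions at significant sites
#'
#' @param calls calls data.frame (rows with \code{significant == TRUE} are
#'   used)
#' @param mat the \code{EditingMatrix}
#' @param n_components number of components to return (default 2)
#' @return data.frame of sample scores with condition labels, plus the
#'   proportion of variance per component as attribute \code{"var_explained"}
#' @export
pca_editing <- function(calls, mat, n_components = 2) {
  idx <- calls$site_idx[calls$significant]
  if (length(idx) < 2) stop("need >= 2 significant sites for PCA")
  epm <- t(ep_per_sample(mat, idx))  # samples x sites
  if (nrow(epm) < 2) stop("need >= 2 samples")
  keep <- apply(epm, 2, stats::sd) > 0
  if (!any(keep)) stop("editing proportions are constant across samples")
  pc <- stats::prcomp(epm[, keep, drop = FALSE], center = TRUE,
                      scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  out <- data.frame(sample = mat$samples$sample,
                    condition = mat$samples$condition,
                    pc$x[, seq_len(k), drop = FALSE],
                    stringsAsFactors = FALSE)
  attr(out, "var_explained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  out
}

#' Correlation of editing proportions with ADAR expression
#'
#' Pearson correlation per significant site between per-sample editing
#' proportions and the samples' ADAR TPM, within each condition. The
#' background distribution is obtained by scrambling the TPM vector.
#'
#' @param calls calls data.frame
#' @param mat the \code{EditingMatrix} (samples carry \code{adar_tpm})
#' @param shuffles number of scrambles for the background (default 100)
#' @param seed RNG seed for the scrambles
#' @return list with \code{correlations} (data.frame: site, r_fusion,
#'   r_control) and \code{background} (numeric vector of shuffled fusion
#'   correlations)
#' @export
adar_correlation <- function(calls, mat, shuffles = 100, seed = 1) {
  idx <- calls$site_idx[calls$significant]
  if (length(idx) == 0) stop("no significant sites")
  tpm <- mat$samples$adar_tpm
  cond <- mat$samples$condition
  if (sum(cond == "fusion") < 3 || sum(cond == "control") < 3) {
    stop("need >= 3 samples per condition for correlations")
  }
  epm <- ep_per_sample(mat, idx)

  cor_safe <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  r_f <- apply(epm[, cond == "fusion", drop = FALSE], 1,
               cor_safe, y = tpm[cond == "fusion"])
  r_c <- apply(epm[, cond == "control", drop = FALSE], 1,
               cor_safe, y = tpm[cond == "control"])

  set.seed(seed)
  bg <- numeric(0)
  ep_fus <- epm[, cond == "fusion", drop = FALSE]
  tpm_f <- tpm[cond == "fusion"]
  for (b in seq_len(shuffles)) {
    tpm_sh <- sample(tpm_f)
    bg <- c(bg, apply(ep_fus, 1, cor_safe, y = tpm_sh))
  }
  list(
    correlations = data.frame(
      site = paste0(calls$chrom[calls$significant], ":",
                    calls$pos0[calls$significant], ":",
                    calls$strand[calls$significant]),
      r_fusion = r_f, r_control = r_c, stringsAsFactors = FALSE),
    background = bg[!is.na(bg)]
  )
}

#' Per-target coexpression with the reader gene, joined to maximum editing
#' proportion
#'
#' Coexpression = (# cells expressing reader AND target) / (# cells
#' expressing target), from a single-cell expression matrix. "Expressing"
#' means count > \code{threshold}.
#'
#' @param targets character vector of target gene ids
#' @param sc_matrix genes x cells matrix (binary or counts); rownames are
#'   gene ids
#' @param reader_gene the reader's gene id (must be a rowname)
#' @param calls optional filtered calls annotated with \code{gene_id}
#'   (data.frame with columns gene_id and ep_fusion) used to join the
#'   maximum editing proportion per gene
#' @param threshold expression threshold (default 0: count > 0)
#' @return data.frame: gene, n_cells, coexpr (NA for genes expressed in 0
#'   cells or absent from the matrix), and max_ep when calls are given
#' @export
coexpression_editing <- function(targets, sc_matrix, reader_gene,
                                 calls = NULL, threshold = 0) {
  if (!(reader_gene %in% rownames(sc_matrix))) {
    stop("reader gene ", reader_gene, " absent from the matrix")
  }
  reader_on <- sc_matrix[reader_gene, ] > threshold
  out <- data.frame(gene = targets, n_cells = NA_integer_,
                    coexpr = NA_real_, stringsAsFactors = FALSE)
  present <- targets %in% rownames(sc_matrix)
  for (i in which(present)) {
    on <- sc_matrix[targets[i], ] > threshold
    n <- sum(on)
    out$n_cells[i] <- n
    out$coexpr[i] <- if (n == 0) NA_real_ else sum(on & reader_on) / n
  }
  if (!is.null(calls)) {
    mx <- tapply(calls$ep_fusion, calls$gene_id, max)
    out$max_ep <- as.numeric(mx[out$gene])
  }
  out
}
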