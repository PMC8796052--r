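# Post-processing of single-nucleotide crosslink sites: collapsing runs of
# directly adjacent peaks to the dominant one, building collapsed
# crosslink sites (CSS), splitting IDR-dependent/independent peak sets by
# proximity between full-length and truncated-protein libraries, and
# site-level diagnostics.

#' Collapse directly adjacent crosslink sites to the dominant peak
#'
#' Runs of sites at consecutive genomic positions on the same strand and
#' chromosome reduce to the single site with the highest score; score ties
#' keep the 5'-most genomic position. Idempotent.
#'
#' @param sites width-1 GRanges with a \code{score} column
#' @return the collapsed GRanges
#' @export
collapse_adjacent <- function(sites) {
  if (is.null(sites$score) || anyNA(sites$score)) {
    stop("crosslink sites must carry scores")
  }
  if (length(sites) == 0) return(sites)
  ord <- order(as.character(GenomeInfoDb::seqnames(sites)),
               as.character(GenomicRanges::strand(sites)),
               GenomicRanges::start(sites))
  s <- sites[ord]
  key <- paste0(GenomeInfoDb::seqnames(s), ":", GenomicRanges::strand(s))
  pos <- GenomicRanges::start(s)
  new_run <- c(TRUE, !(key[-1] == key[-length(key)] &
                         pos[-1] == pos[-length(pos)] + 1L))
  run_id <- cumsum(new_run)
  keep <- vapply(split(seq_along(s), run_id), function(idx) {
    idx[which.max(s$score[idx])]  # which.max takes the first (5'-most) tie
  }, integer(1))
  s[sort(keep)]
}

#' Extend collapsed peaks into collapsed crosslink sites (CSS)
#'
#' Each dominant peak is extended \code{ext} nt up- and downstream,
#' yielding intervals of length 2*ext+1 (9 nt by default) centred on the
#' peak. Intervals are clipped at contig edges with a warning.
#'
#' @param sites collapsed width-1 GRanges
#' @param ext extension in nt each side (default 4)
#' @return GRanges of CSS intervals (metadata preserved)
#' @export
make_css <- function(sites, ext = 4) {
  # out-of-bounds ranges are expected here; we warn once after trimming
  out <- suppressWarnings(
    GenomicRanges::resize(sites, width = 2 * ext + 1, fix = "center"))
  lens <- GenomeInfoDb::seqlengths(out)
  clipped <- GenomicRanges::start(out) < 1
  if (!all(is.na(lens))) {
    ends <- lens[as.character(GenomeInfoDb::seqnames(out))]
    clipped <- clipped | (!is.na(ends) & GenomicRanges::end(out) > ends)
  }
  if (any(clipped)) {
    warning(sum(clipped), " CSS interval(s) clipped at contig edges")
  }
  GenomicRanges::trim(out)
}

#' Split full-length-library sites by dependence on the IDR
#'
#' A full-length-library crosslink site is IDR-independent if a
#' truncated-library site lies within \code{max_dist} nt on the same
#' chromosome and strand, IDR-dependent otherwise (exclusive to the
#' full-length library at distance > \code{max_dist}). The partition is
#' exact and exhaustive.
#'
#' @param full_length width-1 GRanges from the full-length-protein library
#' @param truncated width-1 GRanges from the truncated-protein library
#' @param max_dist distance threshold in nt (default 10)
#' @return list with \code{idr_independent} and \code{idr_dependent}
#' @export
split_idr_dependence <- function(full_length, truncated, max_dist = 10) {
  if (length(truncated) == 0) {
    return(list(idr_independent = full_length[0],
                idr_dependent = full_length))
  }
  d <- pos_nearest_dist(full_length, truncated, ignore_strand = FALSE)
  near <- d <= max_dist
  list(idr_independent = full_length[near],
       idr_dependent = full_length[!near])
}

#' Nucleotide proportions at sites
#'
#' Strand-corrected base identity at each single-nucleotide site, reported
#' over the RNA alphabet A/C/G/U.
#'
#' @param sites width-1 GRanges
#' @param bundle a GenomeBundle
#' @return named numeric vector of proportions (sums to 1)
#' @export
nucleotide_proportions <- function(sites, bundle) {
  lens <- Biostrings::width(bundle$genome)[
    match(as.character(GenomeInfoDb::seqnames(sites)),
          names(bundle$genome))]
  if (any(GenomicRanges::start(sites) < 1 |
            GenomicRanges::start(sites) > lens)) {
    stop("site(s) out of sequence bounds")
  }
  b <- as.character(extract_seq(bundle$genome,
                                GenomicRanges::granges(sites)))
  tab <- table(factor(b, levels = BASES))
  p <- as.numeric(tab) / length(sites)
  names(p) <- c("A", "C", "G", "U")
  p
}

#' Cumulative proportion of query sites within a distance of the nearest
#' reference site
#'
#' Unsigned genomic nearest-neighbour distances (same chromosome; strand
#' ignored), accumulated over d = 0..max_d.
#'
#' @param query,reference width-1 GRanges (both non-empty)
#' @param max_d maximum distance reported (default 200)
#' @return data.frame with columns \code{distance} and \code{proportion}
#'   (non-decreasing); the proportion at \code{max_d} is the fraction of
#'   query sites within \code{max_d} nt of a reference site
#' @export
distance_to_nearest <- function(query, reference, max_d = 200) {
  if (length(reference) == 0) stop("reference site table is empty")
  if (length(query) == 0) stop("query site table is empty")
  dist <- pos_nearest_dist(query, reference, ignore_strand = TRUE)
  data.frame(
    distance = 0:max_d,
    proportion = vapply(0:max_d, function(x) mean(dist <= x), numeric(1))
  )
}

#' Metagene profile: per-bin observed/expected site density along the gene
#' body
#'
#' Sites are assigned to gene-body bins (5'UTR, CDS, 3'UTR at
#' \code{bins_per_feature} bins each); the expected distribution comes
#' from a seeded random-position background over the same transcripts.
#' Uniformly distributed sites give ratios near 1.
#'
#' @param sites width-1 GRanges (annotated or not; annotation is applied)
#' @param bundle a GenomeBundle
#' @param bins_per_feature bins per feature (default 10)
#' @param n_background background positions (default 1e5)
#' @param seed RNG seed for the background draw
#' @return data.frame: feature, bin (1..bins_per_feature within feature),
#'   observed and expected proportions, and their ratio \code{oe}
#' @export
metagene_profile <- function(sites, bundle, bins_per_feature = 10,
                             n_background = 1e5, seed = 1) {
  if (length(sites) == 0) stop("empty site table")
  ann <- annotate_positions(sites, bundle)
  ann <- ann[ann$feature != "intergenic"]
  if (length(ann) == 0) stop("no sites overlap annotated transcripts")
  obs_bin <- genebody_bin(ann$feature, ann$rel_pos, bins_per_feature)
  set.seed(seed)
  bg <- sample_transcript_positions(bundle, n_background)
  bg <- annotate_positions(bg, bundle)
  exp_bin <- genebody_bin(bg$feature, bg$rel_pos, bins_per_feature)
  nb <- 3 * bins_per_feature
  obs <- tabulate(obs_bin, nb) / length(ann)
  expd <- tabulate(exp_bin, nb) / length(bg)
  data.frame(
    feature = rep(FEATURE_LEVELS, each = bins_per_feature),
    bin = rep(seq_len(bins_per_feature), 3),
    observed = obs,
    expected = expd,
    oe = ifelse(expd > 0, obs / expd, NA_real_)
  )
}
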