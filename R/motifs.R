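# PWM construction from IUPAC patterns or aligned windows, genome-wide
# log-odds scanning, location-matched background sampling, motif distance
# profiles around anchor sites (per-1000 normalisation with gene-overlap
# eligibility) and gene-body observed/expected enrichment.

#' Background letter frequencies used for PWM log-odds
#'
#' Defaults to the transcriptome composition used throughout the motif
#' analysis: A 0.273, C 0.165, G 0.173, U 0.389.
#'
#' @return named numeric vector over A/C/G/T summing to 1
#' @export
default_background <- function() {
  c(A = 0.273, C = 0.165, G = 0.173, T = 0.389)
}

#' Load the packaged motif catalogue
#'
#' A synthetic reconstruction of the kind of curated 48-motif catalogue
#' used for m6A/crosslink motif analysis: the RRACH/DRACH consensus
#' family, GGAU variants, URUAY-type elements and U/Y-rich tracts, with
#' provenance tags. PWMs are derived from the IUPAC patterns (uniform
#' frequencies over allowed bases) against the supplied background.
#'
#' @param path TSV with columns name, iupac, family, provenance (defaults
#'   to the packaged synthetic catalogue)
#' @param background named base frequencies (default
#'   \code{\link{default_background}})
#' @param pseudo pseudo-frequency added per base (default 0.001)
#' @return data.frame with columns name, iupac, family, provenance and a
#'   list-column \code{pwm} of 4 x L log2-odds matrices
#' @export
motif_catalogue <- function(path = system.file("extdata",
                                               "motif_catalogue_synthetic.tsv",
                                               package = "tribeclip"),
                            background = default_background(),
                            pseudo = 0.001) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$pwm <- lapply(df$iupac, iupac_pwm, background = background,
                   pseudo = pseudo)
  df
}

# frequency matrix (4 x L over BASES) -> log2-odds PWM with pseudo-frequency
pwm_from_freq <- function(freq, background, pseudo) {
  stopifnot(nrow(freq) == 4)
  adj <- (freq + pseudo) / (1 + 4 * pseudo)
  m <- log2(adj / as.numeric(background[BASES]))
  rownames(m) <- BASES
  m
}

#' Build a PWM from aligned equal-length sequence windows
#'
#' Entry (b, j) = log2(p_adj(b, j) / p(b)) where p_adj includes a small
#' pseudo-frequency; a column whose observed frequency equals the
#' background gives 0 as pseudo tends to 0.
#'
#' @param aligned_windows character vector of equal-length sequences
#'   (U accepted, treated as T)
#' @param background named base frequencies over A/C/G/T
#' @param pseudo pseudo-frequency per base (default 0.001)
#' @return 4 x L log2-odds matrix (rows A/C/G/T)
#' @export
build_pwm <- function(aligned_windows, background = default_background(),
                      pseudo = 0.001) {
  stopifnot(length(aligned_windows) >= 1)
  w <- to_dna(aligned_windows)
  if (length(unique(nchar(w))) != 1) {
    stop("aligned windows must all have the same length")
  }
  L <- nchar(w[1])
  chars <- matrix(unlist(strsplit(w, "")), nrow = length(w), byrow = TRUE)
  freq <- vapply(seq_len(L), function(j) {
    as.numeric(table(factor(chars[, j], levels = BASES))) / length(w)
  }, numeric(4))
  pwm_from_freq(freq, background, pseudo)
}

#' Derive a PWM directly from an IUPAC pattern
#'
#' Partial ambiguity codes expand to uniform frequencies over their
#' allowed bases before the log-odds transform. A fully degenerate N
#' carries no positional information, so its column takes the background
#' frequencies (log-odds exactly 0 for every base).
#'
#' @inheritParams build_pwm
#' @param iupac IUPAC string (U treated as T)
#' @export
iupac_pwm <- function(iupac, background = default_background(),
                      pseudo = 0.001) {
  allowed <- iupac_allowed(iupac)
  freq <- vapply(allowed, function(b) {
    if (length(b) == 4) return(as.numeric(background[BASES]))
    f <- numeric(4)
    f[match(b, BASES)] <- 1 / length(b)
    f
  }, numeric(4))
  rownames(freq) <- BASES
  # pseudo shifts background columns off 0; re-anchor them exactly
  m <- pwm_from_freq(freq, background, pseudo)
  n_cols <- vapply(allowed, length, integer(1)) == 4
  m[, n_cols] <- 0
  m
}

# score all windows of one coded sequence against a PWM (vectorised)
score_windows <- function(codes, pwm) {
  L <- ncol(pwm)
  n <- length(codes) - L + 1
  if (n < 1) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(L)) {
    v <- pwm[cbind(codes[j:(j + n - 1)], j)]
    v[is.na(v)] <- -Inf  # non-ACGT characters never match
    sc <- sc + v
  }
  sc
}

#' Scan sequences with a PWM on both strands
#'
#' Every window whose summed log-odds score reaches \code{min_score} is
#' returned; identical to exhaustive window enumeration.
#'
#' @param pwm 4 x L log2-odds matrix (rows A/C/G/T)
#' @param sequences a \code{DNAStringSet} (or a GenomeBundle, whose genome
#'   is used)
#' @param min_score minimum score (default 4)
#' @param motif optional motif name recorded on the matches
#' @return GRanges of matches with \code{score} (and \code{motif})
#' @export
scan_genome <- function(pwm, sequences, min_score = 4, motif = NA_character_) {
  if (inherits(sequences, "GenomeBundle")) sequences <- sequences$genome
  stopifnot(all(is.finite(pwm)))
  L <- ncol(pwm)
  out <- list()
  for (ci in seq_along(sequences)) {
    s <- as.character(sequences[[ci]])
    len <- nchar(s)
    if (len < L) next
    codes <- base_codes(strsplit(s, "")[[1]])
    sc_p <- score_windows(codes, pwm)
    hit_p <- which(sc_p >= min_score)
    rc_codes <- rev(5L - codes)  # A<->T, C<->G on integer codes
    sc_m <- score_windows(rc_codes, pwm)
    hit_m <- which(sc_m >= min_score)
    if (length(hit_p) > 0) {
      out[[length(out) + 1]] <- data.frame(
        chrom = names(sequences)[ci], start = hit_p,
        strand = "+", score = sc_p[hit_p])
    }
    if (length(hit_m) > 0) {
      out[[length(out) + 1]] <- data.frame(
        chrom = names(sequences)[ci], start = len - (hit_m + L - 1) + 1,
        strand = "-", score = sc_m[hit_m])
    }
  }
  if (length(out) == 0) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$score <- numeric(0)
    S4Vectors::mcols(gr)$motif <- character(0)
    return(gr)
  }
  df <- do.call(rbind, out)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, width = L),
                               strand = df$strand, score = df$score,
                               motif = motif)
  GenomeInfoDb::seqlevels(gr) <- names(sequences)
  GenomeInfoDb::seqlengths(gr) <- Biostrings::width(sequences)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Scan a whole motif catalogue
#'
#' @param catalogue data.frame from \code{\link{motif_catalogue}}
#' @param sequences DNAStringSet or GenomeBundle
#' @param min_score minimum log-odds score (default 4)
#' @return GRanges of matches with \code{score} and \code{motif}
#' @export
scan_catalogue <- function(catalogue, sequences, min_score = 4) {
  grl <- lapply(seq_len(nrow(catalogue)), function(i) {
    scan_genome(catalogue$pwm[[i]], sequences, min_score,
                motif = catalogue$name[i])
  })
  do.call(c, grl)
}

#' Sample a location-matched background site set
#'
#' Each anchor site is matched by a random site in a non-target gene at
#' the same gene-body feature and relative-position bin (10 bins per
#' feature by default). The joint (feature, bin) histogram of the
#' background equals that of the anchors exactly.
#'
#' @param sites width-1 GRanges annotated with \code{feature} and
#'   \code{rel_pos} (see \code{\link{annotate_sites}})
#' @param bundle a GenomeBundle
#' @param non_target_genes character vector of gene ids the background may
#'   use (typically expressed genes absent from every target set)
#' @param bins_per_feature bins per feature (default 10)
#' @param seed RNG seed
#' @return width-1 GRanges of background sites annotated with
#'   \code{gene_id}, \code{feature}, \code{rel_pos}
#' @export
matched_background <- function(sites, bundle, non_target_genes,
                               bins_per_feature = 10, seed = 1) {
  stopifnot(!is.null(sites$feature), !is.null(sites$rel_pos))
  set.seed(seed)
  feat <- bundle$features
  feat <- feat[feat$gene_id %in% non_target_genes]
  if (length(feat) == 0) stop("no non-target genes available")
  k <- bins_per_feature

  fl <- GenomicRanges::width(feat)
  # offsets t = 0..flen-1 (5'->3'); bin(t) = floor(t/flen * k)
  bin_width <- function(flen, b) {
    lo <- ceiling(b * flen / k)
    hi <- ceiling((b + 1) * flen / k) - 1
    as.integer(max(0, hi - lo + 1))
  }

  keep <- sites$feature %in% FEATURE_LEVELS
  anchors <- sites[keep]
  abin <- genebody_bin(anchors$feature, anchors$rel_pos, k)
  out <- vector("list", length(anchors))

  for (stratum in sort(unique(abin))) {
    idx <- which(abin == stratum)
    f_name <- FEATURE_LEVELS[(stratum - 1) %/% k + 1]
    b <- (stratum - 1) %% k
    cand <- which(feat$feature == f_name)
    if (length(cand) == 0) {
      stop("no non-target positions available for stratum ",
           f_name, " bin ", b + 1)
    }
    w <- vapply(fl[cand], bin_width, integer(1), b = b)
    cand <- cand[w > 0]
    w <- w[w > 0]
    if (length(cand) == 0) {
      stop("no non-target positions available for stratum ",
           f_name, " bin ", b + 1)
    }
    pick <- if (length(cand) == 1) rep(cand, length(idx)) else {
      sample(cand, length(idx), replace = TRUE, prob = w)
    }
    flen <- fl[pick]
    lo <- ceiling(b * flen / k)
    hi <- ceiling((b + 1) * flen / k) - 1
    t <- lo + floor(stats::runif(length(idx)) * (hi - lo + 1))
    minus <- as.character(GenomicRanges::strand(feat))[pick] == "-"
    pos <- ifelse(minus, GenomicRanges::end(feat)[pick] - t,
                  GenomicRanges::start(feat)[pick] + t)
    for (j in seq_along(idx)) {
      out[[idx[j]]] <- data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(feat))[pick[j]],
        pos = pos[j],
        strand = as.character(GenomicRanges::strand(feat))[pick[j]],
        gene_id = feat$gene_id[pick[j]],
        feature = f_name,
        rel_pos = t[j] / flen[j],
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, width = 1),
                               strand = df$strand, gene_id = df$gene_id,
                               feature = df$feature, rel_pos = df$rel_pos)
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(bundle$features)
  GenomeInfoDb::seqlengths(gr) <-
    GenomeInfoDb::seqlengths(bundle$features)
  gr
}

#' Motif distance profile around anchor sites
#'
#' For each signed, strand-oriented offset d (negative = 5' on the
#' anchor's transcript strand), counts the anchors whose position shifted
#' by d overlaps any motif match (at any point within the match),
#' normalised per 1000 eligible anchors. An anchor is eligible at d only
#' while the shifted position still overlaps an annotated gene. The same
#' profile is computed for the matched background.
#'
#' @param matches GRanges of matches for one motif
#' @param anchors width-1 GRanges with strand
#' @param background matched background GRanges (optional)
#' @param bundle a GenomeBundle (for gene-overlap eligibility)
#' @param half_window maximum |offset| (default 50)
#' @return data.frame: offset, anchors (count per 1000), background
#'   (NA if no background given)
#' @export
motif_distance_profile <- function(matches, anchors, background = NULL,
                                   bundle, half_window = 50) {
  if (length(anchors) == 0) stop("empty anchor set")
  genes_gr <- GenomicRanges::reduce(
    GenomicRanges::GRanges(bundle$genes$chrom,
                           IRanges::IRanges(bundle$genes$start,
                                            bundle$genes$end)),
    ignore.strand = TRUE)

  profile_one <- function(sites) {
    minus <- as.character(GenomicRanges::strand(sites)) == "-"
    sign <- ifelse(minus, -1L, 1L)
    offs <- seq(-half_window, half_window)
    vapply(offs, function(d) {
      sh <- GenomicRanges::shift(sites, sign * d)
      ok <- GenomicRanges::start(sh) >= 1
      sl <- GenomeInfoDb::seqlengths(sh)[
        as.character(GenomeInfoDb::seqnames(sh))]
      ok <- ok & (is.na(sl) | GenomicRanges::start(sh) <= sl)
      sh <- sh[ok]
      elig <- IRanges::overlapsAny(sh, genes_gr, ignore.strand = TRUE)
      if (sum(elig) == 0) return(NA_real_)
      hit <- IRanges::overlapsAny(sh[elig], matches, ignore.strand = FALSE)
      1000 * sum(hit) / sum(elig)
    }, numeric(1))
  }
  data.frame(
    offset = seq(-half_window, half_window),
    anchors = profile_one(anchors),
    background = if (is.null(background)) NA_real_ else
      profile_one(background)
  )
}

#' Gene-body observed/expected enrichment of motif matches
#'
#' The observed distribution of match midpoints over gene-body bins is
#' normalised by the distribution of a large seeded random-position
#' background drawn from the transcript annotation. An enrichment of 1
#' means the motif is neither over- nor under-represented at that
#' location.
#'
#' @param matches GRanges of motif matches
#' @param bundle a GenomeBundle
#' @param n_background number of background positions (default 1e6; must
#'   be at least 100x the number of bins)
#' @param bins_per_feature bins per feature (default 10)
#' @param seed RNG seed
#' @return data.frame: feature, bin, observed, expected, oe
#' @export
genebody_enrichment <- function(matches, bundle, n_background = 1e6,
                                bins_per_feature = 10, seed = 1) {
  if (nrow(bundle$genes) == 0) stop("empty annotation")
  nb <- 3 * bins_per_feature
  if (n_background < 100 * nb) {
    stop("n_background must be at least 100x the number of bins")
  }
  mid <- GenomicRanges::resize(matches, width = 1, fix = "center")
  metagene_profile(mid, bundle, bins_per_feature,
                   n_background = n_background, seed = seed)
}

#' Distance profiles stratified by target status and crosslink proximity
#'
#' Anchors are split three ways: on non-target genes; on target genes with
#' a crosslink site within \code{near_dist} nt ("near"); on target genes
#' without ("far"). A distance profile is computed per stratum. Empty
#' strata are omitted with a message.
#'
#' @param anchors width-1 GRanges annotated with \code{gene_id}
#' @param target_genes character vector of target gene ids
#' @param crosslinks width-1 GRanges of crosslink sites
#' @param matches GRanges of matches for one motif
#' @param bundle a GenomeBundle
#' @param background optional matched background GRanges (used for every
#'   stratum's background curve)
#' @param near_dist nearness threshold in nt (default 25)
#' @param half_window profile half-window (default 50)
#' @return named list of profiles (\code{non_target}, \code{target_near},
#'   \code{target_far})
#' @export
split_anchor_profiles <- function(anchors, target_genes, crosslinks,
                                  matches, bundle, background = NULL,
                                  near_dist = 25, half_window = 50) {
  stopifnot(!is.null(anchors$gene_id))
  on_target <- anchors$gene_id %in% target_genes
  near <- rep(FALSE, length(anchors))
  if (length(crosslinks) > 0) {
    near <- pos_nearest_dist(anchors, crosslinks) <= near_dist
  }
  strata <- list(non_target = !on_target,
                 target_near = on_target & near,
                 target_far = on_target & !near)
  out <- list()
  for (nm in names(strata)) {
    sel <- strata[[nm]]
    if (sum(sel) == 0) {
      message("stratum ", nm, " is empty; profile omitted")
      next
    }
    out[[nm]] <- motif_distance_profile(matches, anchors[sel], background,
                                        bundle, half_window)
  }
  out
}
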