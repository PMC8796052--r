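# Cross-method target comparison: subset overlap tables over a common
# expressed-gene universe, equal-frequency expression binning of
# log2(TPM+1), per-bin target proportions, and support splits.

#' Overlap counts for all subset combinations of target sets
#'
#' For k sets over a universe, counts genes in every of the 2^k - 1
#' membership patterns (exclusive regions) plus the complement (in no
#' set).
#'
#' @param sets named list of character vectors (gene ids), each a subset
#'   of \code{universe}
#' @param universe character vector of all genes considered
#' @return data.frame: one row per membership pattern, with logical
#'   columns per set, \code{count}, and a \code{pattern} label
#' @export
overlap_table <- function(sets, universe) {
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  for (nm in names(sets)) {
    out <- setdiff(sets[[nm]], universe)
    if (length(out) > 0) {
      stop("gene(s) outside the universe in set ", nm, ": ",
           paste(utils::head(out, 5), collapse = ", "))
    }
    if (anyDuplicated(sets[[nm]])) {
      stop("duplicate gene ids in set ", nm)
    }
  }
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  pat <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  names(combos) <- names(sets)
  key <- apply(combos, 1, function(r) paste(as.integer(r), collapse = ""))
  counts <- as.integer(table(factor(pat, levels = key)))
  out <- cbind(combos, count = counts)
  out$pattern <- apply(combos, 1, function(r) {
    inn <- names(sets)[as.logical(r)]
    if (length(inn) == 0) "none" else paste(inn, collapse = "&")
  })
  out
}

#' Equal-frequency expression bins of log2(TPM+1)
#'
#' Expressed genes (TPM > 0) are ranked by log2(TPM+1) and split into
#' \code{n_bins} bins of (near-)equal size in increasing expression; ties
#' break by stable gene-id order. Degenerate input (all TPMs equal) is an
#' error.
#'
#' @param tpm named numeric vector of TPM values (names are gene ids)
#' @param n_bins number of bins (default 9)
#' @return named integer vector: bin (1 = lowest expression) per
#'   expressed gene
#' @export
expression_bins <- function(tpm, n_bins = 9) {
  if (length(tpm) == 0) stop("empty expression table")
  stopifnot(!is.null(names(tpm)), all(tpm >= 0))
  expressed <- tpm[tpm > 0]
  if (length(expressed) < n_bins) {
    stop("fewer expressed genes than bins")
  }
  if (length(unique(expressed)) == 1) {
    stop("degenerate expression values: all equal, cuts undefined")
  }
  lg <- log2(expressed + 1)
  ord <- order(lg, names(expressed))
  n <- length(expressed)
  bin_of_rank <- ceiling(seq_len(n) / n * n_bins)
  bins <- integer(n)
  bins[ord] <- bin_of_rank
  names(bins) <- names(expressed)
  bins
}

#' Per-bin target proportion
#'
#' The fraction of each expression bin's genes that belong to the target
#' set.
#'
#' @param set character vector of target gene ids
#' @param bins named integer vector from \code{\link{expression_bins}}
#' @return data.frame: bin, n_genes, n_targets, proportion
#' @export
per_bin_target_proportion <- function(set, bins) {
  levs <- sort(unique(bins))
  out <- do.call(rbind, lapply(levs, function(b) {
    g <- names(bins)[bins == b]
    if (length(g) == 0) stop("empty expression bin ", b)
    data.frame(bin = b, n_genes = length(g),
               n_targets = sum(g %in% set),
               proportion = mean(g %in% set))
  }))
  rownames(out) <- NULL
  out
}

#' Split a target set by support from other sets, with per-bin
#' distributions
#'
#' Partitions the set by membership in the union of the support sets and
#' returns each part's distribution over expression bins.
#'
#' @param set character vector of target gene ids
#' @param support_sets list of character vectors (support evidence)
#' @param bins named integer vector from \code{\link{expression_bins}}
#' @return list: \code{with_support}, \code{without_support} (gene ids)
#'   and \code{per_bin} (data.frame: bin, n_with, n_without, plus each
#'   part's share of its total)
#' @export
support_split <- function(set, support_sets, bins) {
  support <- unique(unlist(support_sets))
  with_s <- intersect(set, support)
  without_s <- setdiff(set, support)
  levs <- sort(unique(bins))
  per_bin <- do.call(rbind, lapply(levs, function(b) {
    g <- names(bins)[bins == b]
    data.frame(bin = b,
               n_with = sum(g %in% with_s),
               n_without = sum(g %in% without_s))
  }))
  per_bin$share_with <- if (length(with_s) > 0) {
    per_bin$n_with / length(with_s)
  } else 0
  per_bin$share_without <- if (length(without_s) > 0) {
    per_bin$n_without / length(without_s)
  } else 0
  rownames(per_bin) <- NULL
  list(with_support = with_s, without_support = without_s,
       per_bin = per_bin)
}
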