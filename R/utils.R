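# Shared low-level helpers: IUPAC expansion, beta-binomial draws and
# likelihoods, small numeric utilities. RNA motifs are handled with DNA
# alphabet internally (U <-> T) and reported with U where user-facing.

IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

BASES <- c("A", "C", "G", "T")

#' Expand an IUPAC pattern into per-position allowed bases
#'
#' @param iupac a single IUPAC string (U is treated as T).
#' @return list of character vectors, one per position.
#' @keywords internal
iupac_allowed <- function(iupac) {
  chars <- strsplit(toupper(iupac), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_MAP))
  if (length(bad) > 0) {
    stop("unknown IUPAC code(s): ", paste(bad, collapse = ", "))
  }
  lapply(chars, function(ch) IUPAC_MAP[[ch]])
}

#' Draw one concrete instance of an IUPAC pattern
#' @keywords internal
iupac_instance <- function(iupac) {
  allowed <- iupac_allowed(iupac)
  paste(vapply(allowed, function(b) {
    if (length(b) == 1L) b else sample(b, 1L)
  }, character(1)), collapse = "")
}

#' Convert a base string to integer codes (A=1, C=2, G=3, T=4; other = NA)
#' @keywords internal
base_codes <- function(seq_chars) {
  match(seq_chars, BASES)
}

#' Beta-binomial random draws
#'
#' Parameterised by mean probability `prob` and overdispersion `rho`
#' (intra-class correlation); `rho = 0` degenerates to the binomial.
#'
#' @param n number of draws
#' @param size integer vector of trial counts
#' @param prob mean success probability
#' @param rho overdispersion in [0, 1)
#' @return integer vector of successes
#' @keywords internal
rbetabinom <- function(n, size, prob, rho = 0) {
  stopifnot(rho >= 0, rho < 1, prob >= 0, prob <= 1)
  size <- rep_len(size, n)
  if (rho == 0 || prob == 0 || prob == 1) {
    return(stats::rbinom(n, size, prob))
  }
  ab <- (1 - rho) / rho
  p <- stats::rbeta(n, prob * ab, (1 - prob) * ab)
  stats::rbinom(n, size, p)
}

#' Beta-binomial log-likelihood with mean/overdispersion parameterisation
#'
#' @param x successes, @param size trials (vectors), @param prob mean,
#' @param rho overdispersion. Vectorised over x/size.
#' @return total log-likelihood
#' @keywords internal
dbetabinom_loglik <- function(x, size, prob, rho) {
  if (prob <= 0) {
    return(if (all(x == 0)) 0 else -Inf)
  }
  if (prob >= 1) {
    return(if (all(x == size)) 0 else -Inf)
  }
  if (rho <= 0) {
    return(sum(stats::dbinom(x, size, prob, log = TRUE)))
  }
  ab <- (1 - rho) / rho
  a <- prob * ab
  b <- (1 - prob) * ab
  sum(lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b))
}

#' Maximise the beta-binomial likelihood over the mean for fixed rho
#' @keywords internal
fit_bb_prob <- function(x, size, rho) {
  keep <- size > 0
  x <- x[keep]
  size <- size[keep]
  if (length(x) == 0) {
    return(list(prob = 0, loglik = 0))
  }
  if (all(x == 0)) {
    return(list(prob = 0, loglik = 0))
  }
  if (all(x == size)) {
    return(list(prob = 1, loglik = 0))
  }
  opt <- stats::optimize(
    function(p) -dbetabinom_loglik(x, size, p, rho),
    interval = c(1e-9, 1 - 1e-9), tol = 1e-7
  )
  list(prob = opt$minimum, loglik = -opt$objective)
}

#' Positional distance to the nearest reference site
#'
#' |pos_query - pos_reference| minimised over the reference, computed per
#' chromosome (and per strand unless \code{ignore_strand}). Queries with
#' no eligible reference get Inf. Note this is the difference of
#' single-nucleotide positions, not the inter-range gap.
#'
#' @param query,reference width-1 GRanges
#' @param ignore_strand match across strands (default TRUE)
#' @return numeric vector of distances, one per query
#' @keywords internal
pos_nearest_dist <- function(query, reference, ignore_strand = TRUE) {
  qk <- as.character(GenomeInfoDb::seqnames(query))
  rk <- as.character(GenomeInfoDb::seqnames(reference))
  if (!ignore_strand) {
    qk <- paste0(qk, GenomicRanges::strand(query))
    rk <- paste0(rk, GenomicRanges::strand(reference))
  }
  qp <- GenomicRanges::start(query)
  rp <- GenomicRanges::start(reference)
  out <- rep(Inf, length(query))
  for (k in unique(qk)) {
    ref <- sort(rp[rk == k])
    if (length(ref) == 0) next
    qi <- which(qk == k)
    pos <- qp[qi]
    i <- findInterval(pos, ref)
    d_lo <- ifelse(i >= 1, pos - ref[pmax(i, 1)], Inf)
    d_hi <- ifelse(i < length(ref), ref[pmin(i + 1, length(ref))] - pos,
                   Inf)
    out[qi] <- pmin(d_lo, d_hi)
  }
  out
}

# editing-rate grid for profile-likelihood maximisation (log-spaced:
# editing proportions concentrate near 0)
P_GRID <- exp(seq(log(1e-5), log(0.9999), length.out = 80))

#' Grid-profile beta-binomial log-likelihood maximum over the mean
#'
#' Binomial-coefficient terms are omitted (they cancel in likelihood
#' ratios on the same data).
#' @keywords internal
bb_ll_grid_max <- function(x, n, rho) {
  keep <- n > 0
  x <- x[keep]
  n <- n[keep]
  if (length(x) == 0) return(0)
  if (rho <= 0) {
    ph <- min(max(sum(x) / sum(n), 1e-12), 1 - 1e-12)
    return(sum(stats::dbinom(x, n, ph, log = TRUE)))
  }
  ab <- (1 - rho) / rho
  best <- -Inf
  for (p in P_GRID) {
    a <- p * ab
    b <- (1 - p) * ab
    ll <- sum(lbeta(x + a, n - x + b) - lbeta(a, b))
    if (ll > best) best <- ll
  }
  best
}

# signed LRT statistic: pooled vs per-condition beta-binomial editing rate;
# positive sign when the fusion rate is at least the control rate
bb_lrt_stat <- function(x, n, is_f, rho) {
  ll0 <- bb_ll_grid_max(x, n, rho)
  ll1 <- bb_ll_grid_max(x[is_f], n[is_f], rho) +
    bb_ll_grid_max(x[!is_f], n[!is_f], rho)
  epf <- sum(x[is_f]) / max(1, sum(n[is_f]))
  epc <- sum(x[!is_f]) / max(1, sum(n[!is_f]))
  s <- max(0, 2 * (ll1 - ll0))
  if (epf >= epc) s else -s
}

# B signed LRT statistics simulated under the fitted per-site null
# (pooled rate p0, shared rho); fully vectorised over replicates
bb_boot_stats <- function(n, is_f, p0, rho, B) {
  ns <- length(n)
  xb <- matrix(rbetabinom(B * ns, rep(n, each = B), p0, rho), B, ns)
  nb <- matrix(rep(n, each = B), B, ns)
  clamp <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  if (rho <= 0) {
    m0 <- rowSums(stats::dbinom(xb, nb, clamp(rowSums(xb) / sum(n)),
                                log = TRUE))
    mf <- rowSums(stats::dbinom(
      xb[, is_f, drop = FALSE], nb[, is_f, drop = FALSE],
      clamp(rowSums(xb[, is_f, drop = FALSE]) / sum(n[is_f])), log = TRUE))
    mc <- rowSums(stats::dbinom(
      xb[, !is_f, drop = FALSE], nb[, !is_f, drop = FALSE],
      clamp(rowSums(xb[, !is_f, drop = FALSE]) / sum(n[!is_f])),
      log = TRUE))
  } else {
    ab <- (1 - rho) / rho
    m0 <- rep(-Inf, B)
    mf <- rep(-Inf, B)
    mc <- rep(-Inf, B)
    for (p in P_GRID) {
      a <- p * ab
      b <- (1 - p) * ab
      lmat <- lbeta(xb + a, nb - xb + b) - lbeta(a, b)
      m0 <- pmax(m0, rowSums(lmat))
      mf <- pmax(mf, rowSums(lmat[, is_f, drop = FALSE]))
      mc <- pmax(mc, rowSums(lmat[, !is_f, drop = FALSE]))
    }
  }
  st <- pmax(0, 2 * (mf + mc - m0))
  epf <- rowSums(xb[, is_f, drop = FALSE]) / sum(n[is_f])
  epc <- rowSums(xb[, !is_f, drop = FALSE]) / sum(n[!is_f])
  ifelse(epf >= epc, st, -st)
}

#' Method-of-moments overdispersion estimate for grouped binomial data
#'
#' Standard one-way ANOVA-type estimator on per-sample proportions,
#' weighted by trial counts; clamped to [0, 0.95].
#' @keywords internal
estimate_rho_mom <- function(x, size) {
  keep <- size > 0
  x <- x[keep]
  size <- size[keep]
  k <- length(x)
  if (k < 2) {
    return(0)
  }
  n_tot <- sum(size)
  p_hat <- sum(x) / n_tot
  if (p_hat <= 0 || p_hat >= 1) {
    return(0)
  }
  # Pearson chi-square over samples relative to pooled proportion
  s2 <- sum((x - size * p_hat)^2 / (size * p_hat * (1 - p_hat)))
  nbar <- n_tot / k
  denom <- (k - 1) * (nbar - 1)
  if (denom <= 0) {
    return(0)
  }
  rho <- (s2 / (k - 1) - 1) / (nbar - 1)
  min(max(rho, 0), 0.95)
}

#' Reverse complement of a plain character string
#' @keywords internal
revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# print T as U for user-facing motif output
to_rna <- function(s) gsub("T", "U", toupper(s))
to_dna <- function(s) gsub("U", "T", toupper(s))
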