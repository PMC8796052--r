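# Motif-window feature matrices around anchor sites and gradient-boosted
# classification: m6A vs matched background, and reader-bound vs unbound
# m6A sites. Windows are 'at' [-10,+10], 'up' [-60,-11] (5', negative
# offsets on the transcript strand) and 'down' [+11,+60]; features are
# per-motif match counts truncated at 10, standardised on training rows
# only.

WINDOW_DEFS <- list(at = c(-10L, 10L), up = c(-60L, -11L),
                    down = c(11L, 60L))

#' Remove redundant anchors within a window
#'
#' Greedy reduction: repeatedly keep the highest-scoring site and drop all
#' others within \code{window} nt of it (same chromosome; strand ignored).
#' Sites without scores are treated as equal and reduced left to right.
#'
#' @param sites width-1 GRanges (optional \code{score})
#' @param window exclusion radius in nt (default 120)
#' @return the reduced GRanges
#' @export
reduce_redundant <- function(sites, window = 120) {
  if (length(sites) <= 1) return(sites)
  sc <- if (is.null(sites$score)) rep(0, length(sites)) else sites$score
  expanded <- GenomicRanges::resize(GenomicRanges::granges(sites),
                                    width = 2 * window + 1, fix = "center")
  hits <- GenomicRanges::findOverlaps(expanded, sites, ignore.strand = TRUE)
  nb <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  ord <- order(-sc, as.character(GenomeInfoDb::seqnames(sites)),
               GenomicRanges::start(sites))
  dropped <- logical(length(sites))
  keep <- logical(length(sites))
  for (i in ord) {
    if (dropped[i]) next
    keep[i] <- TRUE
    dropped[nb[[as.character(i)]]] <- TRUE
  }
  sites[keep]
}

window_ranges <- function(anchors, win) {
  minus <- as.character(GenomicRanges::strand(anchors)) == "-"
  p <- GenomicRanges::start(anchors)
  lo <- ifelse(minus, p - win[2], p + win[1])
  hi <- ifelse(minus, p - win[1], p + win[2])
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(anchors),
                         IRanges::IRanges(lo, hi),
                         strand = GenomicRanges::strand(anchors))
}

#' Build a motif-window feature matrix
#'
#' Rows are anchor sites (label 1) and negatives (label 0); columns are
#' motif x window (\code{at}, \code{up}, \code{down}). A motif match is
#' counted in a window if it overlaps it at any point; counts are
#' truncated at \code{truncate}. One fifth of the rows (stratified by
#' label) form the held-out split; per-feature standardisation is fitted
#' on training rows only. Anchors are first reduced for redundancy (the
#' matched negatives are paired 1:1 and left as given) and rows whose
#' windows cross a contig edge are dropped with a message.
#'
#' @param anchors width-1 GRanges of positive sites
#' @param negatives width-1 GRanges of negative sites
#' @param catalogue data.frame from \code{\link{motif_catalogue}}
#' @param matches GRanges of catalogue matches (with \code{motif})
#' @param truncate count cap (default 10)
#' @param held_out_fraction fraction of rows held out (default 1/5)
#' @param seed RNG seed for the split
#' @param dedupe reduce redundant anchors first (default TRUE)
#' @return a \code{FeatureMatrix}: list with \code{counts} (raw),
#'   \code{x} (normalised), \code{label}, \code{split}, \code{center},
#'   \code{scale}
#' @export
build_features <- function(anchors, negatives, catalogue, matches,
                           truncate = 10, held_out_fraction = 1 / 5,
                           seed = 1, dedupe = TRUE) {
  if (dedupe) {
    anchors <- reduce_redundant(anchors)
  }
  sites <- c(GenomicRanges::granges(anchors),
             GenomicRanges::granges(negatives))
  label <- c(rep(1L, length(anchors)), rep(0L, length(negatives)))

  # drop rows whose 120-nt window crosses a contig edge
  lens <- GenomeInfoDb::seqlengths(sites)[
    as.character(GenomeInfoDb::seqnames(sites))]
  p <- GenomicRanges::start(sites)
  ok <- p - 60 >= 1 & (is.na(lens) | p + 60 <= lens)
  if (any(!ok)) {
    message(sum(!ok), " site(s) too close to a contig edge; rows dropped")
    sites <- sites[ok]
    label <- label[ok]
  }

  motifs <- catalogue$name
  n <- length(sites)
  counts <- matrix(0L, n, 3 * length(motifs))
  colnames(counts) <- as.vector(outer(motifs, names(WINDOW_DEFS),
                                      paste, sep = "_"))
  for (w in names(WINDOW_DEFS)) {
    wr <- window_ranges(sites, WINDOW_DEFS[[w]])
    for (m in motifs) {
      mm <- matches[matches$motif == m]
      cnt <- GenomicRanges::countOverlaps(wr, mm, ignore.strand = FALSE)
      counts[, paste0(m, "_", w)] <- pmin(as.integer(cnt), truncate)
    }
  }

  set.seed(seed)
  split <- rep("train", n)
  for (lab in unique(label)) {
    idx <- which(label == lab)
    n_h <- round(length(idx) * held_out_fraction)
    split[sample(idx, n_h)] <- "held_out"
  }

  tr <- split == "train"
  ctr <- colMeans(counts[tr, , drop = FALSE])
  scl <- apply(counts[tr, , drop = FALSE], 2, stats::sd)
  scl[scl == 0] <- 1
  x <- sweep(sweep(counts, 2, ctr), 2, scl, "/")

  structure(list(counts = counts, x = x, label = label, split = split,
                 center = ctr, scale = scl, sites = sites),
            class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat("FeatureMatrix:", nrow(x$x), "sites x", ncol(x$x), "features (",
      sum(x$label == 1), "positive /", sum(x$label == 0), "negative;",
      sum(x$split == "held_out"), "held out )\n")
  invisible(x)
}

#' Train a gradient-boosted tree classifier on a feature matrix
#'
#' Gradient boosting with learning rate (shrinkage) 0.05, maximum
#' interaction depth 6 and up to 2000 trees; the tree count is selected by
#' 5-fold cross-validated AUC on the training rows. Per-feature
#' importances (total gain) are normalised to sum 100.
#'
#' @param fm a \code{FeatureMatrix}
#' @param shrinkage learning rate (default 0.05)
#' @param depth maximum tree depth (default 6)
#' @param n_trees maximum number of trees (default 2000)
#' @param cv_folds cross-validation folds (default 5)
#' @param seed RNG seed (fold assignment; training is single-threaded and
#'   deterministic)
#' @param features optional character vector restricting the model to
#'   these feature columns
#' @return a \code{GbmFit}: list with \code{model}, \code{importance}
#'   (data.frame feature/importance summing to 100), \code{best_trees},
#'   \code{cv_curve}, \code{features}
#' @export
train_gbm <- function(fm, shrinkage = 0.05, depth = 6, n_trees = 2000,
                      cv_folds = 5, seed = 1, features = NULL) {
  tr <- fm$split == "train"
  y <- fm$label[tr]
  if (length(unique(y)) < 2) stop("training rows contain a single class")
  x <- fm$x[tr, , drop = FALSE]
  if (!is.null(features)) {
    stopifnot(all(features %in% colnames(x)))
    x <- x[, features, drop = FALSE]
  }
  set.seed(seed)
  params <- list(objective = "binary:logistic", eta = shrinkage,
                 max_depth = depth, nthread = 1,
                 eval_metric = "auc")
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  cv <- xgboost::xgb.cv(params = params, data = dtrain,
                        nrounds = n_trees, nfold = cv_folds,
                        early_stopping_rounds = 50, maximize = TRUE,
                        verbose = 0)
  best <- cv$early_stop$best_iteration
  model <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = best, verbose = 0)
  imp <- data.frame(feature = colnames(x), importance = 0)
  imp_raw <- if (ncol(x) == 1) {
    data.frame(Feature = colnames(x), Gain = 1)
  } else {
    xgboost::xgb.importance(model = model)
  }
  m <- match(imp_raw$Feature, imp$feature)
  imp$importance[m] <- imp_raw$Gain
  imp$importance <- 100 * imp$importance / sum(imp$importance)
  imp <- imp[order(-imp$importance), ]
  rownames(imp) <- NULL
  structure(list(model = model, importance = imp, best_trees = best,
                 cv_curve = cv$evaluation_log, features = colnames(x)),
            class = "GbmFit")
}

#' Predict class probabilities from a fitted model
#'
#' @param fit a \code{GbmFit}
#' @param fm a \code{FeatureMatrix}
#' @param rows which rows to score ("held_out", "train" or "all")
#' @return list with \code{scores} and \code{labels}
#' @export
predict_gbm <- function(fit, fm, rows = "held_out") {
  sel <- switch(rows,
                held_out = fm$split == "held_out",
                train = fm$split == "train",
                all = rep(TRUE, length(fm$split)))
  x <- fm$x[sel, fit$features, drop = FALSE]
  dx <- xgboost::xgb.DMatrix(x, nthread = 1)
  list(scores = stats::predict(fit$model, dx), labels = fm$label[sel])
}

#' Area under the ROC curve by the rank (Mann-Whitney) statistic
#'
#' @param scores numeric classifier scores
#' @param labels 0/1 labels (both classes present)
#' @return list with \code{auc} and a \code{roc} data.frame (threshold,
#'   fpr, tpr)
#' @export
auc_rank <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("need both classes to compute AUC")
  r <- rank(scores)  # ties get average ranks
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(-scores)
  tp <- cumsum(labels[ord] == 1)
  fp <- cumsum(labels[ord] == 0)
  keep <- !duplicated(scores[ord], fromLast = TRUE)
  roc <- data.frame(threshold = scores[ord][keep],
                    fpr = fp[keep] / n0, tpr = tp[keep] / n1)
  roc <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), roc)
  list(auc = auc, roc = roc)
}

#' Evaluate a fitted model on the held-out rows
#'
#' @param fit a \code{GbmFit}
#' @param fm the \code{FeatureMatrix}
#' @return list with \code{auc} and \code{roc}
#' @export
evaluate_auc <- function(fit, fm) {
  pr <- predict_gbm(fit, fm, rows = "held_out")
  if (length(unique(pr$labels)) < 2) stop("held-out rows are single-class")
  auc_rank(pr$scores, pr$labels)
}

#' Refit on the top-k most important features
#'
#' @param fm the \code{FeatureMatrix}
#' @param fit the full-model \code{GbmFit}
#' @param k number of features to keep (default 10)
#' @param ... passed to \code{\link{train_gbm}}
#' @return list with \code{fit} (the reduced \code{GbmFit}) and \code{auc}
#'   on the same held-out rows
#' @export
reduced_model <- function(fm, fit, k = 10, ...) {
  if (k < 1) stop("k must be >= 1")
  k <- min(k, nrow(fit$importance))
  top <- fit$importance$feature[seq_len(k)]
  # keep the original column order so k = all features reproduces the
  # full fit exactly
  top <- intersect(colnames(fm$x), top)
  rfit <- train_gbm(fm, features = top, ...)
  list(fit = rfit, auc = evaluate_auc(rfit, fm)$auc)
}

#' Label m6A sites by reader binding and build the contrast feature matrix
#'
#' Positives are m6A sites with a crosslink site within \code{near_dist}
#' nt; negatives are m6A sites with none.
#'
#' @param m6a_sites width-1 GRanges of m6A sites
#' @param crosslinks width-1 GRanges of crosslink sites
#' @param catalogue,matches as in \code{\link{build_features}}
#' @param near_dist binding distance threshold in nt (default 10)
#' @param ... passed to \code{\link{build_features}}
#' @return a \code{FeatureMatrix}
#' @export
contrast_bound_vs_unbound <- function(m6a_sites, crosslinks, catalogue,
                                      matches, near_dist = 10, ...) {
  near <- rep(FALSE, length(m6a_sites))
  if (length(crosslinks) > 0) {
    near <- pos_nearest_dist(m6a_sites, crosslinks) <= near_dist
  }
  if (sum(near) == 0 || sum(!near) == 0) {
    stop("both bound and unbound classes must be non-empty")
  }
  build_features(m6a_sites[near], m6a_sites[!near], catalogue, matches, ...)
}
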