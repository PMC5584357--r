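# ROC / AUC benchmarking of a similarity matrix against a gold standard.
#
# Predictions are thresholded on the similarity score (higher score =>
# predicted interaction). The ROC curve is traced at fixed score intervals
# (default width 0.1) sweeping the metric's range from the top down, and the
# area under the curve is the sum of trapezoid areas
# AUC = 1/2 * sum_i (X_i - X_{i-1}) (Y_i + Y_{i-1}),
# with X the false positive rate and Y the true positive rate. Ten-fold
# cross-validation partitions the labeled pairs uniformly at random into ten
# near-equal subsets and reports the AUC distribution over them.

#' Join similarity scores with gold-standard labels
#'
#' Pairs whose proteins are missing from the similarity matrix are dropped
#' and counted per class.
#'
#' @param sm A `similarity_matrix`.
#' @param gs A `gold_standard`.
#' @return A `scored_pairs` data frame (`id1`, `id2`, `score`, `label`) with
#'   attributes `metric`, `flavor`, `dropped` (named count vector).
#' @export
score_pairs <- function(sm, gs) {
  pairs <- rbind(
    cbind(gs$positives, label = "TP"),
    if (nrow(gs$negatives)) cbind(gs$negatives, label = "TN")
  )
  ids <- rownames(sm)
  present <- pairs$id1 %in% ids & pairs$id2 %in% ids
  dropped <- c(TP = sum(!present & pairs$label == "TP"),
               TN = sum(!present & pairs$label == "TN"))
  if (any(dropped > 0)) {
    message(sprintf(
      "score_pairs: dropped %d TP and %d TN pair(s) with proteins absent from the similarity matrix",
      dropped["TP"], dropped["TN"]
    ))
  }
  pairs <- pairs[present, , drop = FALSE]
  if (!nrow(pairs)) {
    stop("no gold-standard pair survives the join with the similarity matrix",
         call. = FALSE)
  }
  pairs$score <- sm[cbind(match(pairs$id1, ids), match(pairs$id2, ids))]
  if (any(!is.finite(pairs$score))) {
    stop("non-finite similarity score in gold-standard pairs", call. = FALSE)
  }
  rownames(pairs) <- NULL
  structure(pairs[, c("id1", "id2", "score", "label")],
            class = c("scored_pairs", "data.frame"),
            metric = attr(sm, "metric"), flavor = gs$flavor,
            dropped = dropped)
}

# (FPR, TPR) sweep over descending thresholds; prediction is score >= t
.roc_points <- function(score, label, thresholds) {
  pos <- label == "TP"
  np <- sum(pos)
  nn <- sum(!pos)
  thresholds <- sort(unique(thresholds), decreasing = TRUE)
  tpr <- vapply(thresholds, function(t) sum(score >= t & pos) / np,
                numeric(1L))
  fpr <- vapply(thresholds, function(t) sum(score >= t & !pos) / nn,
                numeric(1L))
  x <- c(0, fpr, 1)
  y <- c(0, tpr, 1)
  keep <- c(TRUE, diff(x) != 0 | diff(y) != 0)
  data.frame(fpr = x[keep], tpr = y[keep])
}

.metric_range <- function(metric, score, bin_width) {
  switch(metric,
    dcor = c(0, 1),
    pc = c(-1, 1),
    mi = c(0, max(bin_width, ceiling(max(score) / bin_width) * bin_width)),
    c(floor(min(score) / bin_width) * bin_width,
      max(bin_width, ceiling(max(score) / bin_width) * bin_width))
  )
}

#' Binned ROC curve of a scored pair set
#'
#' Thresholds descend over the metric's score range in `bin_width` steps
#' (range `[0, 1]` for distance correlation, `[-1, 1]` for Pearson, and
#' `[0, ceiling(max/width) * width]` for mutual information). The endpoints
#' `(0, 0)` and `(1, 1)` are always included; consecutive duplicate points
#' are collapsed.
#'
#' @param sp A `scored_pairs` set with at least one pair of each class.
#' @param bin_width Score interval width (default 0.1).
#' @param range Optional explicit score range `c(lo, hi)` overriding the
#'   metric default.
#' @param fold Optional fold identifier carried into the result.
#' @return A `roc_result`: list with `points` (data frame `fpr`, `tpr`),
#'   `auc`, `thresholds`, `metric`, `bin_width`, `fold`.
#' @export
binned_roc <- function(sp, bin_width = 0.1, range = NULL, fold = NA) {
  np <- sum(sp$label == "TP")
  nn <- sum(sp$label == "TN")
  if (np < 1L || nn < 1L) {
    stop("ROC needs at least one pair of each class", call. = FALSE)
  }
  metric <- attr(sp, "metric")
  if (is.null(range)) {
    range <- .metric_range(if (is.null(metric)) "" else metric,
                           sp$score, bin_width)
  }
  thresholds <- seq(range[2L], range[1L], by = -bin_width)
  pts <- .roc_points(sp$score, sp$label, thresholds)
  structure(list(points = pts, auc = auc_trapezoid(pts),
                 thresholds = thresholds, metric = metric,
                 bin_width = bin_width, fold = fold),
            class = "roc_result")
}

#' Exact (unbinned) ROC curve
#'
#' Thresholds at every distinct observed score, giving the step ROC whose
#' trapezoid area equals the Mann-Whitney rank statistic normalized by
#' `n_TP * n_TN`.
#'
#' @inheritParams binned_roc
#' @return A `roc_result`.
#' @export
exact_roc <- function(sp, fold = NA) {
  np <- sum(sp$label == "TP")
  nn <- sum(sp$label == "TN")
  if (np < 1L || nn < 1L) {
    stop("ROC needs at least one pair of each class", call. = FALSE)
  }
  thresholds <- sort(unique(sp$score), decreasing = TRUE)
  pts <- .roc_points(sp$score, sp$label, thresholds)
  structure(list(points = pts, auc = auc_trapezoid(pts),
                 thresholds = thresholds, metric = attr(sp, "metric"),
                 bin_width = NA_real_, fold = fold),
            class = "roc_result")
}

#' Trapezoid area under a ROC curve
#'
#' `AUC = 1/2 * sum_i (X_i - X_{i-1}) (Y_i + Y_{i-1})` over the ordered
#' curve points.
#'
#' @param roc A `roc_result`, or a data frame of ordered points with columns
#'   `fpr` and `tpr`.
#' @return The area, in `[0, 1]`.
#' @export
auc_trapezoid <- function(roc) {
  pts <- if (inherits(roc, "roc_result")) roc$points else roc
  x <- pts$fpr
  y <- pts$tpr
  if (is.unsorted(x)) {
    stop("ROC points are not ordered by false positive rate", call. = FALSE)
  }
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n])) / 2
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC (%s%s): %d points, AUC = %.4f\n",
              if (is.null(x$metric)) "scores" else x$metric,
              if (is.na(x$bin_width)) ", exact"
              else sprintf(", bin width %.2g", x$bin_width),
              nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "b", pch = 16,
       xlab = "False positive rate", ylab = "True positive rate",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Ten-fold cross-validated AUC
#'
#' Partitions the scored pairs uniformly at random into `k` subsets of
#' near-equal size and computes the binned AUC on each. If any fold ends up
#' single-class the partition is redrawn (up to `max_retries`); if that
#' fails, a stratified partition is used and flagged in the report. All
#' randomness flows from `seed`.
#'
#' @inheritParams binned_roc
#' @param k Number of folds (default 10).
#' @param seed Integer seed (required).
#' @param max_retries Redraws allowed before the stratified fallback.
#' @return A `cv_report`: list with `fold_auc`, `folds` (fold assignment per
#'   pair), `summary` (mean, quartiles), `seed`, `metric`, `flavor`,
#'   `stratified`, `k`, `bin_width`, `pair_key`.
#' @export
ten_fold_cv <- function(sp, k = 10L, seed, bin_width = 0.1, range = NULL,
                        max_retries = 20L) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  n <- nrow(sp)
  np <- sum(sp$label == "TP")
  nn <- sum(sp$label == "TN")
  if (np < k || nn < k) {
    stop(sprintf(
      "cross-validation needs at least k = %d pairs of each class (have %d TP, %d TN)",
      k, np, nn
    ), call. = FALSE)
  }
  set.seed(seed)
  stratified <- FALSE
  fold <- NULL
  for (try in seq_len(max_retries)) {
    cand <- sample(rep_len(seq_len(k), n))
    ok <- all(vapply(seq_len(k), function(f) {
      any(sp$label[cand == f] == "TP") && any(sp$label[cand == f] == "TN")
    }, logical(1L)))
    if (ok) {
      fold <- cand
      break
    }
  }
  if (is.null(fold)) {
    # stratified fallback: partition each class separately
    fold <- integer(n)
    tp <- which(sp$label == "TP")
    tn <- which(sp$label == "TN")
    fold[tp] <- sample(rep_len(seq_len(k), length(tp)))
    fold[tn] <- sample(rep_len(seq_len(k), length(tn)))
    stratified <- TRUE
  }
  fold_auc <- vapply(seq_len(k), function(f) {
    sub <- sp[fold == f, , drop = FALSE]
    attr(sub, "metric") <- attr(sp, "metric")
    binned_roc(sub, bin_width = bin_width, range = range, fold = f)$auc
  }, numeric(1L))
  qs <- stats::quantile(fold_auc, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(
    fold_auc = fold_auc, folds = fold,
    summary = c(mean = mean(fold_auc), q1 = qs[1L], median = qs[2L],
                q3 = qs[3L]),
    seed = seed, metric = attr(sp, "metric"), flavor = attr(sp, "flavor"),
    stratified = stratified, k = k, bin_width = bin_width,
    pair_key = paste(sp$id1, sp$id2, sep = "\r")
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV (%s%s, seed %d%s): median AUC = %.4f, mean = %.4f [Q1 %.4f, Q3 %.4f]\n",
    x$k, if (is.null(x$metric)) "scores" else x$metric,
    if (is.null(x$flavor)) "" else paste0(", ", x$flavor),
    x$seed, if (x$stratified) ", stratified fallback" else "",
    x$summary["median"], x$summary["mean"], x$summary["q1"], x$summary["q3"]
  ))
  invisible(x)
}

#' Compare cross-validated metrics on identical folds
#'
#' Requires two or more [ten_fold_cv()] reports computed on the same pairs
#' with the same fold assignment (use the same seed on scored-pair sets that
#' share the gold standard). Reports the per-fold AUCs side by side, all
#' pairwise paired differences, and five-number box-plot summaries.
#'
#' @param reports List of `cv_report` objects (named by metric if the
#'   reports lack metric tags).
#' @return A `metric_comparison`: list with `fold_auc` matrix (fold x
#'   metric), `differences`, `boxstats`, `k`, `flavor`.
#' @export
compare_metrics <- function(reports) {
  if (length(reports) < 2L) {
    stop("metric comparison needs at least two cross-validation reports",
         call. = FALSE)
  }
  nm <- names(reports)
  tags <- vapply(seq_along(reports), function(i) {
    tag <- reports[[i]]$metric
    if (is.null(tag) || !nzchar(tag)) tag <- if (!is.null(nm)) nm[i] else ""
    if (!nzchar(tag)) sprintf("metric%d", i) else tag
  }, character(1L))
  ref <- reports[[1L]]
  for (r in reports[-1L]) {
    if (r$k != ref$k || !identical(r$folds, ref$folds) ||
        !identical(r$pair_key, ref$pair_key)) {
      stop("cross-validation reports were not computed on identical folds",
           call. = FALSE)
    }
  }
  tab <- vapply(reports, `[[`, numeric(ref$k), "fold_auc")
  colnames(tab) <- tags
  cmb <- utils::combn(seq_along(tags), 2L)
  differences <- vapply(seq_len(ncol(cmb)), function(c) {
    tab[, cmb[1L, c]] - tab[, cmb[2L, c]]
  }, numeric(ref$k))
  differences <- matrix(differences, nrow = ref$k)
  colnames(differences) <- vapply(seq_len(ncol(cmb)), function(c) {
    paste(tags[cmb[1L, c]], tags[cmb[2L, c]], sep = " - ")
  }, character(1L))
  boxstats <- apply(tab, 2L, stats::fivenum)
  rownames(boxstats) <- c("min", "q1", "median", "q3", "max")
  structure(list(fold_auc = tab, differences = differences,
                 boxstats = boxstats, k = ref$k, flavor = ref$flavor),
            class = "metric_comparison")
}

#' @export
print.metric_comparison <- function(x, ...) {
  cat(sprintf("Metric comparison over %d folds%s\n", x$k,
              if (is.null(x$flavor)) "" else sprintf(" (%s)", x$flavor)))
  print(round(x$boxstats, 4))
  cat("Mean paired difference(s):\n")
  print(round(colMeans(x$differences), 4))
  invisible(x)
}

#' @export
plot.metric_comparison <- function(x, ...) {
  graphics::boxplot(x$fold_auc, ylab = "fold AUC", ...)
  invisible(x)
}

#' Write per-fold AUCs as TSV
#'
#' @param report A `cv_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_cv_tsv <- function(report, path) {
  utils::write.table(
    data.frame(fold = seq_len(report$k), auc = report$fold_auc,
               metric = report$metric, flavor = report$flavor,
               seed = report$seed, stratified = report$stratified),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
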