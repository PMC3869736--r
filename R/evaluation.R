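# Performance evaluation against benchmark HK and TS gene sets: confusion
# counts with the overlap-exclusion rule, accuracy/recall/precision/
# specificity in percent, ROC curves with a tie-aware AUC, and the
# cross-coverage analysis with a size-matched random control.

#' Confusion counts against benchmark gene sets
#'
#' Genes present in both truth sets are excluded before counting (the
#' overlap-exclusion rule). `TP` are HK-truth genes called HK, `TN` TS-truth
#' genes called TS, `FP` TS-truth genes called HK, `FN` HK-truth genes
#' called TS.
#'
#' @param calls Tibble with `gene_id` and `call` columns (from
#'   [score_genes()] or a baseline classifier).
#' @param hk_truth,ts_truth Character vectors of benchmark identifiers.
#' @return One-row tibble: `TP`, `FP`, `TN`, `FN`, `n_excluded`.
#' @export
confusion_counts <- function(calls, hk_truth, ts_truth) {
  overlap <- intersect(hk_truth, ts_truth)
  hk <- setdiff(hk_truth, overlap)
  ts <- setdiff(ts_truth, overlap)
  lut <- calls$call
  names(lut) <- calls$gene_id
  miss <- setdiff(c(hk, ts), names(lut))
  if (length(miss)) {
    abort(sprintf("no call for benchmark gene(s): %s", paste(head(miss, 5L), collapse = ", ")))
  }
  tibble(TP = sum(lut[hk] == "HK"), FP = sum(lut[ts] == "HK"),
         TN = sum(lut[ts] == "TS"), FN = sum(lut[hk] == "TS"),
         n_excluded = length(overlap))
}

#' Accuracy, recall, precision and specificity (percent)
#'
#' Standard definitions on the confusion counts; a metric whose denominator
#' is zero is reported as `NA`, not 0.
#'
#' @param counts One-row tibble from [confusion_counts()] (columns `TP`,
#'   `FP`, `TN`, `FN`).
#' @return One-row tibble with the four metrics in percent.
#' @export
classification_metrics <- function(counts) {
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  with(counts, tibble(
    accuracy = pct(TP + TN, TP + TN + FP + FN),
    recall = pct(TP, TP + FN),
    precision = pct(TP, TP + FP),
    specificity = pct(TN, TN + FP)
  ))
}

#' ROC curve and AUC against benchmark gene sets
#'
#' Sweeps the threshold over all distinct scores (after overlap exclusion)
#' and reports sensitivity vs `1 - specificity`. Tied scores are grouped, so
#' the trapezoidal AUC equals the rank statistic
#' `P(score_HK > score_TS) + 0.5 P(equal)`: perfectly ordered scores give
#' AUC 1 and all-tied scores give AUC 0.5.
#'
#' @param scores Tibble with `gene_id` and `score` columns.
#' @param hk_truth,ts_truth Character vectors of benchmark identifiers
#'   (positives / negatives).
#' @return An `hkera_roc` object: tibble of points `(fpr, sensitivity,
#'   threshold)` with an `auc` attribute.
#' @export
roc_curve <- function(scores, hk_truth, ts_truth) {
  overlap <- intersect(hk_truth, ts_truth)
  hk <- setdiff(hk_truth, overlap)
  ts <- setdiff(ts_truth, overlap)
  if (!length(hk) || !length(ts)) abort("both truth classes must be nonempty after overlap exclusion")
  lut <- scores$score
  names(lut) <- scores$gene_id
  miss <- setdiff(c(hk, ts), names(lut))
  if (length(miss)) {
    abort(sprintf("no score for benchmark gene(s): %s", paste(head(miss, 5L), collapse = ", ")))
  }
  s <- c(lut[hk], lut[ts])
  pos <- c(rep(TRUE, length(hk)), rep(FALSE, length(ts)))
  thr <- sort(unique(s), decreasing = TRUE)
  P <- sum(pos); Ng <- sum(!pos)
  # cumulative counts at call rule score >= threshold, grouped by tied score
  ord <- order(-s)
  grp <- match(s[ord], thr)
  tp <- cumsum(tapply(pos[ord], grp, sum))
  fp <- cumsum(tapply(!pos[ord], grp, sum))
  pts <- tibble(
    threshold = c(Inf, thr),
    sensitivity = c(0, as.numeric(tp) / P),
    fpr = c(0, as.numeric(fp) / Ng)
  )
  auc <- sum(diff(pts$fpr) * (head(pts$sensitivity, -1) + pts$sensitivity[-1]) / 2)
  structure(pts, auc = auc, class = c("hkera_roc", class(pts)))
}

#' Area under an ROC curve
#'
#' @param roc An `hkera_roc` object from [roc_curve()].
#' @return The AUC as a single number.
#' @export
auc <- function(roc) attr(roc, "auc")

#' Cross-coverage of a benchmark set across score thresholds
#'
#' At each threshold, genes scoring strictly above it are the predicted HK
#' set; forward coverage is the percentage of predicted genes found in the
#' benchmark and reverse coverage the percentage of the benchmark recovered.
#' A size-matched random gene set drawn (without replacement, seeded) from
#' the universe provides the control percentages at every threshold.
#'
#' @param scores Tibble with `gene_id` and `score` covering `universe`.
#' @param benchmark Character vector, a subset of `universe`.
#' @param universe Character vector of all candidate genes.
#' @param thresholds Numeric vector of score thresholds.
#' @param seed Integer seed for the random control.
#' @return Tibble with one row per threshold: `threshold`, `n_predicted`,
#'   `forward_pct`, `reverse_pct`, `random_forward_pct`,
#'   `random_reverse_pct`. `forward_pct` is `NA` when no gene passes.
#' @export
cross_coverage <- function(scores, benchmark, universe, thresholds, seed = 1L) {
  if (length(setdiff(benchmark, universe))) abort("benchmark must be a subset of the universe")
  lut <- scores$score
  names(lut) <- scores$gene_id
  miss <- setdiff(universe, names(lut))
  if (length(miss)) {
    abort(sprintf("no score for universe gene(s): %s", paste(head(miss, 5L), collapse = ", ")))
  }
  s <- lut[universe]
  withr::with_seed(seed, {
    rows <- purrr::map(sort(thresholds), function(th) {
      pred <- universe[s > th]
      rand <- if (length(pred)) sample(universe, length(pred)) else character()
      hit <- length(intersect(pred, benchmark))
      rhit <- length(intersect(rand, benchmark))
      tibble(
        threshold = th, n_predicted = length(pred),
        forward_pct = if (length(pred)) 100 * hit / length(pred) else NA_real_,
        reverse_pct = 100 * hit / length(benchmark),
        random_forward_pct = if (length(rand)) 100 * rhit / length(rand) else NA_real_,
        random_reverse_pct = 100 * rhit / length(benchmark)
      )
    })
  })
  bind_rows(rows)
}
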