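# Classical expression-threshold HK classifiers. Each returns a continuous
# score oriented "higher = more HK-like" (so ROC curves for all methods read
# the same way; TSI is reported as 1 - TSI) plus a binary HK/TS call under
# the method's published criterion.

baseline_result <- function(method, gene_id, score, call, params) {
  out <- tibble(gene_id = unname(gene_id), score = unname(score),
                call = unname(ifelse(call, "HK", "TS")))
  attr(out, "method") <- method
  attr(out, "params") <- params
  out
}

default_min_tissues <- function(N, min_tissues) {
  mt <- min_tissues %||% (N - 1L)
  if (mt > N) abort(sprintf("min_tissues (%d) exceeds the tissue count (%d)", mt, N))
  mt
}

#' Expression-magnitude classifier (Exp)
#'
#' A gene is HK iff its intensity is at least `intensity_thr` in at least
#' `min_tissues` tissues (defaults 200 and `N - 1`, the 35-of-36 rule). The
#' score is the fraction of tissues passing the intensity cutoff. By
#' construction this method cannot see housekeeping genes expressed below
#' the cutoff, however stable their ranking.
#'
#' @param expr Wide expression tibble.
#' @param intensity_thr Intensity cutoff (default 200; the comparison is
#'   `>=`).
#' @param min_tissues Minimum passing tissues for an HK call; default
#'   `N - 1`.
#' @return Tibble `gene_id`, `score`, `call`, with `method`/`params`
#'   attributes.
#' @export
exp_classifier <- function(expr, intensity_thr = 200, min_tissues = NULL) {
  validate_expression(expr)
  m <- expr_matrix(expr)
  mt <- default_min_tissues(ncol(m), min_tissues)
  cnt <- rowSums(m >= intensity_thr)
  baseline_result("Exp", rownames(m), cnt / ncol(m), cnt >= mt,
                  list(intensity_thr = intensity_thr, min_tissues = mt))
}

#' Present-call classifier (PCall)
#'
#' A gene is HK iff it carries a Present call in at least `min_tissues`
#' tissues (default `N - 1`). The score is the fraction of tissues present.
#'
#' @param calls Present-call tibble (logical columns), e.g. from
#'   [derive_present_calls()].
#' @inheritParams exp_classifier
#' @return As [exp_classifier()].
#' @export
pcall_classifier <- function(calls, min_tissues = NULL) {
  m <- call_matrix(calls)
  mt <- default_min_tissues(ncol(m), min_tissues)
  cnt <- rowSums(m)
  baseline_result("PCall", rownames(m), cnt / ncol(m), cnt >= mt,
                  list(min_tissues = mt))
}

#' Fraction-present weighted expression intensity classifier (FPEI)
#'
#' Per gene, the fraction of tissues with a Present call (`FP`) weights the
#' per-tissue intensity: `FPEI(t) = FP * x(t)`. A gene is HK iff its FPEI
#' exceeds `fpei_thr` (strictly, default 100) in at least `min_tissues`
#' tissues; the score is the fraction of tissues exceeding.
#'
#' @param expr Wide expression tibble.
#' @param calls Present-call tibble on the same axes.
#' @param fpei_thr FPEI cutoff (default 100; the comparison is `>`).
#' @inheritParams exp_classifier
#' @return As [exp_classifier()].
#' @export
fpei_classifier <- function(expr, calls, fpei_thr = 100, min_tissues = NULL) {
  validate_expression(expr)
  em <- expr_matrix(expr)
  cm <- call_matrix(calls, expr)
  mt <- default_min_tissues(ncol(em), min_tissues)
  fp <- rowMeans(cm)
  fpei <- em * fp
  cnt <- rowSums(fpei > fpei_thr)
  baseline_result("FPEI", rownames(em), cnt / ncol(em), cnt >= mt,
                  list(fpei_thr = fpei_thr, min_tissues = mt))
}

#' Tissue-specificity index classifier (TSI)
#'
#' The Yanai index `TSI = sum_t (1 - x_t / x_max) / (N - 1)` is 0 for a
#' uniform profile and 1 for single-tissue expression. A gene is HK iff
#' `TSI <= tsi_thr` (default 0.1); the score is `1 - TSI` so all baseline
#' scores orient the same way. All-zero profiles get `TSI = 1` by
#' convention, with a warning.
#'
#' @param expr Wide expression tibble.
#' @param tsi_thr TSI cutoff for the HK call (default 0.1, inclusive).
#' @return As [exp_classifier()], plus a `tsi` column with the raw index.
#' @export
tsi_classifier <- function(expr, tsi_thr = 0.1) {
  validate_expression(expr)
  m <- expr_matrix(expr)
  N <- ncol(m)
  xmax <- apply(m, 1L, max)
  zero <- xmax == 0
  if (any(zero)) {
    warn(sprintf("%d all-zero gene profile(s) assigned TSI = 1 by convention", sum(zero)))
    xmax[zero] <- 1
  }
  tsi <- rowSums(1 - m / xmax) / (N - 1)
  tsi[zero] <- 1
  out <- baseline_result("TSI", rownames(m), 1 - tsi, tsi <= tsi_thr,
                         list(tsi_thr = tsi_thr))
  out$tsi <- unname(tsi)
  out
}
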