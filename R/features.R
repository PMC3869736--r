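# Per-gene features: each query gene is paired with every gene of a fixed
# reference panel; its 16 attributes are the means of the tensor components
# A1..A16 over those pairings. Means of signed fractions preserve sign, so
# attributes 1-8 stay >= 0 and 9-16 stay <= 0.

#' Sample a reference gene panel
#'
#' Draws `n` genes uniformly without replacement from `pool` after removing
#' `exclude` (typically the training/test genes), so the panel is disjoint
#' from any set it is later used with. Deterministic for a fixed seed.
#'
#' @param pool Character vector of candidate gene identifiers.
#' @param exclude Character vector of identifiers to remove first.
#' @param n Panel size (default 50).
#' @param seed Integer seed.
#' @return Character vector of `n` identifiers.
#' @export
select_reference_set <- function(pool, exclude = character(), n = 50, seed = 1L) {
  pool <- unique(as.character(pool))
  avail <- setdiff(pool, exclude)
  if (n < 1L) abort("n must be >= 1")
  if (length(avail) < n) {
    abort(sprintf("reference pool too small: need %d genes, only %d available after exclusion (short by %d)",
                  n, length(avail), n - length(avail)))
  }
  withr::with_seed(seed, sample(avail, n))
}

# batch engine: 16 signed component fractions for one query against a panel.
# Columns of the returned 16 x n_ref matrix match decompose_pair exactly.
query_components <- function(eng, qi, ref_idx, thresholds, pre) {
  rq <- eng$m[qi, ]
  dq <- rq[eng$iu] - rq[eng$ju]
  Dm <- rq - t(eng$m[ref_idx, , drop = FALSE])          # N x n_ref
  Dsi <- Dm[eng$iu, , drop = FALSE]
  Dtj <- Dm[eng$ju, , drop = FALSE]
  prod_sign <- Dsi * Dtj
  stable <- pmax(abs(dq), pre$absd[, ref_idx, drop = FALSE]) <= thresholds$theta_s * eng$G
  coex <- dq * pre$d[, ref_idx, drop = FALSE] >= 0
  disp <- pmin(abs(Dsi), abs(Dtj)) >= thresholds$theta_d * eng$G
  idx <- 8L * (prod_sign < 0) + 4L * (!stable) + 2L * (!coex) + (!disp) + 1L
  idx[prod_sign == 0] <- NA_integer_
  counts <- apply(idx, 2L, tabulate, nbins = 16L)       # 16 x n_ref
  comp <- counts / eng$M
  comp[9:16, ] <- -comp[9:16, , drop = FALSE]
  comp
}

# per-gene tissue-pair rank changes, shared across queries
precompute_rank_changes <- function(eng) {
  d <- t(eng$m[, eng$iu, drop = FALSE]) - t(eng$m[, eng$ju, drop = FALSE]) # M x G? no:
  # eng$m is G x N; eng$m[, iu] is G x M. Transpose to M x G.
  list(d = d, absd = abs(d))
}

#' Feature vector for one query gene
#'
#' Pairs `query` with every gene of `reference` and averages the 16 tensor
#' components over the panel. If the query appears in the panel, that
#' self-pair (a degenerate all-tie decomposition) is dropped with a warning.
#'
#' @param ranks Rank tibble from [rank_transform()].
#' @param query Gene identifier.
#' @param reference Character vector of reference gene identifiers.
#' @param thresholds A [tensor_thresholds()] object.
#' @return One-row tibble: `gene_id`, `A1..A16`.
#' @export
build_feature_vector <- function(ranks, query, reference,
                                 thresholds = tensor_thresholds()) {
  build_feature_table(ranks, query, reference, thresholds)
}

#' Feature table for a set of query genes
#'
#' Batch form of [build_feature_vector()]: one row per query, in query
#' order. The reference panel and thresholds used are recorded as
#' attributes `reference` and `thresholds`.
#'
#' @param ranks Rank tibble from [rank_transform()].
#' @param queries Character vector of query gene identifiers.
#' @param reference Character vector of reference gene identifiers.
#' @param thresholds A [tensor_thresholds()] object.
#' @return Tibble: `gene_id`, `A1..A16`, one row per query.
#' @export
build_feature_table <- function(ranks, queries, reference,
                                thresholds = tensor_thresholds()) {
  eng <- rank_engine(ranks)
  queries <- as.character(queries)
  reference <- unique(as.character(reference))
  if (!length(reference)) abort("reference set is empty")
  bad <- setdiff(c(queries, reference), rownames(eng$m))
  if (length(bad)) {
    abort(sprintf("gene identifier(s) absent from the rank matrix: %s",
                  paste(head(bad, 5L), collapse = ", ")))
  }
  ref_idx_all <- match(reference, rownames(eng$m))
  pre <- precompute_rank_changes(eng)
  rows <- purrr::map(queries, function(q) {
    qi <- match(q, rownames(eng$m))
    ref_idx <- ref_idx_all
    if (qi %in% ref_idx) {
      warn(sprintf("query '%s' is in the reference set; self-pair dropped", q))
      ref_idx <- setdiff(ref_idx, qi)
      if (!length(ref_idx)) abort(sprintf("query '%s': reference set empty after dropping self-pair", q))
    }
    comp <- query_components(eng, qi, ref_idx, thresholds, pre)
    av <- rowMeans(comp)
    names(av) <- component_names()
    tibble(gene_id = q, !!!as.list(av))
  })
  out <- bind_rows(rows)
  attr(out, "reference") <- reference
  attr(out, "thresholds") <- thresholds
  out
}
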