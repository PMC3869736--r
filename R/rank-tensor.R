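# Tensor decomposition of rank concordance for a gene pair.
#
# For genes a, b with within-tissue ranks r_a(t), r_b(t) over G genes and N
# tissues, let D(t) = r_a(t) - r_b(t). Over all M = N(N-1)/2 unordered
# tissue pairs (s, t):
#   ranking      R+ iff D(s) * D(t) > 0, R- iff < 0, tie iff the product is 0
#   stableness   S+ iff max(|r_a(s)-r_a(t)|, |r_b(s)-r_b(t)|) <= theta_s * G
#   co-expression C+ iff (r_a(s)-r_a(t)) * (r_b(s)-r_b(t)) >= 0
#   dispersion   D+ iff min(|D(s)|, |D(t)|) >= theta_d * G
# Kendall's tau (tau-a on the D signs) = (#R+ - #R-) / M. Each non-tie
# tissue pair lands in one of 16 cells; component A_k is the signed fraction
# of tissue pairs in cell k (positive for the 8 R+ cells A1-A8, negative for
# the 8 R- cells A9-A16), so sum(A_k) = tau exactly.

#' Stableness and dispersion thresholds for the tensor decomposition
#'
#' Both cutoffs are expressed as fractions of the gene count `G` so they
#' transfer across matrices of different sizes: a gene's rank change between
#' two tissues is "stable" iff it does not exceed `theta_s * G`, and two
#' genes are "dispersed" in a tissue iff their rank difference is at least
#' `theta_d * G`.
#'
#' @param theta_s Stableness cutoff in `[0, 1]` (default 0.10).
#' @param theta_d Dispersion cutoff in `[0, 1]` (default 0.05).
#' @return A `tensor_thresholds` list.
#' @export
tensor_thresholds <- function(theta_s = 0.10, theta_d = 0.05) {
  if (!is.numeric(theta_s) || length(theta_s) != 1L || theta_s < 0 || theta_s > 1) {
    abort("theta_s must be a single value in [0, 1]")
  }
  if (!is.numeric(theta_d) || length(theta_d) != 1L || theta_d < 0 || theta_d > 1) {
    abort("theta_d must be a single value in [0, 1]")
  }
  structure(list(theta_s = theta_s, theta_d = theta_d), class = "tensor_thresholds")
}

#' @export
print.tensor_thresholds <- function(x, ...) {
  cat(sprintf("tensor thresholds: theta_s = %g, theta_d = %g (fractions of gene count)\n",
              x$theta_s, x$theta_d))
  invisible(x)
}

# names of the 16 components; A1-A8 are the R+ block, A9-A16 the R- block,
# and within each block (S, C, D) enumerate (+,+,+), (+,+,-), (+,-,+),
# (+,-,-), (-,+,+), (-,+,-), (-,-,+), (-,-,-). Hence A8 = (R+, S-, C-, D-).
component_names <- function() paste0("A", 1:16)

# rank tibble -> matrix plus the tissue-pair index scaffolding
rank_engine <- function(ranks) {
  m <- expr_matrix(ranks)
  N <- ncol(m)
  if (N < 2L) abort("need at least 2 tissues")
  pr <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  list(m = m, G = nrow(m), N = N, M = nrow(pr), iu = pr[, 1L], ju = pr[, 2L])
}

lookup_gene <- function(eng, id) {
  i <- match(id, rownames(eng$m))
  if (is.na(i)) abort(sprintf("unknown gene identifier: %s", id))
  i
}

lookup_tissue <- function(eng, id) {
  j <- match(id, colnames(eng$m))
  if (is.na(j)) abort(sprintf("unknown tissue identifier: %s", id))
  j
}

# core: per-tissue-pair factor calls for one gene pair, as logical vectors
pair_factors <- function(ra, rb, G, iu, ju, thresholds) {
  D <- ra - rb
  da <- ra[iu] - ra[ju]
  db <- rb[iu] - rb[ju]
  prod_sign <- D[iu] * D[ju]
  list(
    prod_sign = prod_sign,
    stable = pmax(abs(da), abs(db)) <= thresholds$theta_s * G,
    coex = da * db >= 0,
    disp = pmin(abs(D[iu]), abs(D[ju])) >= thresholds$theta_d * G,
    D = D
  )
}

# 16 signed components + tallies from factor calls
factors_to_decomp <- function(f, M) {
  nontie <- f$prod_sign != 0
  rneg <- f$prod_sign < 0
  idx <- 8L * rneg + 4L * (!f$stable) + 2L * (!f$coex) + (!f$disp) + 1L
  counts <- tabulate(idx[nontie], nbins = 16L)
  comp <- counts / M
  comp[9:16] <- -comp[9:16]
  n_conc <- sum(counts[1:8])
  n_disc <- sum(counts[9:16])
  list(components = comp, cell_counts = counts, tie_count = M - n_conc - n_disc,
       n_conc = n_conc, n_disc = n_disc, tau = (n_conc - n_disc) / M)
}

#' Classify one tissue pair of one gene pair
#'
#' Assigns the four presence/absence factors (ranking concordance,
#' stableness, co-expression, dispersion) to a single unordered tissue pair
#' of a gene pair. The assignment is symmetric in tissue order and in gene
#' order (all four rules depend on sign products or absolute differences).
#'
#' @param ranks Rank tibble from [rank_transform()].
#' @param gene_a,gene_b Gene identifiers.
#' @param tissue_s,tissue_t Distinct tissue identifiers.
#' @param thresholds A [tensor_thresholds()] object.
#' @return One-row tibble with columns `ranking` (`"R+"`, `"R-"` or
#'   `"tie"`), `stableness`, `coexpression`, `dispersion` (`"+"`/`"-"`).
#' @export
classify_tissue_pair <- function(ranks, gene_a, gene_b, tissue_s, tissue_t,
                                 thresholds = tensor_thresholds()) {
  eng <- rank_engine(ranks)
  ia <- lookup_gene(eng, gene_a); ib <- lookup_gene(eng, gene_b)
  s <- lookup_tissue(eng, tissue_s); t <- lookup_tissue(eng, tissue_t)
  if (s == t) abort("tissue_s and tissue_t must differ")
  ra <- eng$m[ia, c(s, t)]; rb <- eng$m[ib, c(s, t)]
  f <- pair_factors(ra, rb, eng$G, 1L, 2L, thresholds)
  tibble(
    ranking = if (f$prod_sign > 0) "R+" else if (f$prod_sign < 0) "R-" else "tie",
    stableness = if (f$stable) "+" else "-",
    coexpression = if (f$coex) "+" else "-",
    dispersion = if (f$disp) "+" else "-"
  )
}

#' Kendall's tau of rank concordance for a gene pair
#'
#' The concordance, over all `M = N(N-1)/2` unordered tissue pairs, of the
#' sign of the between-gene rank difference `D(t) = r_a(t) - r_b(t)`:
#' `tau = (n_conc - n_disc) / M` (tau-a; zero sign products count in the
#' denominator only). `n_pos` / `n_neg` count tissue pairs with `D > 0` /
#' `D < 0` in both tissues, so `n_pos + n_neg = n_conc`.
#'
#' @inheritParams classify_tissue_pair
#' @return One-row tibble: `gene_a`, `gene_b`, `tau`, `n_pairs`, `n_conc`,
#'   `n_disc`, `n_tie`, `n_pos`, `n_neg`.
#' @export
kendall_tau_pair <- function(ranks, gene_a, gene_b) {
  eng <- rank_engine(ranks)
  ia <- lookup_gene(eng, gene_a); ib <- lookup_gene(eng, gene_b)
  D <- eng$m[ia, ] - eng$m[ib, ]
  p <- D[eng$iu] * D[eng$ju]
  n_conc <- sum(p > 0); n_disc <- sum(p < 0)
  tibble(
    gene_a = gene_a, gene_b = gene_b,
    tau = (n_conc - n_disc) / eng$M,
    n_pairs = eng$M, n_conc = n_conc, n_disc = n_disc,
    n_tie = eng$M - n_conc - n_disc,
    n_pos = sum(D[eng$iu] > 0 & D[eng$ju] > 0),
    n_neg = sum(D[eng$iu] < 0 & D[eng$ju] < 0)
  )
}

#' Tensor decomposition of a gene pair's rank concordance
#'
#' Classifies every unordered tissue pair by the four factors and reports
#' the 16 signed components `A1..A16`: `A_k = +count_k / M` for the eight
#' ranking-concordant cells (A1-A8) and `-count_k / M` for the eight
#' ranking-discordant cells (A9-A16); within each block stableness,
#' co-expression and dispersion enumerate `(+,+,+)` through `(-,-,-)`.
#' Tissue pairs with a zero sign product (ties) enter neither block, so the
#' components sum exactly to the tau of [kendall_tau_pair()].
#'
#' @inheritParams classify_tissue_pair
#' @return One-row tibble: `gene_a`, `gene_b`, `tau`, `n_pairs`, `n_conc`,
#'   `n_disc`, `n_tie`, `n_pos`, `n_neg`, then `A1..A16`.
#' @export
decompose_pair <- function(ranks, gene_a, gene_b, thresholds = tensor_thresholds()) {
  eng <- rank_engine(ranks)
  decompose_pair_eng(eng, gene_a, gene_b, thresholds)
}

decompose_pair_eng <- function(eng, gene_a, gene_b, thresholds) {
  ia <- lookup_gene(eng, gene_a); ib <- lookup_gene(eng, gene_b)
  f <- pair_factors(eng$m[ia, ], eng$m[ib, ], eng$G, eng$iu, eng$ju, thresholds)
  d <- factors_to_decomp(f, eng$M)
  comp <- as.list(d$components)
  names(comp) <- component_names()
  tibble(
    gene_a = gene_a, gene_b = gene_b, tau = d$tau,
    n_pairs = eng$M, n_conc = d$n_conc, n_disc = d$n_disc, n_tie = d$tie_count,
    n_pos = sum(f$D[eng$iu] > 0 & f$D[eng$ju] > 0),
    n_neg = sum(f$D[eng$iu] < 0 & f$D[eng$ju] < 0),
    !!!comp
  )
}

#' Decompose a table of gene pairs
#'
#' Batch form of [decompose_pair()].
#'
#' @param ranks Rank tibble from [rank_transform()].
#' @param pairs Tibble (or data frame) with columns `gene_a` and `gene_b`.
#' @param thresholds A [tensor_thresholds()] object.
#' @return Tibble with one row per pair, as [decompose_pair()].
#' @export
decompose_pairs <- function(ranks, pairs, thresholds = tensor_thresholds()) {
  eng <- rank_engine(ranks)
  purrr::map2(pairs$gene_a, pairs$gene_b,
              function(a, b) decompose_pair_eng(eng, a, b, thresholds)) |>
    bind_rows()
}
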