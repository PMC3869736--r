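# Shared fixtures and independent oracles, all built in code.

# wide expression tibble from a plain matrix
make_expr <- function(m, genes = sprintf("g%02d", seq_len(nrow(m))),
                      tissues = sprintf("t%02d", seq_len(ncol(m)))) {
  rownames(m) <- genes
  colnames(m) <- tissues
  tibble::tibble(gene_id = genes,
                 !!!tibble::as_tibble(as.data.frame(m, check.names = FALSE)))
}

expr_mat <- function(tbl) {
  m <- as.matrix(tbl[setdiff(names(tbl), "gene_id")])
  rownames(m) <- tbl$gene_id
  m
}

# a rank tibble taken at face value (columns need not be full permutations;
# useful for constructing exact rank scenarios)
make_ranks <- make_expr

# seeded random expression matrix
random_expr <- function(n_genes, n_tissues, seed = 1) {
  withr::with_seed(seed, make_expr(matrix(runif(n_genes * n_tissues, 1, 1000),
                                          n_genes, n_tissues)))
}

# independent brute-force decomposition oracle: explicit double loop over
# tissue pairs, applying the four factor definitions directly
oracle_decompose <- function(ranks, a, b, theta_s = 0.10, theta_d = 0.05) {
  m <- expr_mat(ranks)
  G <- nrow(m); N <- ncol(m)
  ra <- m[a, ]; rb <- m[b, ]
  counts <- integer(16); ties <- 0L; nconc <- 0L; ndisc <- 0L
  for (s in 1:(N - 1)) {
    for (t in (s + 1):N) {
      Ds <- ra[s] - rb[s]; Dt <- ra[t] - rb[t]
      p <- Ds * Dt
      if (p == 0) { ties <- ties + 1L; next }
      k <- 1L
      if (p < 0) k <- k + 8L
      if (max(abs(ra[s] - ra[t]), abs(rb[s] - rb[t])) > theta_s * G) k <- k + 4L
      if ((ra[s] - ra[t]) * (rb[s] - rb[t]) < 0) k <- k + 2L
      if (min(abs(Ds), abs(Dt)) < theta_d * G) k <- k + 1L
      counts[k] <- counts[k] + 1L
      if (p > 0) nconc <- nconc + 1L else ndisc <- ndisc + 1L
    }
  }
  M <- N * (N - 1) / 2
  comp <- counts / M
  comp[9:16] <- -comp[9:16]
  list(tau = (nconc - ndisc) / M, components = comp, counts = counts,
       ties = ties, n_conc = nconc, n_disc = ndisc)
}

# exhaustive pair-counting AUC oracle: P(s_pos > s_neg) + 0.5 P(equal)
oracle_auc <- function(pos_scores, neg_scores) {
  tot <- 0
  for (p in pos_scores) for (q in neg_scores) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos_scores) * length(neg_scores))
}

# 16-attribute feature tibble with two gaussian clouds separated along A1
separable_features <- function(n_per_class = 40, gap = 5, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(2 * n_per_class * 16), 2 * n_per_class, 16)
    x[seq_len(n_per_class), 1] <- x[seq_len(n_per_class), 1] + gap
    colnames(x) <- paste0("A", 1:16)
    ft <- tibble::tibble(gene_id = sprintf("g%03d", seq_len(2 * n_per_class)),
                         !!!tibble::as_tibble(as.data.frame(x)))
    labels <- tibble::tibble(gene_id = ft$gene_id,
                             label = rep(c("HK", "TS"), each = n_per_class))
    list(features = ft, labels = labels)
  })
}

# small synthetic spec for fast end-to-end tests
small_spec <- function(...) {
  args <- utils::modifyList(
    list(n_tissues = 12L, n_hk = 60L, n_ts = 80L, n_mr = 100L), list(...))
  do.call(synthetic_spec, args)
}
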