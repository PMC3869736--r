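# scenario builder: 100 genes, 2 tissues, genes 1 and 2 given exact ranks
two_tissue_ranks <- function(ra, rb, G = 100) {
  t1 <- setdiff(seq_len(G), c(ra[1], rb[1]))
  t2 <- setdiff(seq_len(G), c(ra[2], rb[2]))
  make_ranks(cbind(c(ra[1], rb[1], t1), c(ra[2], rb[2], t2)))
}

test_that("tissue-pair factor rules match the hand-evaluated example", {
  r <- two_tissue_ranks(c(90, 80), c(50, 40))
  cell <- classify_tissue_pair(r, "g01", "g02", "t01", "t02",
                               tensor_thresholds(0.10, 0.05))
  expect_equal(cell$ranking, "R+")       # D = 40, 40: same sign
  expect_equal(cell$stableness, "+")     # max rank change 10 <= 0.10 * 100
  expect_equal(cell$coexpression, "+")   # both genes move the same way
  expect_equal(cell$dispersion, "+")     # min |D| = 40 >= 0.05 * 100
})

test_that("a gene paired with itself gives a ranking tie", {
  r <- two_tissue_ranks(c(90, 80), c(50, 40))
  cell <- classify_tissue_pair(r, "g01", "g01", "t01", "t02")
  expect_equal(cell$ranking, "tie")
})

test_that("tissue-pair classification is symmetric in tissue and gene order", {
  r <- random_expr(20, 4, seed = 2) |> rank_transform()
  a <- classify_tissue_pair(r, "g03", "g07", "t01", "t03")
  expect_equal(classify_tissue_pair(r, "g03", "g07", "t03", "t01"), a)
  expect_equal(classify_tissue_pair(r, "g07", "g03", "t01", "t03"), a)
})

test_that("kendall tau counts concordant and discordant tissue pairs", {
  # D signs (+,+,+,+): gene a above b in all 4 tissues
  r <- make_ranks(matrix(c(3, 1, 2, 3, 1, 2, 3, 1, 2, 3, 1, 2), 3, 4))
  k <- kendall_tau_pair(r, "g01", "g02")
  expect_equal(k$tau, 1)
  expect_equal(k$n_conc, 6)

  # D signs (+,+,-,-): enumerating the 6 tissue pairs gives 2 conc, 4 disc
  r <- make_ranks(cbind(c(3, 1, 2), c(3, 1, 2), c(1, 3, 2), c(1, 3, 2)))
  k <- kendall_tau_pair(r, "g01", "g02")
  expect_equal(k$n_conc, 2)
  expect_equal(k$n_disc, 4)
  expect_equal(k$tau, -1 / 3)
  expect_equal(k$n_pos + k$n_neg, k$n_conc)
})

test_that("36 tissues give 630 unordered tissue pairs", {
  r <- random_expr(10, 36, seed = 4) |> rank_transform()
  expect_equal(kendall_tau_pair(r, "g01", "g02")$n_pairs, 630)
})

test_that("constant rank offset with full dispersion lands all mass in A1", {
  # 20 genes: gene a holds rank 15 and gene b rank 5 in all 4 tissues
  G <- 20
  col <- c(15, 5, setdiff(1:G, c(15, 5)))
  r <- make_ranks(matrix(rep(col, 4), G, 4))
  d <- decompose_pair(r, "g01", "g02")
  expect_equal(d$A1, 1)
  expect_equal(d$tau, 1)
  expect_true(all(as.numeric(d[paste0("A", 2:16)]) == 0))
})

test_that("self-pair decomposition is all ties", {
  r <- random_expr(15, 5, seed = 9) |> rank_transform()
  d <- decompose_pair(r, "g04", "g04")
  expect_equal(d$tau, 0)
  expect_equal(d$n_tie, d$n_pairs)
  expect_true(all(as.numeric(d[paste0("A", 1:16)]) == 0))
})

test_that("decomposition matches the brute-force enumeration oracle", {
  r <- random_expr(20, 5, seed = 21) |> rank_transform()
  pairs <- withr::with_seed(77, {
    data.frame(gene_a = sample(r$gene_id, 50, replace = TRUE),
               gene_b = sample(r$gene_id, 50, replace = TRUE))
  })
  got <- decompose_pairs(r, pairs)
  for (i in seq_len(nrow(pairs))) {
    want <- oracle_decompose(r, pairs$gene_a[i], pairs$gene_b[i])
    expect_equal(got$tau[i], want$tau)
    expect_equal(as.numeric(got[i, paste0("A", 1:16)]), want$components)
    expect_equal(got$n_tie[i], want$ties)
  }
})

test_that("components conserve tau and counts conserve tissue pairs", {
  r <- random_expr(40, 8, seed = 13) |> rank_transform()
  pairs <- withr::with_seed(5, {
    data.frame(gene_a = sample(r$gene_id, 60, replace = TRUE),
               gene_b = sample(r$gene_id, 60, replace = TRUE))
  })
  d <- decompose_pairs(r, pairs)
  comp <- as.matrix(d[paste0("A", 1:16)])
  expect_true(all(abs(rowSums(comp) - d$tau) <= 1e-12))
  expect_true(all(d$n_conc + d$n_disc + d$n_tie == d$n_pairs))
  expect_true(all(comp[, 1:8] >= 0))
  expect_true(all(comp[, 9:16] <= 0))
})

test_that("tie-free tau matches the closed form in k, the count of positive D", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      N <- sample(3:10, 1)
      r <- random_expr(12, N, seed = sample.int(1e6, 1)) |> rank_transform()
      k <- kendall_tau_pair(r, "g01", "g02")
      m <- expr_mat(r)
      D <- m["g01", ] - m["g02", ]
      if (any(D == 0)) next
      kp <- sum(D > 0)
      expect_equal(k$tau,
                   (choose(kp, 2) + choose(N - kp, 2) - kp * (N - kp)) / choose(N, 2))
    }
  })
})

test_that("decomposition is symmetric under gene swap", {
  r <- random_expr(25, 6, seed = 17) |> rank_transform()
  a <- decompose_pair(r, "g02", "g09")
  b <- decompose_pair(r, "g09", "g02")
  expect_equal(a$tau, b$tau)
  expect_equal(as.numeric(a[paste0("A", 1:16)]), as.numeric(b[paste0("A", 1:16)]))
})

test_that("decomposition is invariant under monotone intensity transforms", {
  expr <- random_expr(25, 6, seed = 19)
  logged <- expr
  logged[-1] <- sqrt(expr[-1])
  expect_equal(decompose_pair(rank_transform(expr), "g01", "g05"),
               decompose_pair(rank_transform(logged), "g01", "g05"))
})

test_that("unknown identifiers raise lookup errors", {
  r <- random_expr(5, 3, seed = 1) |> rank_transform()
  expect_error(kendall_tau_pair(r, "g01", "nope"), "unknown gene")
  expect_error(classify_tissue_pair(r, "g01", "g02", "t01", "zz"), "unknown tissue")
  expect_error(classify_tissue_pair(r, "g01", "g02", "t01", "t01"), "must differ")
})

test_that("threshold constructor validates its bounds", {
  expect_error(tensor_thresholds(-0.1, 0.5), "theta_s")
  expect_error(tensor_thresholds(0.1, 1.5), "theta_d")
})
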