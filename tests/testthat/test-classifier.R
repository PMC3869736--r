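test_that("well-separated clouds train to 100% and every fold tests at 100%", {
  sep <- separable_features(n_per_class = 40, gap = 10, seed = 2)
  m <- train_svm(sep$features, sep$labels)
  sc <- score_genes(sep$features, m)
  expect_equal(sc$call, sep$labels$label)

  cv <- cross_validate(sep$features, sep$labels, k = 5, seed = 8)
  expect_true(all(cv$report$test_accuracy == 100))
})

test_that("flipping every label negates every decision value", {
  sep <- separable_features(seed = 3)
  flipped <- sep$labels
  flipped$label <- ifelse(flipped$label == "HK", "TS", "HK")
  s1 <- score_genes(sep$features, train_svm(sep$features, sep$labels))
  s2 <- score_genes(sep$features, train_svm(sep$features, flipped))
  # the linear decision function is antisymmetric in the labels, and the
  # HK-positive orientation follows the labels
  expect_equal(s2$score, -s1$score, tolerance = 1e-8)
  expect_identical(s2$call, ifelse(s1$call == "HK", "TS", "HK"))
})

test_that("manual decision values agree with the svm library", {
  sep <- separable_features(seed = 5)
  for (kernel in c("linear", "radial")) {
    m <- train_svm(sep$features, sep$labels, kernel = kernel)
    x <- scale(as.matrix(sep$features[paste0("A", 1:16)]),
               center = m$centers, scale = m$scales)
    fit <- e1071::svm(x, factor(sep$labels$label, levels = c("HK", "TS")),
                      kernel = kernel, cost = 1, gamma = 1 / 16, scale = FALSE)
    dv <- as.numeric(attr(predict(fit, x, decision.values = TRUE),
                          "decision.values"))
    orient <- if (mean(dv[sep$labels$label == "HK"]) >= 0) 1 else -1
    expect_equal(score_genes(sep$features, m)$score, orient * dv,
                 tolerance = 1e-8)
  }
})

test_that("models round-trip through JSON with identical scores", {
  sep <- separable_features(seed = 7)
  for (kernel in c("linear", "radial")) {
    m <- train_svm(sep$features, sep$labels, kernel = kernel)
    path <- withr::local_tempfile(fileext = ".json")
    write_hkera_model(m, path)
    m2 <- read_hkera_model(path)
    expect_equal(score_genes(sep$features, m2)$score,
                 score_genes(sep$features, m)$score, tolerance = 1e-12)
  }
})

test_that("calls equal sign comparisons at any threshold", {
  sep <- separable_features(seed = 9)
  m <- train_svm(sep$features, sep$labels)
  for (thr in c(-0.5, 0, 0.3)) {
    sc <- score_genes(sep$features, m, threshold = thr)
    expect_identical(sc$call, ifelse(sc$score > thr, "HK", "TS"))
  }
  expect_true(all(score_genes(sep$features, m, threshold = Inf)$call == "TS"))
})

test_that("partition is disjoint and exhaustive", {
  sc <- tibble::tibble(gene_id = sprintf("g%02d", 1:10),
                       score = c(rep(0.4, 6), rep(-0.2, 4)),
                       call = c(rep("HK", 6), rep("TS", 4)))
  p <- partition_genes(sc)
  expect_length(p$hk, 6)
  expect_length(p$ts, 4)
  expect_setequal(c(p$hk, p$ts), sc$gene_id)
  expect_length(intersect(p$hk, p$ts), 0)
})

test_that("cross-validation is stratified, deterministic, and validates inputs", {
  sep <- separable_features(n_per_class = 25, seed = 11)
  cv1 <- cross_validate(sep$features, sep$labels, k = 5, seed = 13)
  cv2 <- cross_validate(sep$features, sep$labels, k = 5, seed = 13)
  expect_identical(cv1$report, cv2$report)
  expect_identical(cv1$selected_fold, cv2$selected_fold)
  tab <- table(cv1$scores$fold, cv1$scores$label)
  expect_true(all(tab == 5))  # 25 per class over 5 folds

  expect_error(cross_validate(sep$features, sep$labels, k = 30, seed = 1),
               "need at least k")
  one_class <- sep$labels
  one_class$label <- "HK"
  expect_error(cross_validate(sep$features, one_class, k = 5, seed = 1))
})

test_that("degenerate all-constant features refuse to fit", {
  ft <- separable_features(seed = 1)$features
  ft[paste0("A", 1:16)] <- 0
  labels <- tibble::tibble(gene_id = ft$gene_id,
                           label = rep(c("HK", "TS"), each = nrow(ft) / 2))
  expect_error(train_svm(ft, labels), "degenerate")
})

test_that("information gain matches direct entropy computation", {
  mk <- function(vals, labs) {
    ft <- tibble::tibble(gene_id = sprintf("g%02d", seq_along(vals)), A1 = vals)
    list(ft = ft, lab = tibble::tibble(gene_id = ft$gene_id, label = labs))
  }
  # perfect separator on balanced classes: 1 bit
  d <- mk(c(1, 1, 1, 1, 5, 5, 5, 5), rep(c("HK", "TS"), each = 4))
  expect_equal(information_gain(d$ft, d$lab)$gain, 1)
  # constant attribute: 0 bits
  d <- mk(rep(2, 8), rep(c("HK", "TS"), each = 4))
  expect_equal(information_gain(d$ft, d$lab)$gain, 0)
  # 75% agreement at the optimal split of balanced classes: 1 - H(0.25)
  d <- mk(c(0, 0, 0, 0, 1, 1, 1, 1),
          c("HK", "HK", "HK", "TS", "TS", "TS", "TS", "HK"))
  h25 <- -(0.25 * log2(0.25) + 0.75 * log2(0.75))
  expect_equal(information_gain(d$ft, d$lab)$gain, 1 - h25, tolerance = 1e-12)
  expect_equal(1 - h25, 0.18872, tolerance = 1e-4)
})

test_that("information gain stays within [0, 1] for two classes", {
  sep <- separable_features(seed = 15)
  ig <- information_gain(sep$features, sep$labels)
  expect_equal(nrow(ig), 16)
  expect_true(all(ig$gain >= 0 & ig$gain <= 1))
})

test_that("leave-one-out reports 16 deltas and flags the informative attribute", {
  withr::with_seed(17, {
    n <- 30
    x <- matrix(rnorm(2 * n * 16, sd = 0.3), 2 * n, 16)
    x[seq_len(n), 1] <- x[seq_len(n), 1] + 4  # A1 is the only informative one
    colnames(x) <- paste0("A", 1:16)
    ft <- tibble::tibble(gene_id = sprintf("g%03d", seq_len(2 * n)),
                         !!!tibble::as_tibble(as.data.frame(x)))
    lab <- tibble::tibble(gene_id = ft$gene_id,
                          label = rep(c("HK", "TS"), each = n))
  })
  loo <- leave_one_feature_out(ft, lab, k = 5, seed = 19)
  expect_equal(nrow(loo), 16)
  expect_lt(loo$delta_accuracy[loo$attribute == "A1"], -20)

  # duplicating the informative attribute makes either copy redundant
  ft2 <- ft
  ft2$A2 <- ft$A1
  loo2 <- leave_one_feature_out(ft2, lab, k = 5, seed = 19)
  expect_equal(loo2$delta_accuracy[loo2$attribute == "A1"], 0, tolerance = 3)
})

test_that("tidy and glance summarize cross-validation runs", {
  sep <- separable_features(seed = 21)
  cv <- cross_validate(sep$features, sep$labels, k = 5, seed = 23)
  td <- tidy(cv)
  expect_equal(nrow(td), 5)
  expect_true(all(c("fold", "test_accuracy", "train_recall") %in% names(td)))
  gl <- glance(cv)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$selected_fold, cv$selected_fold)
  expect_true(all(td$test_accuracy >= 0 & td$test_accuracy <= 100))
})
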