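# SVM classifier on the 16 tensor attributes. Fitting goes through
# e1071::svm; scoring is recomputed from the extracted support coefficients
# so a model serializes to plain JSON and round-trips exactly. The decision
# value is oriented so that positive = HK; at the default zero threshold a
# positive score is an HK call and a negative score a TS call.

attr_cols <- function(features) {
  cols <- intersect(component_names(), names(features))
  if (!length(cols)) abort("feature table has no attribute columns (A1..A16)")
  cols
}

# labels: tibble (gene_id, label) or named character vector; values HK/TS
normalize_labels <- function(labels) {
  if (is.data.frame(labels)) {
    lab <- as.character(labels$label)
    names(lab) <- as.character(labels$gene_id)
  } else {
    lab <- as.character(labels)
    if (is.null(names(lab))) abort("labels must be a (gene_id, label) tibble or a named vector")
  }
  bad <- setdiff(unique(lab), c("HK", "TS"))
  if (length(bad)) abort(sprintf("labels must be 'HK' or 'TS'; found: %s", paste(bad, collapse = ", ")))
  lab
}

labels_for <- function(features, labels) {
  lab <- normalize_labels(labels)
  miss <- setdiff(features$gene_id, names(lab))
  if (length(miss)) {
    abort(sprintf("no label for gene(s): %s", paste(head(miss, 5L), collapse = ", ")))
  }
  unname(lab[features$gene_id])
}

#' Train an SVM on 16-attribute feature vectors
#'
#' Attributes are z-score standardized with training-set statistics (a
#' zero-variance attribute is centred and left unscaled), then an SVM is
#' fitted. The default linear kernel with cost 1 reflects the near
#' orthogonality of the 16 attributes between the HK and TS classes; an RBF
#' kernel is available via `kernel = "radial"`. The decision axis is
#' oriented so HK-labelled training genes score positive.
#'
#' @param features Feature tibble from [build_feature_table()].
#' @param labels Tibble `(gene_id, label)` or named character vector with
#'   values `"HK"`/`"TS"` covering every feature row.
#' @param kernel `"linear"` (default) or `"radial"`.
#' @param cost Regularization constant (default 1).
#' @param gamma RBF kernel width; default `1/16`.
#' @return An `hkera_model` object.
#' @export
train_svm <- function(features, labels, kernel = c("linear", "radial"),
                      cost = 1, gamma = NULL) {
  kernel <- match.arg(kernel)
  cols <- attr_cols(features)
  y <- labels_for(features, labels)
  if (length(unique(y)) < 2L) abort("both classes (HK and TS) must be present")
  x <- as.matrix(features[cols])
  centers <- colMeans(x)
  scales <- apply(x, 2L, sd)
  if (all(scales == 0)) abort("degenerate features: zero variance in every attribute")
  scales[scales == 0] <- 1
  xs <- scale(x, center = centers, scale = scales)
  yf <- factor(y, levels = c("HK", "TS"))
  gamma <- gamma %||% (1 / length(cols))
  fit <- e1071::svm(xs, yf, kernel = kernel, cost = cost, gamma = gamma,
                    scale = FALSE)
  dv <- as.numeric(attr(predict(fit, xs, decision.values = TRUE), "decision.values"))
  orientation <- if (mean(dv[y == "HK"]) >= mean(dv[y == "TS"])) 1 else -1
  model <- structure(list(
    kernel = kernel, cost = cost, gamma = gamma,
    attributes = cols,
    centers = as.numeric(centers), scales = as.numeric(scales),
    sv = unname(as.matrix(fit$SV)), coefs = as.numeric(fit$coefs),
    rho = as.numeric(fit$rho), orientation = orientation,
    n_train = nrow(x),
    metadata = list(thresholds = attr(features, "thresholds"),
                    reference = attr(features, "reference"))
  ), class = "hkera_model")
  model
}

#' @export
print.hkera_model <- function(x, ...) {
  cat(sprintf("hkera SVM model: %s kernel, cost %g, %d support vectors, %d attributes\n",
              x$kernel, x$cost, length(x$coefs), length(x$attributes)))
  invisible(x)
}

# raw decision values, oriented HK-positive
decision_values <- function(model, x) {
  xs <- scale(x[, model$attributes, drop = FALSE],
              center = model$centers, scale = model$scales)
  K <- switch(model$kernel,
    linear = xs %*% t(model$sv),
    radial = {
      d2 <- outer(rowSums(xs^2), rowSums(model$sv^2), "+") - 2 * xs %*% t(model$sv)
      exp(-model$gamma * pmax(d2, 0))
    })
  model$orientation * (as.numeric(K %*% model$coefs) - model$rho)
}

#' Score genes and call them HK or TS
#'
#' The score is the signed SVM decision value (positive leaning HK); it is
#' not clipped, so scores may fall slightly outside `[-1, 1]`. The call is
#' `HK` iff `score > threshold` (default 0).
#'
#' @param features Feature tibble with the model's 16 attributes.
#' @param model An `hkera_model` from [train_svm()].
#' @param threshold Score cutoff for the HK call (default 0).
#' @return Tibble: `gene_id`, `score`, `call`.
#' @export
score_genes <- function(features, model, threshold = 0) {
  cols <- model$attributes
  miss <- setdiff(cols, names(features))
  if (length(miss)) {
    abort(sprintf("feature table lacks attribute column(s): %s", paste(miss, collapse = ", ")))
  }
  s <- decision_values(model, as.matrix(features[cols]))
  tibble(gene_id = features$gene_id, score = s,
         call = ifelse(s > threshold, "HK", "TS"))
}

#' Partition a score table into HK and TS gene sets
#'
#' @param scores Score tibble from [score_genes()].
#' @return List with character vectors `hk` and `ts` (disjoint, exhaustive).
#' @export
partition_genes <- function(scores) {
  list(hk = scores$gene_id[scores$call == "HK"],
       ts = scores$gene_id[scores$call == "TS"])
}

fold_metrics <- function(truth, call) {
  tp <- sum(truth == "HK" & call == "HK")
  tn <- sum(truth == "TS" & call == "TS")
  fp <- sum(truth == "TS" & call == "HK")
  fn <- sum(truth == "HK" & call == "TS")
  c(accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
    recall = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    precision = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_)
}

#' Stratified k-fold cross-validation of the SVM
#'
#' Genes are partitioned into `k` folds stratified by class (equal class
#' counts per fold where divisible, remainder spread round-robin); each fold
#' is held out in turn. Per fold, training and test accuracy, recall and
#' precision are reported in percent (HK is the positive class). The
#' selected model is the fold with the best test accuracy, ties broken by
#' recall then precision then fold index. Deterministic for a fixed seed.
#'
#' @inheritParams train_svm
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return An `hkera_cv` object: `report` (per-fold metrics tibble),
#'   `models` (list of `hkera_model`), `selected_fold`, `model` (the
#'   selected model), and `scores` (out-of-fold score tibble).
#' @export
cross_validate <- function(features, labels, k = 5L, seed = 1L,
                           kernel = c("linear", "radial"), cost = 1, gamma = NULL) {
  kernel <- match.arg(kernel)
  y <- labels_for(features, labels)
  classes <- c("HK", "TS")
  for (cl in classes) {
    if (sum(y == cl) < k) {
      abort(sprintf("class %s has %d genes; need at least k = %d", cl, sum(y == cl), k))
    }
  }
  fold <- integer(nrow(features))
  withr::with_seed(seed, {
    for (cl in classes) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  cols <- attr_cols(features)
  rows <- list(); models <- list(); oof <- list()
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    m <- train_svm(features[tr, , drop = FALSE],
                   tibble(gene_id = features$gene_id[tr], label = y[tr]),
                   kernel = kernel, cost = cost, gamma = gamma)
    sc_tr <- score_genes(features[tr, , drop = FALSE], m)
    sc_te <- score_genes(features[te, , drop = FALSE], m)
    mt <- fold_metrics(y[tr], sc_tr$call)
    me <- fold_metrics(y[te], sc_te$call)
    rows[[f]] <- tibble(fold = f,
                        train_accuracy = mt["accuracy"], train_recall = mt["recall"],
                        train_precision = mt["precision"],
                        test_accuracy = me["accuracy"], test_recall = me["recall"],
                        test_precision = me["precision"])
    models[[f]] <- m
    oof[[f]] <- mutate(sc_te, fold = f, label = y[te])
  }
  report <- bind_rows(rows)
  ord <- order(-report$test_accuracy, -report$test_recall, -report$test_precision,
               report$fold)
  structure(list(report = report, models = models,
                 selected_fold = report$fold[ord[1L]],
                 model = models[[report$fold[ord[1L]]]],
                 scores = bind_rows(oof), k = k, seed = seed),
            class = "hkera_cv")
}

#' @export
print.hkera_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d); selected fold %d\n",
              x$k, x$seed, x$selected_fold))
  cat(sprintf("mean test accuracy %.1f%%, recall %.1f%%, precision %.1f%%\n",
              mean(x$report$test_accuracy), mean(x$report$test_recall),
              mean(x$report$test_precision)))
  invisible(x)
}

#' @describeIn cross_validate Per-fold metrics as a tibble.
#' @param x An `hkera_cv` object.
#' @param ... Unused.
#' @export
tidy.hkera_cv <- function(x, ...) x$report

#' @describeIn cross_validate One-row summary (means over folds plus the
#'   selected fold's test metrics).
#' @export
glance.hkera_cv <- function(x, ...) {
  r <- x$report
  sel <- r[r$fold == x$selected_fold, ]
  tibble(k = x$k, selected_fold = x$selected_fold,
         mean_test_accuracy = mean(r$test_accuracy),
         mean_test_recall = mean(r$test_recall),
         mean_test_precision = mean(r$test_precision),
         selected_test_accuracy = sel$test_accuracy,
         selected_test_recall = sel$test_recall,
         selected_test_precision = sel$test_precision)
}

#' Information gain of each attribute
#'
#' For each attribute, the reduction in class entropy achieved by the best
#' single binary split of that attribute: `IG = H(class) - H(class | split)`,
#' maximized over midpoints of consecutive distinct values, in bits. For two
#' classes the gain lies in `[0, 1]`; a constant attribute has gain 0 and an
#' attribute that separates balanced classes perfectly has gain 1.
#'
#' @inheritParams train_svm
#' @return Tibble: `attribute`, `gain`, `split` (the optimal cut point).
#' @export
information_gain <- function(features, labels) {
  y <- labels_for(features, labels)
  cols <- attr_cols(features)
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  h_class <- h(table(y) / length(y))
  n <- length(y)
  rows <- purrr::map(cols, function(a) {
    v <- features[[a]]
    u <- sort(unique(v))
    if (length(u) < 2L) return(tibble(attribute = a, gain = 0, split = NA_real_))
    cuts <- (u[-1] + u[-length(u)]) / 2
    gains <- vapply(cuts, function(ct) {
      lo <- v <= ct
      h_class - (sum(lo) / n) * h(table(y[lo]) / sum(lo)) -
        (sum(!lo) / n) * h(table(y[!lo]) / sum(!lo))
    }, numeric(1))
    best <- which.max(gains)
    tibble(attribute = a, gain = max(0, gains[best]), split = cuts[best])
  })
  bind_rows(rows)
}

#' Leave-one-attribute-out analysis
#'
#' Re-runs the full cross-validation 16 times, each time with one attribute
#' removed, and reports the change in mean test accuracy relative to the
#' full model (`delta_accuracy = accuracy_without - accuracy_full`; negative
#' values mean the attribute helps). The same seed is used throughout so
#' fold assignments match.
#'
#' @inheritParams cross_validate
#' @return Tibble: `attribute`, `delta_accuracy`, plus `accuracy_full` as an
#'   attribute.
#' @export
leave_one_feature_out <- function(features, labels, k = 5L, seed = 1L,
                                  kernel = c("linear", "radial"), cost = 1) {
  kernel <- match.arg(kernel)
  cols <- attr_cols(features)
  full <- cross_validate(features, labels, k = k, seed = seed,
                         kernel = kernel, cost = cost)
  acc_full <- mean(full$report$test_accuracy)
  rows <- purrr::map(cols, function(a) {
    sub <- features[c("gene_id", setdiff(cols, a))]
    cv <- cross_validate(sub, labels, k = k, seed = seed,
                         kernel = kernel, cost = cost)
    tibble(attribute = a,
           delta_accuracy = mean(cv$report$test_accuracy) - acc_full)
  })
  out <- bind_rows(rows)
  attr(out, "accuracy_full") <- acc_full
  out
}

#' Serialize a model to JSON
#'
#' Writes every number needed to reproduce scores exactly (kernel, support
#' vectors, coefficients, rho, orientation, standardization constants,
#' metadata) at full precision.
#'
#' @param model An `hkera_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hkera_model <- function(model, path) {
  obj <- unclass(model)
  obj$sv <- apply(obj$sv, 1L, identity, simplify = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a model written by [write_hkera_model()]
#'
#' @param path Path to the JSON file.
#' @return An `hkera_model`.
#' @export
read_hkera_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$sv <- if (is.list(obj$sv)) do.call(rbind, obj$sv) else as.matrix(obj$sv)
  structure(obj, class = "hkera_model")
}
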