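# Seeded synthetic transcriptomes with the structure the classifier
# exploits: an HK-like population whose between-gene ranking is nearly
# constant across tissues (gene-specific median intensity times small
# lognormal tissue noise), a TS-like population expressed high in a few
# tissues and near background elsewhere, and a noisy middle-ranged (MR)
# remainder. Intensity level and rank preservation are controlled
# independently, which is exactly the axis that separates rank-based
# classification from magnitude thresholds.

#' Specification of a synthetic transcriptome
#'
#' Defaults mirror the composition of the 13,075-gene x 36-tissue reference
#' compendium scaled to 2,000 genes: 388 HK-like, 734 TS-like and 878
#' middle-ranged genes, so a 300 + 300 training split plus a disjoint
#' 50-gene reference panel can be drawn from the HK and TS pools exactly as
#' in the study protocol.
#'
#' @param n_tissues Number of tissues (default 36).
#' @param n_hk,n_ts,n_mr Genes per population (defaults 388, 734, 878).
#' @param hk_rank_noise_sd Log-scale tissue noise for HK genes (default
#'   0.05); 0 gives perfectly preserved rankings.
#' @param ts_on_tissues Tissues in which a TS gene is expressed (default 3).
#' @param ts_on_level,ts_off_level Median on/off intensities for TS genes
#'   (defaults 500 and 10).
#' @param ts_noise_sd Log-scale noise for TS genes (default 0.3).
#' @param mr_noise_sd Log-scale noise for MR genes (default 0.5).
#' @param base_level_range Range of gene-specific median intensities, drawn
#'   log-uniformly (default `c(50, 5000)`).
#' @param call_threshold Intensity cutoff for derived present calls
#'   (default 100).
#' @param seed Integer seed; each gene gets its own substream so adding
#'   genes does not perturb existing ones.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_tissues = 36L, n_hk = 388L, n_ts = 734L, n_mr = 878L,
                           hk_rank_noise_sd = 0.05, ts_on_tissues = 3L,
                           ts_on_level = 500, ts_off_level = 10,
                           ts_noise_sd = 0.3, mr_noise_sd = 0.5,
                           base_level_range = c(50, 5000),
                           call_threshold = 100, seed = 1L) {
  if (n_tissues < 2L) abort("need at least 2 tissues")
  if (any(c(n_hk, n_ts, n_mr) < 0L)) abort("population sizes must be >= 0")
  if (n_hk + n_ts + n_mr < 4L) abort("need at least 4 genes in total")
  if (hk_rank_noise_sd < 0 || ts_noise_sd < 0 || mr_noise_sd < 0) abort("noise sd must be >= 0")
  if (ts_on_level <= ts_off_level) abort("ts_on_level must exceed ts_off_level")
  if (ts_on_tissues < 1L || ts_on_tissues > n_tissues) abort("ts_on_tissues must be in 1..n_tissues")
  if (length(base_level_range) != 2L || any(base_level_range <= 0) ||
      base_level_range[1] > base_level_range[2]) {
    abort("base_level_range must be a positive increasing interval")
  }
  structure(list(
    n_tissues = as.integer(n_tissues), n_hk = as.integer(n_hk),
    n_ts = as.integer(n_ts), n_mr = as.integer(n_mr),
    hk_rank_noise_sd = hk_rank_noise_sd, ts_on_tissues = as.integer(ts_on_tissues),
    ts_on_level = ts_on_level, ts_off_level = ts_off_level,
    ts_noise_sd = ts_noise_sd, mr_noise_sd = mr_noise_sd,
    base_level_range = base_level_range, call_threshold = call_threshold,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# per-gene substream seed, kept below 2^31
gene_seed <- function(seed, offset, i) {
  (as.numeric(seed) * 48271 + offset * 1e6 + i) %% 2147483587
}

#' Generate a labeled synthetic transcriptome
#'
#' @param spec A [synthetic_spec()].
#' @return List: `expr` (wide intensity tibble), `calls` (present-call
#'   tibble at `spec$call_threshold`), `truth` (tibble `gene_id`, `class`
#'   with values `HK`/`TS`/`MR`).
#' @export
generate_transcriptome <- function(spec = synthetic_spec()) {
  if (!inherits(spec, "synthetic_spec")) abort("spec must come from synthetic_spec()")
  N <- spec$n_tissues
  lo <- log(spec$base_level_range[1]); hi <- log(spec$base_level_range[2])
  gene_row <- function(offset, i, f) {
    withr::with_seed(gene_seed(spec$seed, offset, i), f())
  }
  hk <- lapply(seq_len(spec$n_hk), function(i) gene_row(1L, i, function() {
    base <- exp(runif(1, lo, hi))
    base * exp(rnorm(N, 0, spec$hk_rank_noise_sd))
  }))
  ts <- lapply(seq_len(spec$n_ts), function(i) gene_row(2L, i, function() {
    on <- sample(N, spec$ts_on_tissues)
    x <- spec$ts_off_level * exp(rnorm(N, 0, spec$ts_noise_sd))
    x[on] <- spec$ts_on_level * exp(rnorm(spec$ts_on_tissues, 0, spec$ts_noise_sd))
    x
  }))
  mr <- lapply(seq_len(spec$n_mr), function(i) gene_row(3L, i, function() {
    base <- exp(runif(1, lo, hi))
    base * exp(rnorm(N, 0, spec$mr_noise_sd))
  }))
  m <- do.call(rbind, c(hk, ts, mr))
  ids <- c(sprintf("HK%04d", seq_len(spec$n_hk)),
           sprintf("TS%04d", seq_len(spec$n_ts)),
           sprintf("MR%04d", seq_len(spec$n_mr)))
  rownames(m) <- ids
  colnames(m) <- sprintf("tissue%02d", seq_len(N))
  expr <- matrix_to_tbl(m)
  list(
    expr = expr,
    calls = derive_present_calls(expr, spec$call_threshold),
    truth = tibble(gene_id = ids,
                   class = rep(c("HK", "TS", "MR"),
                               c(spec$n_hk, spec$n_ts, spec$n_mr)))
  )
}

#' Build a labeled benchmark from a synthetic transcriptome
#'
#' Mirrors the study protocol: `n_train_per_class` genes are drawn from the
#' HK and TS pools for training/testing, and a disjoint reference panel of
#' `n_reference` genes is drawn from the remaining pool genes. The default
#' panel is TS-only, the composition reported for the published classifier;
#' `"HK-only"` and `"mixed"` panels are available for robustness checks.
#'
#' @param spec A [synthetic_spec()] describing the transcriptome.
#' @param n_train_per_class Labeled genes per class (default 300).
#' @param n_reference Reference panel size (default 50).
#' @param reference_composition `"TS-only"` (default), `"HK-only"` or
#'   `"mixed"` (half HK, half TS).
#' @param seed Integer seed for the selections (independent of the
#'   transcriptome seed in `spec`).
#' @return List: `data` (the [generate_transcriptome()] output), `ranks`
#'   (rank tibble), `train` (tibble `gene_id`, `label`), `reference`
#'   (character vector), `truth`.
#' @export
make_benchmark <- function(spec = synthetic_spec(), n_train_per_class = 300L,
                           n_reference = 50L,
                           reference_composition = c("TS-only", "HK-only", "mixed"),
                           seed = 1L) {
  reference_composition <- match.arg(reference_composition)
  data <- generate_transcriptome(spec)
  hk_pool <- data$truth$gene_id[data$truth$class == "HK"]
  ts_pool <- data$truth$gene_id[data$truth$class == "TS"]
  for (pool in list(HK = hk_pool, TS = ts_pool)) {
    if (length(pool) < n_train_per_class) {
      abort(sprintf("class pool too small: need %d training genes, have %d",
                    n_train_per_class, length(pool)))
    }
  }
  sel <- withr::with_seed(seed, list(
    hk = sample(hk_pool, n_train_per_class),
    ts = sample(ts_pool, n_train_per_class)
  ))
  train <- tibble(gene_id = c(sel$hk, sel$ts),
                  label = rep(c("HK", "TS"), each = n_train_per_class))
  reference <- switch(reference_composition,
    "TS-only" = select_reference_set(ts_pool, train$gene_id, n_reference, seed = seed + 1L),
    "HK-only" = select_reference_set(hk_pool, train$gene_id, n_reference, seed = seed + 1L),
    "mixed" = c(
      select_reference_set(hk_pool, train$gene_id, n_reference %/% 2L, seed = seed + 1L),
      select_reference_set(ts_pool, train$gene_id, n_reference - n_reference %/% 2L,
                           seed = seed + 2L)
    ))
  list(data = data, ranks = rank_transform(data$expr), train = train,
       reference = reference, reference_composition = reference_composition,
       truth = data$truth)
}
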