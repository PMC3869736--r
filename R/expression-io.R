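# Expression tables are wide tibbles: a `gene_id` character column followed
# by one numeric column per tissue. Present-call tables use logical columns
# on the same axes; rank tables hold within-tissue ranks on the same axes.

#' Validate a wide expression tibble
#'
#' Checks the invariants every downstream computation relies on: unique gene
#' and tissue identifiers, finite nonnegative intensities, and at least two
#' genes and two tissues.
#'
#' @param expr A tibble with a `gene_id` character column and one numeric
#'   column per tissue.
#' @param what Label used in error messages.
#' @return `expr`, invisibly, after validation.
#' @export
validate_expression <- function(expr, what = "expression table") {
  if (!is.data.frame(expr) || !"gene_id" %in% names(expr)) {
    abort(sprintf("%s must be a data frame with a 'gene_id' column", what))
  }
  ids <- as.character(expr$gene_id)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate gene identifier(s) in %s: %s", what,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  tissues <- setdiff(names(expr), "gene_id")
  if (anyDuplicated(tissues)) {
    abort(sprintf("duplicate tissue identifier(s) in %s", what))
  }
  if (length(tissues) < 2L || nrow(expr) < 2L) {
    abort(sprintf("%s needs at least 2 genes and 2 tissues", what))
  }
  vals <- as.matrix(expr[tissues])
  if (!is.numeric(vals)) abort(sprintf("non-numeric value in %s", what))
  if (anyNA(vals) || any(!is.finite(vals))) {
    abort(sprintf("missing or non-finite value in %s (missing data are rejected, not imputed)", what))
  }
  if (any(vals < 0)) abort(sprintf("negative intensity in %s", what))
  invisible(expr)
}

# wide tibble -> numeric matrix with gene_id rownames
expr_matrix <- function(expr) {
  tissues <- setdiff(names(expr), "gene_id")
  m <- as.matrix(expr[tissues])
  rownames(m) <- as.character(expr$gene_id)
  m
}

matrix_to_tbl <- function(m) {
  out <- as_tibble(as.data.frame(m, check.names = FALSE))
  tibble(gene_id = rownames(m), !!!out)
}

#' Read a gene-by-tissue expression table
#'
#' Reads a delimited text file with one header row of tissue names, gene
#' identifiers in the first column, and nonnegative intensities elsewhere.
#' Parsing is strict: ragged rows, non-numeric or negative values, and
#' duplicated identifiers are errors, each reported with the offending line
#' or identifier.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A wide tibble with a `gene_id` column and one numeric column per
#'   tissue, rows and columns in file order.
#' @export
read_expression_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) abort(sprintf("%s: need a header row and at least one gene row", path))
  cells <- strsplit(lines, sep, fixed = TRUE)
  header <- cells[[1]]
  ncol_exp <- length(header)
  body <- cells[-1]
  bad <- which(lengths(body) != ncol_exp)
  if (length(bad)) {
    abort(sprintf("%s: line %d has %d fields, expected %d",
                  path, bad[1] + 1L, lengths(body)[bad[1]], ncol_exp))
  }
  gene_id <- vapply(body, `[[`, character(1), 1L)
  vals <- matrix(NA_real_, nrow = length(body), ncol = ncol_exp - 1L)
  for (j in seq_len(ncol_exp - 1L)) {
    col <- vapply(body, `[[`, character(1), j + 1L)
    num <- suppressWarnings(as.numeric(col))
    if (anyNA(num)) {
      abort(sprintf("%s: non-numeric value '%s' at line %d, column '%s'",
                    path, col[which(is.na(num))[1]],
                    which(is.na(num))[1] + 1L, header[j + 1L]))
    }
    vals[, j] <- num
  }
  colnames(vals) <- header[-1L]
  out <- tibble(gene_id = gene_id, !!!as_tibble(as.data.frame(vals, check.names = FALSE)))
  validate_expression(out, what = path)
  out
}

#' Write a gene-by-tissue expression table
#'
#' Inverse of [read_expression_table()]; round-trips exactly for values
#' representable at full double precision.
#'
#' @param expr Wide expression tibble.
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  tissues <- setdiff(names(expr), "gene_id")
  sep <- if (dialect == "tsv") "\t" else ","
  m <- expr_matrix(expr)
  lines <- c(
    paste(c("gene_id", tissues), collapse = sep),
    paste(expr$gene_id,
          apply(m, 1L, function(r) paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
                                         collapse = sep)),
          sep = sep)
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a gene list
#'
#' One identifier per line; blank lines and `#` comments are ignored and
#' duplicates are collapsed with a warning.
#'
#' @param path Path to the file.
#' @return Character vector of unique identifiers.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- trimws(readr::read_lines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) abort(sprintf("%s: no gene identifiers found", path))
  if (anyDuplicated(lines)) {
    warn(sprintf("%s: %d duplicated identifier(s) collapsed", path, sum(duplicated(lines))))
  }
  unique(lines)
}

#' Write a gene list
#'
#' @param genes Character vector of identifiers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  readr::write_lines(unique(as.character(genes)), path)
  invisible(path)
}

#' Per-tissue rank transform
#'
#' Ranks all genes within each tissue in ascending intensity order (rank 1 =
#' lowest), averaging ties, so every tissue column is a permutation of
#' `1..G` after tie-averaging and sums to `G(G+1)/2` exactly. All pairwise
#' rank-concordance computation consumes this transform, which makes the
#' method invariant to any strictly monotone per-tissue rescaling of the
#' intensities. Ranks are taken over the full gene universe of `expr`;
#' subsetting genes changes ranks, so rank first, subset later.
#'
#' @param expr Wide expression tibble (see [read_expression_table()]).
#' @return Tibble of the same shape holding within-tissue ranks.
#' @export
rank_transform <- function(expr) {
  validate_expression(expr)
  m <- expr_matrix(expr)
  r <- apply(m, 2L, rank, ties.method = "average")
  rownames(r) <- rownames(m)
  matrix_to_tbl(r)
}

#' Derive present/absent calls by intensity threshold
#'
#' A surrogate for platform detection calls (e.g. MAS5 detection p < 0.01)
#' when only intensities are shipped: a gene is called present in a tissue
#' iff its intensity is at least `call_threshold`.
#'
#' @param expr Wide expression tibble.
#' @param call_threshold Nonnegative intensity cutoff (default 100).
#' @return Tibble of the same shape with logical present/absent columns.
#' @export
derive_present_calls <- function(expr, call_threshold = 100) {
  validate_expression(expr)
  if (!is.numeric(call_threshold) || call_threshold < 0) {
    abort("call_threshold must be >= 0")
  }
  m <- expr_matrix(expr) >= call_threshold
  matrix_to_tbl(m)
}

# logical call tibble -> logical matrix, checking axes against expr if given
call_matrix <- function(calls, expr = NULL) {
  m <- as.matrix(calls[setdiff(names(calls), "gene_id")])
  rownames(m) <- as.character(calls$gene_id)
  storage.mode(m) <- "logical"
  if (!is.null(expr)) {
    em <- expr_matrix(expr)
    if (!identical(dim(m), dim(em)) ||
        !identical(rownames(m), rownames(em)) ||
        !identical(colnames(m), colnames(em))) {
      abort("call matrix axes do not match the expression matrix")
    }
  }
  m
}
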