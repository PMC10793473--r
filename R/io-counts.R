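#' Count matrix with per-cell metadata
#'
#' A `mimir_counts` object bundles a genes-by-cells sparse matrix of UMI
#' counts with a tibble of per-cell metadata. It is the entry point for both
#' the trajectory workflow (which needs `pseudotime` and `cell_type`) and the
#' perturbation workflow (which needs `condition` and `batch`).
#'
#' @param counts A genes-by-cells matrix of non-negative integer counts with
#'   unique row (gene) and column (cell) names.
#' @param cell_meta A data frame with one row per cell, keyed by `cell_id`.
#'   Recognised columns: `pseudotime` (numeric, >= 0), `stage`, `cell_type`,
#'   `condition`, `batch`. Missing label columns are filled with `"unknown"`.
#'
#' @return A `mimir_counts` object.
#' @export
count_matrix <- function(counts, cell_meta) {
  counts <- methods::as(Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    mimir_abort("counts must have gene rownames and cell colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    mimir_abort("duplicate gene ids in counts", class = "mimir_parse_error")
  }
  if (anyDuplicated(colnames(counts))) {
    mimir_abort("duplicate cell ids in counts", class = "mimir_parse_error")
  }
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    mimir_abort("counts must be non-negative integers",
                class = "mimir_parse_error")
  }
  cell_meta <- as_tibble(cell_meta)
  if (!"cell_id" %in% names(cell_meta)) {
    mimir_abort("cell_meta must have a cell_id column")
  }
  missing <- setdiff(colnames(counts), cell_meta$cell_id)
  if (length(missing) > 0) {
    mimir_abort(
      sprintf("cells missing from metadata: %s",
              paste(utils::head(missing, 10), collapse = ", ")),
      class = "mimir_meta_error", missing = missing
    )
  }
  cell_meta <- cell_meta[match(colnames(counts), cell_meta$cell_id), ]
  for (col in c("cell_type", "condition", "batch")) {
    if (!col %in% names(cell_meta)) cell_meta[[col]] <- "unknown"
  }
  if (!"pseudotime" %in% names(cell_meta)) cell_meta$pseudotime <- NA_real_
  if (!"stage" %in% names(cell_meta)) cell_meta$stage <- NA_character_
  if (any(!is.na(cell_meta$pseudotime) & cell_meta$pseudotime < 0)) {
    mimir_abort("pseudotime must be >= 0")
  }
  structure(
    list(counts = counts, cell_meta = cell_meta),
    class = "mimir_counts"
  )
}

#' @export
print.mimir_counts <- function(x, ...) {
  cat(sprintf("<mimir_counts> %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  cell types: %s\n",
              paste(unique(x$cell_meta$cell_type), collapse = ", ")))
  invisible(x)
}

#' @export
dim.mimir_counts <- function(x) dim(x$counts)

#' Read a count matrix with cell metadata
#'
#' Reads either a MatrixMarket sparse triplet file with gene/cell TSV
#' sidecars, or a dense TSV with gene rows and cell columns, and joins a
#' per-cell metadata table keyed by `cell_id`.
#'
#' @param path Path to the `.mtx` file or the dense TSV.
#' @param format `"mtx_triplet"` or `"dense_tsv"`.
#' @param meta_path Path to a TSV of per-cell metadata with a `cell_id`
#'   column.
#' @param genes_path,cells_path Sidecar paths for `mtx_triplet`; default to
#'   `path` with `.mtx` replaced by `.genes.tsv` / `.cells.tsv`. Each is a
#'   headerless single-column file.
#'
#' @return A [count_matrix()] object.
#' @export
read_count_matrix <- function(path,
                              format = c("mtx_triplet", "dense_tsv"),
                              meta_path,
                              genes_path = NULL,
                              cells_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    mimir_abort(sprintf("file not found: %s", path),
                class = "mimir_parse_error")
  }
  if (format == "mtx_triplet") {
    genes_path <- genes_path %||% sub("\\.mtx$", ".genes.tsv", path)
    cells_path <- cells_path %||% sub("\\.mtx$", ".cells.tsv", path)
    for (p in c(genes_path, cells_path)) {
      if (!file.exists(p)) {
        mimir_abort(sprintf("sidecar not found: %s", p),
                    class = "mimir_parse_error")
      }
    }
    m <- tryCatch(Matrix::readMM(path), error = function(e) {
      mimir_abort(sprintf("malformed MatrixMarket file %s: %s",
                          path, conditionMessage(e)),
                  class = "mimir_parse_error")
    })
    genes <- readLines(genes_path)
    cells <- readLines(cells_path)
    if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
      mimir_abort(
        sprintf("dimension mismatch in %s: matrix %dx%d vs %d genes, %d cells",
                path, nrow(m), ncol(m), length(genes), length(cells)),
        class = "mimir_parse_error"
      )
    }
    dimnames(m) <- list(genes, cells)
  } else {
    tab <- read.delim(path, check.names = FALSE, row.names = 1)
    m <- as.matrix(tab)
    if (!is.numeric(m)) {
      mimir_abort(sprintf("non-numeric entries in %s", path),
                  class = "mimir_parse_error")
    }
  }
  meta <- read.delim(meta_path, check.names = FALSE,
                     colClasses = c(cell_id = "character"))
  count_matrix(m, meta)
}

#' Log-normalize a count matrix
#'
#' Scales each cell's counts to sum to `scale_total`, adds 1, and transforms
#' to log2 space. Zero counts map to exactly 0, so sparsity is preserved.
#'
#' @param m A [count_matrix()] object.
#' @param scale_total Per-cell target sum after scaling (default 15000).
#'
#' @return A `mimir_normalized` object with `values` (genes-by-cells, log2
#'   scale), `cell_meta`, and `scale_total`.
#' @export
normalize_counts <- function(m, scale_total = 15000) {
  stopifnot(inherits(m, "mimir_counts"))
  if (!is_scalar_number(scale_total) || scale_total <= 0) {
    mimir_abort("scale_total must be a positive number")
  }
  totals <- Matrix::colSums(m$counts)
  if (any(totals == 0)) {
    mimir_abort(
      sprintf("zero-total cell(s): %s",
              paste(utils::head(colnames(m$counts)[totals == 0], 5),
                    collapse = ", ")),
      class = "mimir_normalize_error"
    )
  }
  v <- m$counts
  # scale columns then log2(x + 1); operate on the sparse slots directly
  v@x <- v@x * rep.int(scale_total / totals, diff(v@p))
  v@x <- log2(v@x + 1)
  structure(
    list(values = v, cell_meta = m$cell_meta, scale_total = scale_total),
    class = "mimir_normalized"
  )
}

#' @export
print.mimir_normalized <- function(x, ...) {
  cat(sprintf("<mimir_normalized> %d genes x %d cells (log2, total %g)\n",
              nrow(x$values), ncol(x$values), x$scale_total))
  invisible(x)
}

#' @export
dim.mimir_normalized <- function(x) dim(x$values)
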