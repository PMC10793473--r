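# Small in-code fixtures shared across test files.

# 3-gene x 2-cell count fixture with 4 nonzeros, written as MatrixMarket
# triplet + sidecars + metadata TSV; returns the file paths.
write_mtx_fixture <- function(dir) {
  m <- Matrix::sparseMatrix(
    i = c(1, 1, 2, 3), j = c(1, 2, 1, 2), x = c(5, 1, 2, 7),
    dims = c(3, 2)
  )
  mtx <- file.path(dir, "toy.mtx")
  Matrix::writeMM(m, mtx)
  writeLines(c("gA", "gB", "gC"), file.path(dir, "toy.genes.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "toy.cells.tsv"))
  meta <- file.path(dir, "toy.meta.tsv")
  write.table(
    data.frame(cell_id = c("c1", "c2"), pseudotime = c(0.1, 0.9),
               cell_type = "traj", condition = "ctrl", batch = "b0"),
    meta, sep = "\t", quote = FALSE, row.names = FALSE
  )
  list(mtx = mtx, meta = meta,
       dense = {
         dense <- file.path(dir, "toy_dense.tsv")
         dm <- as.matrix(m)
         dimnames(dm) <- list(c("gA", "gB", "gC"), c("c1", "c2"))
         write.table(cbind(gene = rownames(dm), as.data.frame(dm)), dense,
                     sep = "\t", quote = FALSE, row.names = FALSE)
         dense
       })
}

# count matrix object straight from a dense matrix + minimal metadata
make_counts <- function(m, pseudotime = NULL, cell_type = "traj",
                        condition = "ctrl", batch = "b0") {
  meta <- tibble::tibble(
    cell_id = colnames(m),
    pseudotime = pseudotime %||% rep(NA_real_, ncol(m)),
    cell_type = rep_len(cell_type, ncol(m)),
    condition = rep_len(condition, ncol(m)),
    batch = rep_len(batch, ncol(m))
  )
  count_matrix(m, meta)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# three-term toy ontology: A is_a R, B is_a R
toy_dag <- function() {
  ontology_dag(
    tibble::tibble(term_id = c("R", "A", "B"), name = c("R", "A", "B")),
    tibble::tibble(child = c("A", "B"), parent = c("R", "R"),
                   relation = "is_a")
  )
}

# profile object built directly from a matrix of per-bin means
make_profile <- function(values, t_lo = NULL, t_hi = NULL) {
  nb <- ncol(values)
  t_lo <- t_lo %||% seq(0, 1 - 1 / nb, length.out = nb)
  t_hi <- t_hi %||% seq(1 / nb, 1, length.out = nb)
  structure(
    list(values = values,
         bins = tibble::tibble(segment = seq_len(nb), t_lo = t_lo,
                               t_hi = t_hi, n_cells = 1L),
         excluded_prefix = 0L),
    class = "mimir_profile"
  )
}
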