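#' Similarity matrix container
#'
#' Symmetric gene-by-gene similarity with unit diagonal (expression and
#' functional kinds) or a combination-rule diagonal (combined kind).
#'
#' @param values Symmetric numeric matrix with gene dimnames.
#' @param kind `"expression"`, `"functional"` or `"combined"`.
#' @return A `mimir_similarity` object (a matrix with attributes).
#' @export
similarity_matrix <- function(values,
                              kind = c("expression", "functional",
                                       "combined")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(rownames(values))) {
    mimir_abort("similarity matrix needs gene dimnames")
  }
  if (max(abs(values - t(values))) > 1e-8) {
    mimir_abort("similarity matrix must be symmetric")
  }
  structure(values, kind = kind, class = c("mimir_similarity", "matrix"))
}

#' @export
print.mimir_similarity <- function(x, ...) {
  cat(sprintf("<mimir_similarity:%s> %d genes\n", attr(x, "kind"), nrow(x)))
  invisible(x)
}

#' @describeIn similarity_matrix Long-form tibble of the upper triangle.
#' @method tidy mimir_similarity
#' @param x A `mimir_similarity`.
#' @param ... Unused.
#' @export
tidy.mimir_similarity <- function(x, ...) {
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(
    gene_a = rownames(x)[idx[, 1]],
    gene_b = colnames(x)[idx[, 2]],
    similarity = x[idx],
    kind = attr(x, "kind")
  )
}

#' Build gene-by-pseudotime expression profiles
#'
#' Averages log2-normalized expression over the cells of each pseudotime
#' segment, one row per gene. Optionally drops the earliest segment, whose
#' cells precede lineage specification and would dilute the
#' trajectory-specific dynamics.
#'
#' @param data A `mimir_normalized` matrix.
#' @param segments A `mimir_segments` partition covering the trajectory.
#' @param genes Genes to profile (default: all genes in `data`).
#' @param exclude_presegment Drop the earliest segment (default `FALSE`).
#'
#' @return A `mimir_profile` object: `values` (genes x bins),
#'   `bins` (tibble of retained segments), `excluded_prefix`.
#' @export
build_profiles <- function(data, segments, genes = NULL,
                           exclude_presegment = FALSE) {
  stopifnot(inherits(data, "mimir_normalized"),
            inherits(segments, "mimir_segments"))
  genes <- genes %||% rownames(data$values)
  missing <- setdiff(genes, rownames(data$values))
  if (length(missing) > 0) {
    mimir_abort(sprintf("gene(s) absent from data: %s",
                        paste(utils::head(missing, 5), collapse = ", ")),
                class = "mimir_gene_error")
  }
  keep <- as_tibble(segments)
  excluded <- 0L
  if (exclude_presegment) {
    keep <- keep[-1, ]
    excluded <- 1L
    if (nrow(keep) == 0) {
      mimir_abort("no segments left after excluding the earliest")
    }
  }
  vals <- vapply(keep$cells, function(cs) {
    cs <- intersect(cs, colnames(data$values))
    if (length(cs) == 0) {
      mimir_abort("segment contains no cells present in data")
    }
    Matrix::rowMeans(data$values[genes, cs, drop = FALSE])
  }, numeric(length(genes)))
  if (length(genes) == 1) vals <- matrix(vals, nrow = 1)
  rownames(vals) <- genes
  colnames(vals) <- paste0("bin", keep$segment)
  structure(
    list(values = vals,
         bins = select(keep, "segment", "t_lo", "t_hi", "n_cells"),
         excluded_prefix = excluded),
    class = "mimir_profile"
  )
}

#' @export
print.mimir_profile <- function(x, ...) {
  cat(sprintf("<mimir_profile> %d genes x %d bins (%d leading bin(s) excluded)\n",
              nrow(x$values), ncol(x$values), x$excluded_prefix))
  invisible(x)
}

#' Pairwise distances between pseudotime profiles
#'
#' Jensen-Shannon divergence is computed with base-2 logarithms on
#' sum-normalized profiles (so it is bounded by 1); Euclidean, cosine and
#' Canberra act on the raw profiles.
#'
#' @param p A `mimir_profile`.
#' @param metric One of `"jsd"`, `"euclidean"`, `"cosine"`, `"canberra"`.
#' @return A symmetric gene-by-gene distance matrix with zero diagonal and
#'   a `metric` attribute.
#' @export
profile_distance <- function(p, metric = c("jsd", "euclidean", "cosine",
                                           "canberra")) {
  metric <- match.arg(metric)
  stopifnot(inherits(p, "mimir_profile"))
  v <- p$values
  d <- switch(
    metric,
    euclidean = as.matrix(stats::dist(v, method = "euclidean")),
    canberra = as.matrix(stats::dist(v, method = "canberra")),
    cosine = {
      nrm <- sqrt(rowSums(v^2))
      zero <- nrm == 0
      if (any(zero)) {
        mimir_abort(sprintf("all-zero profile for gene(s): %s",
                            paste(rownames(v)[zero][1:min(5, sum(zero))],
                                  collapse = ", ")),
                    class = "mimir_profile_error")
      }
      s <- (v %*% t(v)) / outer(nrm, nrm)
      d <- 1 - pmin(pmax(s, -1), 1)
      d[d < 0] <- 0
      d
    },
    jsd = {
      rs <- rowSums(v)
      zero <- rs == 0
      if (any(zero)) {
        mimir_abort(sprintf("all-zero profile under jsd for gene(s): %s",
                            paste(rownames(v)[zero][1:min(5, sum(zero))],
                                  collapse = ", ")),
                    class = "mimir_profile_error")
      }
      q <- v / rs
      ent <- function(m) {
        # base-2 entropy by row with 0 log 0 = 0
        x <- m * log2(m)
        x[m == 0] <- 0
        -rowSums(x)
      }
      h <- ent(q)
      G <- nrow(q)
      d <- matrix(0, G, G, dimnames = list(rownames(v), rownames(v)))
      for (i in seq_len(G - 1)) {
        mix <- (q[rep(i, G - i), , drop = FALSE] +
                  q[(i + 1):G, , drop = FALSE]) / 2
        hm <- ent(mix)
        d[i, (i + 1):G] <- hm - (h[i] + h[(i + 1):G]) / 2
      }
      d <- d + t(d)
      d[d < 0] <- 0
      d
    }
  )
  diag(d) <- 0
  attr(d, "metric") <- metric
  d
}

#' Expression similarity from profile distances
#'
#' Distances are scaled zero-preservingly so the largest observed distance
#' maps to `cap` (default 0.95); similarity is one minus the scaled
#' distance. Identical dynamics therefore always attain similarity 1, and
#' the most dissimilar pair attains `1 - cap`.
#'
#' @param distances Symmetric non-negative distance matrix (from
#'   [profile_distance()]).
#' @param cap Upper bound of the scaled distance (default 0.95).
#' @return A [similarity_matrix()] of kind `"expression"`.
#' @export
expression_similarity <- function(distances, cap = 0.95) {
  stopifnot(is.matrix(distances))
  if (any(distances < 0)) mimir_abort("distances must be >= 0")
  mx <- max(distances)
  if (mx == 0) {
    rlang::warn("all distances are zero; similarities set to 1")
    s <- matrix(1, nrow(distances), ncol(distances),
                dimnames = dimnames(distances))
  } else {
    s <- 1 - cap * distances / mx
  }
  diag(s) <- 1
  similarity_matrix(s, kind = "expression")
}
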