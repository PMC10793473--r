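#' Segment a pseudotime axis into cell bins
#'
#' Divides the pseudotime line into `n_segments` equal-width intervals, then
#' fuses adjacent under-populated segments (fewer than `min_cells` cells)
#' until every final segment holds at least `min_cells` cells. When several
#' consecutive segments are under-populated, the fusion plan is chosen to
#' keep as many segments as possible and, among those, to make the final
#' cell counts as even as possible (minimum variance). For up to 16 initial
#' segments all contiguous fusion plans are enumerated exhaustively;
#' beyond that the smallest segment is greedily merged into its smaller
#' neighbour.
#'
#' @param cells Data frame with columns `cell_id` and `pseudotime`, or a
#'   numeric vector of pseudotimes named by cell id.
#' @param n_segments Number of initial equal-width segments (default 15).
#' @param min_cells Minimum cells per final segment (default 60).
#'
#' @return A `mimir_segments` tibble: one row per final segment with
#'   `segment`, `t_lo`, `t_hi`, `n_cells` and a `cells` list-column.
#' @export
segment_pseudotime <- function(cells, n_segments = 15, min_cells = 60) {
  if (is.numeric(cells)) {
    cells <- tibble(cell_id = names(cells) %||%
                      as.character(seq_along(cells)),
                    pseudotime = unname(cells))
  }
  cells <- as_tibble(cells)
  stopifnot(all(c("cell_id", "pseudotime") %in% names(cells)))
  pt <- cells$pseudotime
  if (length(pt) < 1) mimir_abort("need at least one cell")
  lo <- min(pt); hi <- max(pt)
  if (hi == lo) hi <- lo + 1e-9
  breaks <- seq(lo, hi, length.out = n_segments + 1)
  bin <- findInterval(pt, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_segments)

  if (sum(counts) < min_cells) {
    plan <- rep(1L, n_segments)
  } else if (all(counts >= min_cells)) {
    plan <- seq_len(n_segments)
  } else if (n_segments <= 16) {
    plan <- best_fusion_exhaustive(counts, min_cells)
  } else {
    plan <- fusion_greedy(counts, min_cells)
  }

  seg_of_bin <- plan
  segs <- sort(unique(seg_of_bin))
  out <- map(segs, function(s) {
    bins <- which(seg_of_bin == s)
    idx <- bin %in% bins
    tibble(
      t_lo = breaks[min(bins)],
      t_hi = breaks[max(bins) + 1],
      n_cells = sum(idx),
      cells = list(cells$cell_id[idx][order(pt[idx])])
    )
  }) |> bind_rows()
  out <- mutate(out, segment = dplyr::row_number(), .before = 1)
  structure(out, class = c("mimir_segments", class(out)),
            n_initial = n_segments, min_cells = min_cells)
}

# Enumerate all contiguous groupings of bins; keep those whose segment
# counts all reach min_cells; prefer more segments, then lower count
# variance.
best_fusion_exhaustive <- function(counts, min_cells) {
  B <- length(counts)
  cum <- c(0, cumsum(counts))
  best <- NULL; best_k <- -1; best_var <- Inf
  # boundaries encoded as a bitmask over the B-1 interior cut points
  for (mask in 0:(bitwShiftL(1L, B - 1L) - 1L)) {
    cuts <- which(bitwAnd(mask, bitwShiftL(1L, 0:(B - 2))) != 0)
    ends <- c(cuts, B)
    starts <- c(1, cuts + 1)
    seg_counts <- cum[ends + 1] - cum[starts]
    if (any(seg_counts < min_cells)) next
    k <- length(seg_counts)
    v <- if (k > 1) var(seg_counts) else 0
    if (k > best_k || (k == best_k && v < best_var)) {
      best_k <- k; best_var <- v
      best <- rep(seq_along(starts), ends - starts + 1)
    }
  }
  best %||% rep(1L, B)
}

# Greedy fallback: repeatedly merge the smallest segment into its smaller
# neighbour until all segments reach min_cells.
fusion_greedy <- function(counts, min_cells) {
  groups <- as.list(seq_along(counts))
  sizes <- counts
  while (length(sizes) > 1 && any(sizes < min_cells)) {
    i <- which.min(sizes)
    nb <- c(if (i > 1) i - 1, if (i < length(sizes)) i + 1)
    j <- nb[which.min(sizes[nb])]
    a <- min(i, j); b <- max(i, j)
    groups[[a]] <- c(groups[[a]], groups[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    groups[[b]] <- NULL
    sizes <- sizes[-b]
  }
  plan <- integer(length(counts))
  for (s in seq_along(groups)) plan[groups[[s]]] <- s
  plan
}

#' Area under the precision-recall curve of a score ranking
#'
#' Average precision of the descending-score ranking of binary labels,
#' evaluated at every distinct score threshold so tied scores contribute as
#' one block: `AP = sum_k (R_k - R_{k-1}) P_k` over thresholds `k`. With
#' fully tied (constant) scores this equals the positive prevalence -- the
#' expected value for an uninformative ranking.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (0/1 or logical) of the same length.
#' @return A number in `[0, 1]`.
#' @export
aucpr <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  P <- sum(labels)
  if (P == 0 || P == length(labels)) {
    mimir_abort("labels must contain both classes",
                class = "mimir_label_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # indices where a threshold can be placed (end of each tie block)
  block_end <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[block_end]
  n_seen <- block_end
  precision <- tp / n_seen
  recall <- tp / P
  sum(diff(c(0, recall)) * precision)
}

#' Call marker genes for one cell group against a background
#'
#' For every gene, compares expression in `group_cells` against
#' `background_cells`: detection fraction in the group, AUCPR of the gene as
#' a classifier between the two groups, the ratio of that AUCPR to its
#' uninformative expectation, and the log2 fold change of mean expression.
#' A gene passes when `detect_frac >= detect_min`, `aucpr_ratio >= fold`
#' and `logfc > logfc_min`, with `fold` defaulting to 2 in trajectory mode
#' and 7.5 in stage mode.
#'
#' @param data A `mimir_normalized` matrix.
#' @param group_cells,background_cells Disjoint, non-empty cell-id sets.
#' @param mode `"trajectory"` or `"stage"` (sets the default AUCPR fold).
#' @param window Label recorded in the output (segment index or stage).
#' @param detect_min Minimum detected fraction in the group (default 0.1).
#' @param fold Required AUCPR enrichment over the uninformative expectation;
#'   default 2 (trajectory) or 7.5 (stage).
#' @param logfc_min Minimum log2 fold change (default 0.3).
#' @param aucpr_null `"prevalence"` uses the analytic uninformative baseline
#'   (positive-class prevalence); `"permutation"` estimates it by label
#'   permutation.
#' @param n_perm Permutations when `aucpr_null = "permutation"`.
#' @param seed Seed for the permutation null.
#'
#' @return A tibble with one row per gene: `gene`, `window`, `detect_frac`,
#'   `aucpr`, `aucpr_ratio`, `logfc`, `passes`.
#' @export
call_markers <- function(data, group_cells, background_cells,
                         mode = c("trajectory", "stage"),
                         window = NA, detect_min = 0.1, fold = NULL,
                         logfc_min = 0.3,
                         aucpr_null = c("prevalence", "permutation"),
                         n_perm = 1000, seed = 0) {
  mode <- match.arg(mode)
  aucpr_null <- match.arg(aucpr_null)
  stopifnot(inherits(data, "mimir_normalized"))
  fold <- fold %||% if (mode == "trajectory") 2 else 7.5
  group_cells <- intersect(group_cells, colnames(data$values))
  background_cells <- intersect(background_cells, colnames(data$values))
  if (length(group_cells) == 0 || length(background_cells) == 0) {
    mimir_abort("group and background cell sets must be non-empty",
                class = "mimir_label_error")
  }
  if (length(intersect(group_cells, background_cells)) > 0) {
    mimir_abort("group and background cells must be disjoint")
  }
  vg <- data$values[, group_cells, drop = FALSE]
  vb <- data$values[, background_cells, drop = FALSE]
  detect_frac <- Matrix::rowSums(vg > 0) / length(group_cells)
  logfc <- Matrix::rowMeans(vg) - Matrix::rowMeans(vb)
  labels <- c(rep(1L, length(group_cells)), rep(0L, length(background_cells)))
  prevalence <- mean(labels)
  vals <- cbind(as.matrix(vg), as.matrix(vb))
  ap <- apply(vals, 1, aucpr, labels = labels)
  null_ap <- if (aucpr_null == "prevalence") {
    rep(prevalence, nrow(vals))
  } else {
    withr::with_seed(seed, {
      perms <- replicate(n_perm, sample(labels))
      apply(vals, 1, function(v) {
        mean(apply(perms, 2, function(l) aucpr(v, l)))
      })
    })
  }
  out <- tibble(
    gene = rownames(data$values),
    window = window,
    detect_frac = unname(detect_frac),
    aucpr = unname(ap),
    aucpr_ratio = unname(ap / null_ap),
    logfc = unname(logfc)
  )
  mutate(out, passes = .data$detect_frac >= detect_min &
           .data$aucpr_ratio >= fold & .data$logfc > logfc_min)
}

#' Define trajectory- or stage-enriched genes from marker calls
#'
#' Trajectory mode admits a gene that passes in the final pseudotime
#' segment, or in at least two segments. Stage mode admits a gene that
#' passes at any developmental stage.
#'
#' @param calls A tibble of marker calls with a `window` column (as from
#'   [call_markers()] over several windows, row-bound), or a list of such
#'   tibbles ordered by window.
#' @param mode `"trajectory"` or `"stage"`.
#' @param cell_type Label carried on the result.
#'
#' @return A `mimir_enriched` object: `cell_type`, `genes`, and a
#'   `provenance` tibble (`gene`, `rule`, `n_windows`).
#' @export
define_enriched <- function(calls, mode = c("trajectory", "stage"),
                            cell_type = "unknown") {
  mode <- match.arg(mode)
  if (is.list(calls) && !is.data.frame(calls)) calls <- bind_rows(calls)
  calls <- as_tibble(calls)
  windows <- unique(calls$window)
  # the final pseudotime segment: numeric windows order naturally,
  # labelled windows keep their order of appearance
  last_window <- if (is.numeric(windows)) max(windows) else
    windows[length(windows)]
  passed <- filter(calls, .data$passes)
  per_gene <- passed |>
    group_by(.data$gene) |>
    summarise(n_windows = dplyr::n_distinct(.data$window),
              in_last = any(.data$window == last_window),
              .groups = "drop")
  if (mode == "trajectory") {
    per_gene <- mutate(per_gene, rule = dplyr::case_when(
      .data$in_last & .data$n_windows >= 2 ~ "last-segment,>=2-segments",
      .data$in_last ~ "last-segment",
      .data$n_windows >= 2 ~ ">=2-segments",
      TRUE ~ NA_character_
    ))
  } else {
    per_gene <- mutate(per_gene, rule = "any-stage")
  }
  per_gene <- filter(per_gene, !is.na(.data$rule))
  structure(
    list(cell_type = cell_type,
         genes = per_gene$gene,
         provenance = select(per_gene, "gene", "rule", "n_windows")),
    class = "mimir_enriched"
  )
}

#' @export
print.mimir_enriched <- function(x, ...) {
  cat(sprintf("<mimir_enriched> %s: %d genes\n", x$cell_type,
              length(x$genes)))
  invisible(x)
}

#' Union of enriched gene sets from two datasets
#'
#' @param a,b `mimir_enriched` objects for the same cell type.
#' @return A `mimir_enriched` object with the union of genes and merged
#'   provenance.
#' @export
union_enriched <- function(a, b) {
  stopifnot(inherits(a, "mimir_enriched"), inherits(b, "mimir_enriched"))
  if (!identical(a$cell_type, b$cell_type)) {
    mimir_abort(sprintf("cell_type mismatch: %s vs %s",
                        a$cell_type, b$cell_type),
                class = "mimir_celltype_error")
  }
  prov <- bind_rows(a$provenance, b$provenance) |>
    group_by(.data$gene) |>
    summarise(rule = paste(unique(unlist(strsplit(.data$rule, ","))),
                           collapse = ","),
              n_windows = max(.data$n_windows), .groups = "drop")
  structure(
    list(cell_type = a$cell_type,
         genes = union(a$genes, b$genes),
         provenance = prov),
    class = "mimir_enriched"
  )
}

#' Term over-representation by Fisher's exact test
#'
#' One-sided over-representation p-value per term via the exact
#' hypergeometric tail, testing whether `genes` carry the term more often
#' than expected from `background`. Terms with no carrier in the background
#' are skipped.
#'
#' @param genes Gene set of interest (must be a subset of `background`).
#' @param annotations A `mimir_annotations` object.
#' @param background Background gene universe.
#' @return A tibble: `term`, `n_set`, `n_background`, `odds_ratio`,
#'   `p_value`, ordered by p-value.
#' @export
fisher_enrichment <- function(genes, annotations, background) {
  stopifnot(inherits(annotations, "mimir_annotations"))
  genes <- unique(genes); background <- unique(background)
  if (!all(genes %in% background)) {
    mimir_abort("genes must be a subset of background",
                class = "mimir_background_error")
  }
  g2t <- filter(annotations$gene_to_terms, .data$gene %in% background)
  if (nrow(g2t) == 0) {
    return(tibble(term = character(), n_set = integer(),
                  n_background = integer(), odds_ratio = numeric(),
                  p_value = numeric()))
  }
  N <- length(background); n <- length(genes)
  out <- g2t |>
    group_by(term = .data$term) |>
    summarise(n_background = dplyr::n_distinct(.data$gene),
              n_set = dplyr::n_distinct(intersect(.data$gene, genes)),
              .groups = "drop") |>
    mutate(
      odds_ratio = (.data$n_set / n) / (.data$n_background / N),
      p_value = phyper(.data$n_set - 1, .data$n_background,
                       N - .data$n_background, n, lower.tail = FALSE)
    ) |>
    arrange(.data$p_value)
  out
}
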