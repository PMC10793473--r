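#' Andrew's wave psi for robust M-estimation
#'
#' Redescending influence function `psi(u) = a sin(u/a)` for
#' `|u| <= a*pi`, 0 beyond, with the standard tuning constant
#' `a = 1.339`. Follows the weight-function protocol of [MASS::rlm()]
#' (`deriv = 0` returns `psi(u)/u`).
#'
#' @param u Scaled residuals.
#' @param a Tuning constant (default 1.339).
#' @param deriv 0 for weights `psi(u)/u`, 1 for `psi'(u)`.
#' @export
psi_andrew <- function(u, a = 1.339, deriv = 0) {
  if (deriv == 0) {
    w <- ifelse(abs(u) <= a * pi, sin(u / a) / (u / a), 0)
    w[u == 0] <- 1
    w
  } else {
    ifelse(abs(u) <= a * pi, cos(u / a), 0)
  }
}

#' Build the perturbation design matrix
#'
#' One row per cell: observed TF expression levels (forced to exactly 0 in
#' conditions where that TF was mutated or CRISPR-targeted), an `injection`
#' covariate (0 for uninjected controls, 1 for single-gene-targeted, 1.5
#' for multi-gene-targeted conditions), and a 0/1 `batch` covariate.
#'
#' @param data A `mimir_normalized` matrix holding the TF rows.
#' @param tfs TF gene names (rows of `data`).
#' @param knockout_map Named list: condition -> character vector of TFs
#'   knocked out in that condition (may be empty). Every condition present
#'   in the data must appear.
#' @param injection_map Optional named numeric: condition -> injection
#'   value; defaults to 0/1/1.5 from the number of TFs targeted.
#'
#' @return A `mimir_design` object: `X` (cells x predictors), `tfs`,
#'   `cell_ids`.
#' @export
build_design <- function(data, tfs, knockout_map, injection_map = NULL) {
  stopifnot(inherits(data, "mimir_normalized"))
  missing_tf <- setdiff(tfs, rownames(data$values))
  if (length(missing_tf) > 0) {
    mimir_abort(sprintf("TF(s) absent from data: %s",
                        paste(missing_tf, collapse = ", ")),
                class = "mimir_gene_error")
  }
  meta <- data$cell_meta
  conds <- unique(meta$condition)
  missing_cond <- setdiff(conds, names(knockout_map))
  if (length(missing_cond) > 0) {
    mimir_abort(sprintf("condition(s) missing from knockout_map: %s",
                        paste(missing_cond, collapse = ", ")),
                class = "mimir_condition_error")
  }
  unknown <- setdiff(unlist(knockout_map), tfs)
  if (length(unknown) > 0) {
    mimir_abort(sprintf("knockout_map names unknown TF(s): %s",
                        paste(unknown, collapse = ", ")),
                class = "mimir_condition_error")
  }
  tf_levels <- t(as.matrix(data$values[tfs, , drop = FALSE]))
  colnames(tf_levels) <- tfs
  for (cond in conds) {
    ko <- knockout_map[[cond]]
    if (length(ko) > 0) {
      tf_levels[meta$condition == cond, ko] <- 0
    }
  }
  inj <- if (!is.null(injection_map)) {
    unname(injection_map[meta$condition])
  } else {
    n_targeted <- lengths(knockout_map)[meta$condition]
    ifelse(n_targeted == 0, 0, ifelse(n_targeted == 1, 1, 1.5))
  }
  batch_raw <- meta$batch
  batch <- if (is.numeric(batch_raw)) {
    as.numeric(batch_raw)
  } else {
    as.numeric(factor(batch_raw)) - 1
  }
  X <- cbind(tf_levels, injection = inj, batch = batch)
  rownames(X) <- meta$cell_id
  structure(list(X = X, tfs = tfs, cell_ids = meta$cell_id),
            class = "mimir_design")
}

#' @export
print.mimir_design <- function(x, ...) {
  cat(sprintf("<mimir_design> %d cells x %d predictors (%s)\n",
              nrow(x$X), ncol(x$X), paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}

#' Robust linear fit of one gene on the design
#'
#' Iteratively reweighted M-estimation with the Andrew's-wave criterion
#' (MAD scale, at most 50 iterations). Coefficient p-values are asymptotic
#' normal tests from the robust fit; the coefficient of determination is
#' computed from the raw (unweighted) residuals,
#' `R2 = 1 - SSres / SStot`. A constant response is degenerate:
#' `R2 = 0` and no coefficient can pass the target thresholds.
#'
#' @param y Per-cell expression of one gene (aligned to the design rows).
#' @param design A `mimir_design`.
#' @param gene Gene name for reporting.
#' @param maxit Maximum IRLS iterations (default 50).
#' @param acc Convergence tolerance on coefficients (default 1e-8).
#' @return A tibble with one row per predictor: `gene`, `term`,
#'   `estimate`, `std_error`, `p_value`, plus per-gene `r2` and
#'   `converged`.
#' @export
fit_robust <- function(y, design, gene = "gene", maxit = 50, acc = 1e-8) {
  stopifnot(inherits(design, "mimir_design"))
  X <- design$X
  stopifnot(length(y) == nrow(X))
  terms_all <- colnames(X)
  empty <- function(r2, converged) {
    tibble(gene = gene, term = terms_all, estimate = NA_real_,
           std_error = NA_real_, p_value = NA_real_, r2 = r2,
           converged = converged)
  }
  if (length(unique(y)) < 2) return(empty(0, TRUE))
  # drop constant / rank-deficient columns
  keep <- apply(X, 2, function(col) var(col) > 0)
  if (any(!keep)) {
    rlang::warn(sprintf("dropping constant column(s): %s",
                        paste(colnames(X)[!keep], collapse = ", ")))
  }
  Xk <- X[, keep, drop = FALSE]
  qrX <- qr(cbind(1, Xk))
  if (qrX$rank < ncol(Xk) + 1) {
    drop_idx <- setdiff(seq_len(ncol(Xk) + 1), qrX$pivot[seq_len(qrX$rank)])
    drop_names <- colnames(Xk)[drop_idx - 1]
    rlang::warn(sprintf("dropping rank-deficient column(s): %s",
                        paste(drop_names, collapse = ", ")))
    keep[drop_names] <- FALSE
    Xk <- X[, keep, drop = FALSE]
  }
  # an (almost) exact linear fit has no residual scale for M-estimation;
  # report the least-squares solution directly
  ls <- stats::lm.fit(cbind(1, Xk), y)
  if (sd(ls$residuals) < 1e-10) {
    est <- setNames(ls$coefficients[-1], colnames(Xk))
    out <- empty(1, TRUE)
    i <- match(names(est), out$term)
    out$estimate[i] <- unname(est)
    out$std_error[i] <- 0
    out$p_value[i] <- ifelse(abs(est) > 1e-10, 0, 1)
    return(out)
  }
  fit <- tryCatch(
    MASS::rlm(x = cbind(`(Intercept)` = 1, Xk), y = y, psi = psi_andrew,
              scale.est = "MAD", maxit = maxit, acc = acc),
    error = function(e) NULL
  )
  if (is.null(fit)) return(empty(NA_real_, FALSE))
  sm <- summary(fit)$coefficients
  est <- sm[, "Value"]; se <- sm[, "Std. Error"]
  pv <- 2 * pnorm(-abs(est / se))
  res <- y - fit$fitted.values
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot == 0) 0 else 1 - sum(res^2) / sstot
  tibble(
    gene = gene,
    term = terms_all,
    estimate = unname(est[terms_all]),
    std_error = unname(se[terms_all]),
    p_value = unname(pv[terms_all]),
    r2 = r2,
    converged = isTRUE(fit$converged)
  )
}

#' Robust target-gene fits for all response genes
#'
#' Fits every detected response gene against the perturbation design. TFs
#' are excluded from the responses; genes detected in fewer than
#' `detect_min` of the cells are skipped to avoid all-zero regressions.
#'
#' @param data A `mimir_normalized` matrix (same cells as the design).
#' @param design A `mimir_design`.
#' @param genes Candidate response genes (default: all non-TF genes).
#' @param cell_type Label recorded on the fits.
#' @param detect_min Minimum detected cell fraction (default 0.01).
#' @inheritParams fit_robust
#' @return A `mimir_target_fits` tibble (long over gene x predictor).
#' @export
fit_targets <- function(data, design, genes = NULL, cell_type = "unknown",
                        detect_min = 0.01, maxit = 50, acc = 1e-8) {
  stopifnot(inherits(data, "mimir_normalized"),
            inherits(design, "mimir_design"))
  genes <- genes %||% rownames(data$values)
  tf_in <- intersect(genes, design$tfs)
  if (length(tf_in) > 0) {
    rlang::warn(sprintf("TF(s) excluded from responses: %s",
                        paste(tf_in, collapse = ", ")))
    genes <- setdiff(genes, design$tfs)
  }
  vals <- data$values[genes, design$cell_ids, drop = FALSE]
  det <- Matrix::rowSums(vals > 0) / ncol(vals)
  genes <- genes[det >= detect_min]
  out <- bind_rows(map(genes, function(g) {
    fit_robust(as.numeric(vals[g, ]), design, gene = g, maxit = maxit,
               acc = acc)
  }))
  out$cell_type <- cell_type
  class(out) <- c("mimir_target_fits", class(out))
  out
}

#' @describeIn fit_targets One row per gene: `r2`, `converged`, best TF
#'   coefficient.
#' @method glance mimir_target_fits
#' @param x A `mimir_target_fits` tibble.
#' @param ... Unused.
#' @export
glance.mimir_target_fits <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$gene, .data$cell_type) |>
    summarise(r2 = .data$r2[1], converged = .data$converged[1],
              max_coef = suppressWarnings(max(.data$estimate, na.rm = TRUE)),
              .groups = "drop")
}

#' Call TF target genes from robust fits
#'
#' A gene is a positive target of a TF when the gene's model explains
#' enough variance (`r2 > r2_min`), the TF's coefficient exceeds
#' `coef_min`, and its p-value is below `p_max`; negative targets use the
#' symmetric coefficient rule. Non-converged fits are excluded.
#'
#' @param fits A `mimir_target_fits` tibble.
#' @param r2_min,coef_min,p_max Thresholds (defaults 0.15, 0.05, 1e-9).
#' @return A tibble of calls: `tf`, `gene`, `cell_type`, `direction`
#'   (`positive`/`negative`), `estimate`, `p_value`, `r2`.
#' @export
call_targets <- function(fits, r2_min = 0.15, coef_min = 0.05,
                         p_max = 1e-9) {
  fits <- as_tibble(fits)
  tf_terms <- setdiff(unique(fits$term), c("injection", "batch"))
  calls <- fits |>
    filter(.data$term %in% tf_terms, .data$converged,
           !is.na(.data$estimate), .data$r2 > r2_min,
           .data$p_value < p_max, abs(.data$estimate) > coef_min) |>
    mutate(direction = ifelse(.data$estimate > 0, "positive", "negative")) |>
    select(tf = "term", "gene",
           dplyr::any_of("cell_type"), "direction", "estimate",
           "p_value", "r2") |>
    arrange(.data$tf, dplyr::desc(.data$estimate))
  calls
}

#' Consensus induced targets across cell types
#'
#' For mis-expression data a separate single-TF model is fit per cell
#' type; a gene is an induced target of a TF when it is called a positive
#' target in at least `min_cell_types` cell types.
#'
#' @param calls Target calls (from [call_targets()]) pooled over cell
#'   types, with a `cell_type` column.
#' @param min_cell_types Consensus threshold (default 2).
#' @return A tibble: `tf`, `gene`, `n_cell_types`, `cell_types`.
#' @export
call_induced_targets <- function(calls, min_cell_types = 2) {
  calls <- as_tibble(calls)
  stopifnot(all(c("tf", "gene", "cell_type", "direction") %in% names(calls)))
  calls |>
    filter(.data$direction == "positive") |>
    group_by(.data$tf, .data$gene) |>
    summarise(n_cell_types = dplyr::n_distinct(.data$cell_type),
              cell_types = paste(sort(unique(.data$cell_type)),
                                 collapse = ","),
              .groups = "drop") |>
    filter(.data$n_cell_types >= min_cell_types)
}

#' Classify targets into shared and cell-type-specific sets
#'
#' Shared targets are regulated by both TF groups (one per cell type);
#' A-specific targets are regulated only by group A and prefer cell type
#' 1; B-specific symmetrically. Targets in one set only but preferring the
#' other cell type remain unclassified and are reported separately.
#'
#' @param targets_a,targets_b Character vectors of target genes for TF
#'   group A (cell type 1) and B (cell type 2).
#' @param enrichment Tibble with `gene` and `preferred` (the cell type
#'   where the gene is more highly expressed).
#' @param cell_type_1,cell_type_2 The two cell-type labels.
#' @return A tibble: `gene`, `class`
#'   (`shared` / `A_specific` / `B_specific` / `unclassified`).
#' @export
classify_targets <- function(targets_a, targets_b, enrichment,
                             cell_type_1, cell_type_2) {
  enrichment <- as_tibble(enrichment)
  stopifnot(all(c("gene", "preferred") %in% names(enrichment)))
  pref <- setNames(enrichment$preferred, enrichment$gene)
  genes <- union(targets_a, targets_b)
  cls <- vapply(genes, function(g) {
    in_a <- g %in% targets_a; in_b <- g %in% targets_b
    if (in_a && in_b) return("shared")
    p <- pref[g]
    if (in_a && !is.na(p) && p == cell_type_1) return("A_specific")
    if (in_b && !is.na(p) && p == cell_type_2) return("B_specific")
    "unclassified"
  }, character(1))
  tibble(gene = genes, class = unname(cls))
}

#' Rank modules by their target-gene percentage
#'
#' @param targets Character vector of target genes (or a calls tibble with
#'   a `gene` column).
#' @param partition A [module_partition()] sharing a gene universe with
#'   the targets.
#' @return A tibble per module: `module`, `n_genes`, `n_targets`,
#'   `target_pct`, ranked descending.
#' @export
target_module_overlap <- function(targets, partition) {
  stopifnot(inherits(partition, "mimir_partition"))
  if (is.data.frame(targets)) targets <- unique(targets$gene)
  if (length(intersect(targets, partition$assignment$gene)) == 0 &&
      length(targets) > 0) {
    mimir_abort("targets share no genes with the partition",
                class = "mimir_gene_error")
  }
  partition$assignment |>
    group_by(.data$module) |>
    summarise(n_genes = dplyr::n(),
              n_targets = sum(.data$gene %in% targets), .groups = "drop") |>
    mutate(target_pct = 100 * .data$n_targets / .data$n_genes) |>
    arrange(dplyr::desc(.data$target_pct), .data$module)
}
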