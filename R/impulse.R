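# Impulse model: product of a rising and a falling sigmoid,
#   y(t) = (1/h1) * [h0 + (h1-h0) sig(b1 (t - t1))]
#                 * [h2 + (h1-h2) sig(b2 (t2 - t))]
# h0/h1/h2 are baseline/peak/final levels, t1/t2 onset/offset times,
# b1/b2 slopes.

impulse_curve <- function(par, t) {
  (1 / par[["h1"]]) *
    (par[["h0"]] + (par[["h1"]] - par[["h0"]]) *
       sigmoid(par[["b1"]] * (t - par[["t1"]]))) *
    (par[["h2"]] + (par[["h1"]] - par[["h2"]]) *
       sigmoid(par[["b2"]] * (par[["t2"]] - t)))
}

sigmoid_curve <- function(par, t) {
  par[["h0"]] + (par[["h1"]] - par[["h0"]]) *
    sigmoid(par[["b1"]] * (t - par[["t1"]]))
}

eval_fit_curve <- function(fit, t) {
  switch(fit$model,
         flat = rep(fit$params[["h0"]], length(t)),
         sigmoid = sigmoid_curve(fit$params, t),
         impulse = impulse_curve(fit$params, t))
}

# deterministic per-gene seed from the gene name (stable across sessions)
gene_seed <- function(gene, seed = 0) {
  (sum(utf8ToInt(gene) * seq_along(utf8ToInt(gene))) * 31 + seed) %% 2147483647
}

#' Fit an impulse model to one gene's pseudotime profile
#'
#' Least-squares fit of the double-sigmoid impulse curve by multi-start
#' quasi-Newton optimization (20 deterministic random starts seeded from
#' the gene name). A single rising sigmoid and a flat model are also fit;
#' the simpler model is kept unless the richer one improves the residual
#' sum of squares by more than 5% per extra parameter pair. Onset and
#' offset are the threshold crossings of the fitted curve (see
#' [onset_offset()]).
#'
#' @param y Per-bin expression values of one gene.
#' @param t Pseudotime bin centers (same length as `y`, >= 5 bins).
#' @param gene Gene name (used for the deterministic seed and reporting).
#' @param seed Global seed mixed into the per-gene seed.
#' @param n_starts Number of random starts (default 20).
#' @param level_fraction Threshold for the on-interval (default 0.5).
#' @param improvement Required relative RSS improvement per extra
#'   parameter pair (default 0.05).
#'
#' @return A `mimir_impulse` object: `gene`, `model` (`flat`, `sigmoid` or
#'   `impulse`), named `params`, `rss`, and `on_interval` (`c(t_on, t_off)`
#'   or `NULL` for flat fits).
#' @export
fit_impulse <- function(y, t, gene = "gene", seed = 0, n_starts = 20,
                        level_fraction = 0.5, improvement = 0.05) {
  if (length(y) != length(t) || length(y) < 5) {
    mimir_abort("need >= 5 bins with matching pseudotime centers")
  }
  if (any(!is.finite(y)) || any(!is.finite(t))) {
    mimir_abort("non-finite values in profile", class = "mimir_fit_error")
  }
  rng <- range(t); span <- diff(rng)
  if (span == 0) mimir_abort("degenerate pseudotime axis")

  flat_par <- c(h0 = mean(y))
  rss_flat <- sum((y - mean(y))^2)

  fit_one <- function(obj, par0, lower, upper) {
    res <- tryCatch(
      optim(par0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 200)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) {
      res <- tryCatch(optim(par0, obj, method = "Nelder-Mead",
                            control = list(maxit = 500)),
                      error = function(e) NULL)
    }
    res
  }

  ylo <- min(y); yhi <- max(y); amp <- max(yhi - ylo, 1e-6)
  obj_sig <- function(p) {
    names(p) <- c("h0", "h1", "t1", "b1")
    sum((y - sigmoid_curve(p, t))^2)
  }
  obj_imp <- function(p) {
    names(p) <- c("h0", "h1", "h2", "t1", "dt", "b1", "b2")
    q <- c(p[c("h0", "h1", "h2", "t1")], t2 = unname(p[["t1"]] + p[["dt"]]),
           p[c("b1", "b2")])
    sum((y - impulse_curve(q, t))^2)
  }

  best_sig <- NULL; best_imp <- NULL
  withr::with_seed(gene_seed(gene, seed), {
    for (k in seq_len(n_starts)) {
      p0s <- c(h0 = runif(1, ylo, ylo + 0.3 * amp),
               h1 = runif(1, yhi - 0.3 * amp, yhi + 0.2 * amp),
               t1 = runif(1, rng[1], rng[2]),
               b1 = runif(1, 2 / span, 40 / span))
      r <- fit_one(obj_sig, p0s,
                   lower = c(0, 1e-6, rng[1] - span, 0.1 / span),
                   upper = c(yhi + amp, yhi + amp, rng[2] + span,
                             200 / span))
      if (!is.null(r) && (is.null(best_sig) || r$value < best_sig$value)) {
        best_sig <- r
      }
      p0i <- c(h0 = runif(1, ylo, ylo + 0.3 * amp),
               h1 = runif(1, yhi - 0.3 * amp, yhi + 0.2 * amp),
               h2 = runif(1, ylo, ylo + 0.5 * amp),
               t1 = runif(1, rng[1], rng[2]),
               dt = runif(1, 0.05 * span, 0.8 * span),
               b1 = runif(1, 2 / span, 40 / span),
               b2 = runif(1, 2 / span, 40 / span))
      r <- fit_one(obj_imp, p0i,
                   lower = c(0, 1e-6, 0, rng[1] - span, 0, 0.1 / span,
                             0.1 / span),
                   upper = c(yhi + amp, yhi + amp, yhi + amp, rng[2] + span,
                             2 * span, 200 / span, 200 / span))
      if (!is.null(r) && (is.null(best_imp) || r$value < best_imp$value)) {
        best_imp <- r
      }
    }
  })

  rss_sig <- if (!is.null(best_sig)) best_sig$value else Inf
  rss_imp <- if (!is.null(best_imp)) best_imp$value else Inf

  # prefer the simpler model unless the richer one clearly improves rss
  model <- "flat"; params <- flat_par; rss <- rss_flat
  if (rss_sig < (1 - improvement) * rss) {
    model <- "sigmoid"
    params <- setNames(best_sig$par, c("h0", "h1", "t1", "b1"))
    rss <- rss_sig
  }
  if (rss_imp < (1 - improvement) * rss) {
    p <- setNames(best_imp$par, c("h0", "h1", "h2", "t1", "dt", "b1", "b2"))
    params <- c(p[c("h0", "h1", "h2", "t1")],
                t2 = unname(p[["t1"]] + p[["dt"]]), p[c("b1", "b2")])
    model <- "impulse"
    rss <- rss_imp
  }
  # near-constant profiles stay flat regardless
  if (amp < 1e-8) {
    model <- "flat"; params <- flat_par; rss <- rss_flat
  }

  fit <- structure(
    list(gene = gene, model = model, params = params, rss = rss,
         t_range = rng, on_interval = NULL),
    class = "mimir_impulse"
  )
  if (model != "flat") {
    fit$on_interval <- onset_offset(fit, level_fraction = level_fraction)
  }
  fit
}

#' @export
print.mimir_impulse <- function(x, ...) {
  cat(sprintf("<mimir_impulse> %s: %s model, rss %.3g", x$gene, x$model,
              x$rss))
  if (!is.null(x$on_interval)) {
    cat(sprintf(", on [%.3g, %.3g]", x$on_interval[1], x$on_interval[2]))
  }
  cat("\n")
  invisible(x)
}

#' Onset and offset times of a fitted temporal curve
#'
#' The fitted curve is evaluated on a dense grid over the observed
#' pseudotime range; the gene is "on" wherever the curve reaches
#' `level_fraction` of the amplitude between its minimum and maximum.
#' Onset (offset) is the earliest (latest) such time; a monotone rising
#' sigmoid therefore stays on until the trajectory end.
#'
#' @param fit A `mimir_impulse` fit (model must not be flat).
#' @param level_fraction Fraction of the rise amplitude defining "on"
#'   (default 0.5).
#' @param n_grid Grid resolution (default 1024).
#' @return `c(t_on, t_off)`.
#' @export
onset_offset <- function(fit, level_fraction = 0.5, n_grid = 1024) {
  stopifnot(inherits(fit, "mimir_impulse"))
  if (fit$model == "flat") {
    mimir_abort("flat fits have no on-interval", class = "mimir_fit_error")
  }
  tg <- seq(fit$t_range[1], fit$t_range[2], length.out = n_grid)
  yg <- eval_fit_curve(fit, tg)
  lo <- min(yg); hi <- max(yg)
  thr <- lo + level_fraction * (hi - lo)
  on <- which(yg >= thr)
  c(t_on = tg[min(on)], t_off = tg[max(on)])
}

#' Fit impulse models to every gene of a profile
#'
#' @param profile A `mimir_profile`.
#' @param genes Genes to fit (default all).
#' @inheritParams fit_impulse
#' @return A `mimir_impulse_fits` tibble: one row per gene with `model`,
#'   the parameters, `rss`, `t_on`, `t_off`.
#' @export
fit_impulse_profiles <- function(profile, genes = NULL, seed = 0,
                                 n_starts = 20, level_fraction = 0.5) {
  stopifnot(inherits(profile, "mimir_profile"))
  genes <- genes %||% rownames(profile$values)
  centers <- (profile$bins$t_lo + profile$bins$t_hi) / 2
  rows <- map(genes, function(g) {
    fit <- fit_impulse(profile$values[g, ], centers, gene = g, seed = seed,
                       n_starts = n_starts,
                       level_fraction = level_fraction)
    tibble(
      gene = g, model = fit$model, rss = fit$rss,
      h0 = fit$params[["h0"]],
      h1 = if ("h1" %in% names(fit$params)) fit$params[["h1"]] else NA_real_,
      h2 = if ("h2" %in% names(fit$params)) fit$params[["h2"]] else NA_real_,
      t1 = if ("t1" %in% names(fit$params)) fit$params[["t1"]] else NA_real_,
      t2 = if ("t2" %in% names(fit$params)) fit$params[["t2"]] else NA_real_,
      b1 = if ("b1" %in% names(fit$params)) fit$params[["b1"]] else NA_real_,
      b2 = if ("b2" %in% names(fit$params)) fit$params[["b2"]] else NA_real_,
      t_on = if (!is.null(fit$on_interval)) fit$on_interval[[1]] else NA_real_,
      t_off = if (!is.null(fit$on_interval)) fit$on_interval[[2]] else NA_real_
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("mimir_impulse_fits", class(out))
  out
}

#' Order modules into a temporal cascade
#'
#' Modules are ordered by the mean onset time of their member genes;
#' activity is the fraction of member genes whose on-interval covers each
#' pseudotime bin. Modules whose genes are all flat carry no onset and are
#' placed last with a warning.
#'
#' @param fits A `mimir_impulse_fits` tibble (from
#'   [fit_impulse_profiles()]).
#' @param partition A [module_partition()] over (a subset of) the fitted
#'   genes.
#' @param bins Tibble of bins with `t_lo`, `t_hi` (e.g. `profile$bins`).
#' @return A `mimir_cascade` object: `order` (module ids, ascending mean
#'   onset), `mean_onset` tibble, `activity` (module-by-bin matrix in
#'   `[0, 1]`).
#' @export
order_modules <- function(fits, partition, bins) {
  stopifnot(inherits(partition, "mimir_partition"))
  fits <- as_tibble(fits)
  bins <- as_tibble(bins)
  joined <- dplyr::inner_join(fits, partition$assignment, by = "gene")
  if (nrow(joined) == 0) mimir_abort("no fitted genes in the partition")
  onset <- joined |>
    group_by(.data$module) |>
    summarise(mean_onset = mean(.data$t_on, na.rm = TRUE),
              n_genes = dplyr::n(), .groups = "drop")
  all_flat <- is.nan(onset$mean_onset)
  if (any(all_flat)) {
    rlang::warn(sprintf("module(s) with all-flat fits placed last: %s",
                        paste(onset$module[all_flat], collapse = ", ")))
    onset$mean_onset[all_flat] <- Inf
  }
  onset <- arrange(onset, .data$mean_onset)
  centers <- (bins$t_lo + bins$t_hi) / 2
  activity <- matrix(
    0, nrow(onset), length(centers),
    dimnames = list(onset$module,
                    paste0("bin", bins$segment %||% seq_along(centers))))
  for (m in onset$module) {
    members <- filter(joined, .data$module == m)
    covers <- vapply(centers, function(tc) {
      mean(!is.na(members$t_on) & members$t_on <= tc &
             members$t_off >= tc)
    }, numeric(1))
    activity[m, ] <- covers
  }
  structure(
    list(order = onset$module, mean_onset = onset, activity = activity,
         bin_centers = centers),
    class = "mimir_cascade"
  )
}

#' @export
print.mimir_cascade <- function(x, ...) {
  cat(sprintf("<mimir_cascade> %d modules: %s\n", length(x$order),
              paste(utils::head(x$order, 8), collapse = " -> ")))
  invisible(x)
}

#' @describeIn order_modules Long-form activity tibble
#' @method tidy mimir_cascade
#'   (`module`, `bin`, `bin_center`, `activity`).
#' @param x A `mimir_cascade`.
#' @param ... Unused.
#' @export
tidy.mimir_cascade <- function(x, ...) {
  tibble(
    module = rep(rownames(x$activity), ncol(x$activity)),
    bin = rep(colnames(x$activity), each = nrow(x$activity)),
    bin_center = rep(x$bin_centers, each = nrow(x$activity)),
    activity = as.vector(x$activity)
  )
}

#' Fraction of each cell's transcripts in a module
#'
#' @param m A [count_matrix()].
#' @param module_genes Gene set of one module.
#' @param cells Cells to evaluate (default all).
#' @return Tibble with `cell_id` and `fraction` in `[0, 1]`.
#' @export
module_transcript_fraction <- function(m, module_genes, cells = NULL) {
  stopifnot(inherits(m, "mimir_counts"))
  cells <- cells %||% colnames(m$counts)
  totals <- Matrix::colSums(m$counts[, cells, drop = FALSE])
  if (any(totals == 0)) {
    mimir_abort(sprintf("zero-total cell(s): %s",
                        paste(utils::head(cells[totals == 0], 5),
                              collapse = ", ")),
                class = "mimir_normalize_error")
  }
  genes <- intersect(module_genes, rownames(m$counts))
  part <- if (length(genes) == 0) {
    rep(0, length(cells))
  } else {
    Matrix::colSums(m$counts[genes, cells, drop = FALSE])
  }
  tibble(cell_id = cells, fraction = unname(part / totals))
}
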