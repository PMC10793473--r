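#' Heatmap of module activity along pseudotime
#'
#' Modules (rows, cascade order) by pseudotime bins (columns), coloured by
#' the fraction of member genes "on" in each bin.
#'
#' @param object A `mimir_cascade` from [order_modules()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mimir_cascade
#' @export
autoplot.mimir_cascade <- function(object, ...) {
  df <- tidy(object)
  df$module <- factor(df$module, levels = rev(object$order))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center, y = .data$module,
                                   fill = .data$activity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "fraction on") +
    ggplot2::labs(x = "pseudotime", y = NULL,
                  title = "Module activity cascade") +
    ggplot2::theme_minimal()
}

#' Plot pseudotime expression profiles for a set of genes
#'
#' @param profile A `mimir_profile`.
#' @param genes Genes to draw (default: first 12).
#' @return A ggplot of mean log2 expression per bin.
#' @export
plot_profiles <- function(profile, genes = NULL) {
  stopifnot(inherits(profile, "mimir_profile"))
  genes <- genes %||% utils::head(rownames(profile$values), 12)
  centers <- (profile$bins$t_lo + profile$bins$t_hi) / 2
  df <- tibble(
    gene = rep(genes, each = length(centers)),
    pseudotime = rep(centers, length(genes)),
    expression = as.vector(t(profile$values[genes, , drop = FALSE]))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pseudotime,
                                   y = .data$expression,
                                   colour = .data$gene)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pseudotime", y = "mean log2 expression") +
    ggplot2::theme_minimal()
}

#' Coefficient-significance plot of robust target fits
#'
#' TF coefficient against -log10 p-value for every fitted gene, with the
#' calling thresholds drawn as reference lines.
#'
#' @param fits A `mimir_target_fits` tibble.
#' @param tf Which TF term to plot (default: first).
#' @param coef_min,p_max Thresholds drawn as reference lines.
#' @return A ggplot.
#' @export
plot_target_calls <- function(fits, tf = NULL, coef_min = 0.05,
                              p_max = 1e-9) {
  fits <- as_tibble(fits)
  tf <- tf %||% setdiff(unique(fits$term), c("injection", "batch"))[1]
  df <- filter(fits, .data$term == tf, !is.na(.data$estimate))
  df$neglog10p <- -log10(pmax(df$p_value, 1e-300))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                   y = .data$neglog10p)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = c(-coef_min, coef_min),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(p_max), linetype = "dashed") +
    ggplot2::labs(x = sprintf("%s coefficient", tf),
                  y = "-log10 p-value") +
    ggplot2::theme_minimal()
}
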