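#' Evidence channels for gene pairs
#'
#' Container for per-pair association evidence: interaction channels (e.g.
#' `coexpression`, `experiments`, `textmining`) and, once assembled, one
#' semantic channel per annotation database. Scores live in `[0, 1]`;
#' `NA` means the channel carries no evidence for that pair (distinct from a
#' zero score). Pair keys are unordered: `gene_a < gene_b`.
#'
#' @param pairs Tibble with columns `gene_a`, `gene_b` and one numeric column
#'   per channel.
#' @param prior Fixed prior probability shared by all channels (default
#'   0.41, the convention of the interaction-score combination rule).
#'
#' @return A `mimir_channels` object.
#' @export
evidence_channels <- function(pairs, prior = 0.41) {
  pairs <- as_tibble(pairs)
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  if (!is_scalar_number(prior) || prior <= 0 || prior >= 1) {
    mimir_abort("prior must be in (0, 1)")
  }
  chan <- channel_names(pairs)
  for (ch in chan) check_range(pairs[[ch]], 0, 1, sprintf("channel %s", ch))
  key <- order_pairs(pairs$gene_a, pairs$gene_b)
  pairs$gene_a <- key$gene_a
  pairs$gene_b <- key$gene_b
  structure(list(pairs = pairs, prior = prior), class = "mimir_channels")
}

channel_names <- function(pairs) {
  setdiff(names(pairs), c("gene_a", "gene_b"))
}

#' @export
print.mimir_channels <- function(x, ...) {
  cat(sprintf("<mimir_channels> %d pairs, prior %.2f; channels: %s\n",
              nrow(x$pairs), x$prior,
              paste(channel_names(x$pairs), collapse = ", ")))
  invisible(x)
}

#' Read a STRING-style full-links score table
#'
#' Whitespace-delimited table with a header naming the two protein/gene
#' columns followed by per-channel integer scores on the 0--1000 convention.
#' Scores are divided by 1000 into `[0, 1]`. The derived `combined_score`
#' column, when present, is never kept as a channel.
#'
#' @param path File path.
#' @param drop_channels Channel names to exclude (default: the `database`
#'   and `database_transferred` sources, whose underlying annotation
#'   databases are undisclosed and would double-count the self-computed
#'   semantic channels).
#' @param prior Prior passed to [evidence_channels()].
#'
#' @return A [evidence_channels()] object with symmetric, deduplicated pairs.
#' @export
read_string_links <- function(path,
                              drop_channels = c("database",
                                                "database_transferred"),
                              prior = 0.41) {
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3) {
    mimir_abort(sprintf("expected protein1 protein2 + channels in %s", path),
                class = "mimir_parse_error")
  }
  names(tab)[1:2] <- c("gene_a", "gene_b")
  score_cols <- setdiff(names(tab), c("gene_a", "gene_b"))
  for (ch in score_cols) {
    x <- tab[[ch]]
    bad <- which(!is.na(x) & (x < 0 | x > 1000))
    if (length(bad) > 0) {
      mimir_abort(
        sprintf("score outside 0-1000 in column %s, data row %d of %s",
                ch, bad[1], path),
        class = "mimir_parse_error"
      )
    }
    tab[[ch]] <- x / 1000
  }
  keep <- setdiff(score_cols, c(drop_channels, "combined_score"))
  tab <- as_tibble(tab[, c("gene_a", "gene_b", keep)])
  key <- order_pairs(tab$gene_a, tab$gene_b)
  tab$gene_a <- key$gene_a
  tab$gene_b <- key$gene_b
  dup <- duplicated(tab[, c("gene_a", "gene_b")])
  if (any(dup)) {
    # symmetric files list each pair twice; keep the max score per channel
    tab <- tab |>
      group_by(.data$gene_a, .data$gene_b) |>
      summarise(dplyr::across(dplyr::all_of(keep), ~ max(.x, na.rm = TRUE)),
                .groups = "drop")
  }
  evidence_channels(tab, prior = prior)
}
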