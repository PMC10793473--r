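#' Module partition
#'
#' Assignment of each gene to exactly one module, with optional per-module
#' annotation labels and provenance of the configuration that produced it.
#'
#' @param assignment Tibble with columns `gene`, `module` (each gene once).
#' @param annotations Optional named character vector: module id -> label.
#' @param config Optional named list recording how the partition was made
#'   (logic, metric, algorithm, resolution, seed).
#'
#' @return A `mimir_partition` object.
#' @export
module_partition <- function(assignment, annotations = NULL, config = list()) {
  assignment <- as_tibble(assignment)
  stopifnot(all(c("gene", "module") %in% names(assignment)))
  assignment$module <- as.character(assignment$module)
  if (anyDuplicated(assignment$gene)) {
    mimir_abort("a gene appears in more than one module",
                class = "mimir_partition_error")
  }
  if (nrow(assignment) == 0) {
    mimir_abort("empty partition", class = "mimir_partition_error")
  }
  structure(
    list(assignment = assignment[, c("gene", "module")],
         annotations = annotations, config = config),
    class = "mimir_partition"
  )
}

partition_sizes <- function(p) {
  table(p$assignment$module)
}

#' @export
print.mimir_partition <- function(x, ...) {
  sizes <- partition_sizes(x)
  cat(sprintf(
    "<mimir_partition> %d genes in %d modules (largest %d, %.0f%% non-singlet)\n",
    nrow(x$assignment), length(sizes), max(sizes),
    100 * mean(x$assignment$module %in% names(sizes)[sizes > 1])))
  invisible(x)
}

#' @describeIn module_partition Tidy a partition into a gene/module tibble.
#' @method tidy mimir_partition
#' @param x A `mimir_partition`.
#' @param ... Unused.
#' @export
tidy.mimir_partition <- function(x, ...) {
  out <- x$assignment
  if (!is.null(x$annotations)) {
    out$annotation <- unname(x$annotations[out$module])
  }
  out
}

#' @describeIn module_partition One-row summary of partition structure.
#' @method glance mimir_partition
#' @export
glance.mimir_partition <- function(x, ...) {
  sizes <- partition_sizes(x)
  non_singlet <- names(sizes)[sizes > 1]
  tibble(
    n_genes = nrow(x$assignment),
    n_modules = length(sizes),
    max_module_size = as.integer(max(sizes)),
    non_singlet_fraction = mean(x$assignment$module %in% non_singlet)
  )
}

#' Write a module partition to disk
#'
#' GMT format writes one row per module (`module_id`, annotation, members);
#' TSV writes the long gene-to-module form. Both round-trip through
#' [read_modules()].
#'
#' @param partition A [module_partition()].
#' @param path Output path.
#' @param format `"gmt"` or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
write_modules <- function(partition, path, format = c("gmt", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(partition, "mimir_partition"))
  if (format == "gmt") {
    modules <- split(partition$assignment$gene, partition$assignment$module)
    ann <- partition$annotations %||% setNames(rep(NA_character_,
                                                   length(modules)),
                                               names(modules))
    lines <- map_chr(names(modules), function(m) {
      label <- ann[[m]] %||% NA_character_
      if (is.null(label) || is.na(label) || label == "") label <- "NA"
      paste(c(m, label, modules[[m]]), collapse = "\t")
    })
    writeLines(lines, path)
  } else {
    write.table(partition$assignment, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read a module partition from disk
#'
#' @param path File written by [write_modules()].
#' @param format `"gmt"` or `"tsv"`.
#' @return A [module_partition()].
#' @export
read_modules <- function(path, format = c("gmt", "tsv")) {
  format <- match.arg(format)
  if (format == "gmt") {
    lines <- readLines(path, warn = FALSE)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 3)
    if (length(bad) > 0) {
      mimir_abort(sprintf("GMT line %d of %s has fewer than 3 fields",
                          bad[1], path),
                  class = "mimir_parse_error")
    }
    assignment <- bind_rows(map(parts, function(p) {
      tibble(gene = p[-(1:2)], module = p[1])
    }))
    ann <- setNames(map_chr(parts, 2), map_chr(parts, 1))
    ann[ann == "NA"] <- NA_character_
    module_partition(assignment, annotations = ann)
  } else {
    tab <- read.delim(path, colClasses = "character")
    module_partition(as_tibble(tab))
  }
}
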