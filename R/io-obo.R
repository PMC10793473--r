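#' Ontology DAG
#'
#' Lightweight container for a hierarchically organised annotation vocabulary:
#' terms plus child-to-parent edges labelled `is_a` or `part_of`. These two
#' relations are the ones with defined weights in the Wang semantic
#' similarity measure; other relation types are dropped at parse time.
#'
#' @param terms Tibble with columns `term_id`, `name`.
#' @param edges Tibble with columns `child`, `parent`, `relation`
#'   (`is_a` or `part_of`).
#'
#' @return A `mimir_ontology` object.
#' @export
ontology_dag <- function(terms, edges) {
  terms <- as_tibble(terms)
  edges <- as_tibble(edges)
  stopifnot(all(c("term_id", "name") %in% names(terms)),
            all(c("child", "parent", "relation") %in% names(edges)))
  bad_rel <- setdiff(unique(edges$relation), c("is_a", "part_of"))
  if (length(bad_rel) > 0) {
    mimir_abort(sprintf("unsupported relation(s): %s",
                        paste(bad_rel, collapse = ", ")))
  }
  unknown <- setdiff(c(edges$child, edges$parent), terms$term_id)
  if (length(unknown) > 0) {
    mimir_abort(sprintf("edge references unknown term(s): %s",
                        paste(utils::head(unknown, 5), collapse = ", ")))
  }
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                       vertices = terms$term_id)
    if (!igraph::is_dag(g)) {
      comp <- igraph::components(g, mode = "strong")
      cyc <- names(comp$membership)[
        comp$membership %in% which(comp$csize > 1)]
      mimir_abort(
        sprintf("ontology contains a cycle involving: %s",
                paste(utils::head(cyc, 6), collapse = ", ")),
        class = "mimir_cycle_error"
      )
    }
  }
  # parent adjacency keyed by child, with relation labels
  parents <- split(
    Map(function(p, r) list(parent = p, relation = r),
        edges$parent, edges$relation),
    edges$child
  )
  structure(
    list(terms = terms, edges = edges, parents = parents),
    class = "mimir_ontology"
  )
}

#' @export
print.mimir_ontology <- function(x, ...) {
  roots <- setdiff(x$terms$term_id, x$edges$child)
  cat(sprintf("<mimir_ontology> %d terms, %d edges, %d root(s)\n",
              nrow(x$terms), nrow(x$edges), length(roots)))
  invisible(x)
}

#' Read an OBO 1.2 ontology file
#'
#' Parses `[Term]` stanzas keeping `id`, `name`, `is_a` and
#' `relationship: part_of` lines. Obsolete terms are excluded entirely;
#' relationship types other than `part_of` are skipped with a warning.
#'
#' @param path Path to an OBO file.
#' @return A [ontology_dag()] object.
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) {
    mimir_abort(sprintf("file not found: %s", path),
                class = "mimir_parse_error")
  }
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- grep("^\\[", lines)
  term_starts <- grep("^\\[Term\\]$", lines)
  ids <- character(); names_ <- character()
  edges <- list(); obsolete <- character(); skipped_rel <- character()
  for (s in term_starts) {
    nxt <- stanza_starts[stanza_starts > s]
    end <- if (length(nxt)) min(nxt) - 1 else length(lines)
    block <- lines[(s + 1):end]
    get1 <- function(key) {
      hit <- grep(paste0("^", key, ":"), block, value = TRUE)
      if (length(hit) == 0) return(NA_character_)
      trimws(sub("!.*$", "", sub(paste0("^", key, ":\\s*"), "", hit[1])))
    }
    id <- get1("id")
    if (is.na(id)) next
    if (identical(get1("is_obsolete"), "true")) {
      obsolete <- c(obsolete, id)
      next
    }
    ids <- c(ids, id)
    names_ <- c(names_, get1("name") %||% id)
    isa <- grep("^is_a:", block, value = TRUE)
    for (ln in isa) {
      parent <- trimws(sub("!.*$", "", sub("^is_a:\\s*", "", ln)))
      edges[[length(edges) + 1]] <-
        tibble(child = id, parent = parent, relation = "is_a")
    }
    rels <- grep("^relationship:", block, value = TRUE)
    for (ln in rels) {
      parts <- strsplit(trimws(sub("!.*$", "",
                                   sub("^relationship:\\s*", "", ln))),
                        "\\s+")[[1]]
      if (length(parts) < 2) next
      if (parts[1] == "part_of") {
        edges[[length(edges) + 1]] <-
          tibble(child = id, parent = parts[2], relation = "part_of")
      } else {
        skipped_rel <- c(skipped_rel, parts[1])
      }
    }
  }
  if (length(skipped_rel) > 0) {
    rlang::warn(sprintf("skipped unsupported relationship type(s): %s",
                        paste(unique(skipped_rel), collapse = ", ")))
  }
  edges <- if (length(edges)) bind_rows(edges) else
    tibble(child = character(), parent = character(), relation = character())
  # drop edges touching obsolete terms or pointing outside the term set
  keep <- !(edges$child %in% obsolete) & !(edges$parent %in% obsolete) &
    edges$child %in% ids & edges$parent %in% ids
  edges <- edges[keep, ]
  dag <- ontology_dag(tibble(term_id = ids, name = names_), edges)
  dag$obsolete <- obsolete
  dag
}

#' Read gene-to-term annotations
#'
#' Reads either a two-column TSV (`gene`, `term`) or a GAF 2.x file (gene
#' symbol from column 3, term from column 5; `NOT`-qualified rows dropped).
#'
#' @param path Annotation file path.
#' @param database_name Label for this evidence channel (e.g. `"GO"`).
#' @param format `"tsv"` or `"gaf"`.
#' @param dag Optional [ontology_dag()]; if given, annotations to unknown
#'   terms are dropped with a warning.
#'
#' @return A `mimir_annotations` object: `database_name` plus a tibble
#'   `gene_to_terms` with columns `gene`, `term`.
#' @export
read_annotations <- function(path, database_name,
                             format = c("tsv", "gaf"), dag = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- read.delim(path, header = FALSE, comment.char = "#",
                      col.names = c("gene", "term"),
                      colClasses = "character")
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "!")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    fields <- fields[lengths(fields) >= 5]
    tab <- tibble(
      gene = map_chr(fields, 3),
      term = map_chr(fields, 5),
      qualifier = map_chr(fields, 4)
    )
    tab <- tab[!grepl("NOT", tab$qualifier), c("gene", "term")]
  }
  tab <- distinct(as_tibble(tab))
  if (!is.null(dag)) {
    unknown <- !(tab$term %in% dag$terms$term_id)
    if (any(unknown)) {
      rlang::warn(sprintf("%d annotation(s) to unknown terms dropped",
                          sum(unknown)))
      tab <- tab[!unknown, ]
    }
  }
  annotation_map(tab, database_name)
}

#' Construct an annotation map
#'
#' @param gene_to_terms Tibble with columns `gene`, `term`.
#' @param database_name Channel label.
#' @return A `mimir_annotations` object.
#' @export
annotation_map <- function(gene_to_terms, database_name) {
  gene_to_terms <- distinct(as_tibble(gene_to_terms)[, c("gene", "term")])
  structure(
    list(database_name = database_name, gene_to_terms = gene_to_terms),
    class = "mimir_annotations"
  )
}

#' @export
print.mimir_annotations <- function(x, ...) {
  cat(sprintf("<mimir_annotations> %s: %d genes, %d terms\n",
              x$database_name, length(unique(x$gene_to_terms$gene)),
              length(unique(x$gene_to_terms$term))))
  invisible(x)
}
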