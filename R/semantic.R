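#' Wang graph-based semantic similarity between two ontology terms
#'
#' Each term contributes weight-decayed "semantic values" to its ancestors:
#' the term itself scores 1, and every ancestor scores the maximum over
#' descending paths of the product of edge weights (`is_a` 0.8, `part_of`
#' 0.6 by default). The similarity of two terms is the summed contribution
#' of their common ancestors divided by the total semantic value of both
#' terms.
#'
#' @param dag A [ontology_dag()].
#' @param a,b Term identifiers.
#' @param weights Named edge-relation weights in (0, 1).
#' @return A number in `[0, 1]`; 1 when `a == b`.
#' @export
wang_term_similarity <- function(dag, a, b,
                                 weights = c(is_a = 0.8, part_of = 0.6)) {
  sa <- wang_svalues(dag, a, weights)
  sb <- wang_svalues(dag, b, weights)
  common <- intersect(names(sa), names(sb))
  if (length(common) == 0) return(0)
  sum(sa[common] + sb[common]) / (sum(sa) + sum(sb))
}

# S-values of `term` over its ancestor closure (term itself included):
# S(term) = 1; S(ancestor) = max over child edges of weight * S(child).
wang_svalues <- function(dag, term, weights = c(is_a = 0.8, part_of = 0.6)) {
  stopifnot(inherits(dag, "mimir_ontology"))
  if (!term %in% dag$terms$term_id) {
    mimir_abort(sprintf("unknown term: %s", term),
                class = "mimir_term_error")
  }
  s <- setNames(1, term)
  queue <- term
  while (length(queue) > 0) {
    x <- queue[1]; queue <- queue[-1]
    for (edge in dag$parents[[x]] %||% list()) {
      cand <- weights[[edge$relation]] * s[[x]]
      if (!(edge$parent %in% names(s)) || cand > s[[edge$parent]]) {
        s[edge$parent] <- cand
        queue <- c(queue, edge$parent)
      }
    }
  }
  s
}

#' Cache of pairwise term similarities
#'
#' Memoizes Wang S-values and term-pair similarities over one ontology so
#' gene-level best-match-average scores reuse term computations.
#'
#' @param dag A [ontology_dag()].
#' @param weights Relation weights passed to [wang_term_similarity()].
#' @return A `mimir_term_cache` object with a `$sim(a, b)` function.
#' @export
term_similarity_cache <- function(dag,
                                  weights = c(is_a = 0.8, part_of = 0.6)) {
  sv <- new.env(parent = emptyenv())
  ts <- new.env(parent = emptyenv())
  get_sv <- function(t) {
    if (is.null(sv[[t]])) sv[[t]] <- wang_svalues(dag, t, weights)
    sv[[t]]
  }
  sim <- function(a, b) {
    key <- if (a <= b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
    hit <- ts[[key]]
    if (!is.null(hit)) return(hit)
    sa <- get_sv(a); sb <- get_sv(b)
    common <- intersect(names(sa), names(sb))
    val <- if (length(common) == 0) 0 else
      sum(sa[common] + sb[common]) / (sum(sa) + sum(sb))
    ts[[key]] <- val
    val
  }
  structure(list(dag = dag, weights = weights, sim = sim),
            class = "mimir_term_cache")
}

#' Best-match-average similarity between two genes' term sets
#'
#' Averages, over both directions, each term's best-matching similarity in
#' the other gene's set. An empty set on either side yields `NA`: the pair
#' carries no evidence from this database, which is distinct from evidence
#' of dissimilarity.
#'
#' @param terms_a,terms_b Character vectors of term ids.
#' @param cache A [term_similarity_cache()].
#' @return A number in `[0, 1]`, or `NA` if either set is empty.
#' @export
bma_gene_similarity <- function(terms_a, terms_b, cache) {
  stopifnot(inherits(cache, "mimir_term_cache"))
  terms_a <- unique(terms_a); terms_b <- unique(terms_b)
  if (length(terms_a) == 0 || length(terms_b) == 0) return(NA_real_)
  m <- matrix(0, length(terms_a), length(terms_b))
  for (i in seq_along(terms_a)) {
    for (j in seq_along(terms_b)) {
      m[i, j] <- cache$sim(terms_a[i], terms_b[j])
    }
  }
  (sum(apply(m, 1, max)) + sum(apply(m, 2, max))) /
    (length(terms_a) + length(terms_b))
}

#' Assemble interaction and semantic evidence channels
#'
#' Adds one semantic channel per annotation database (gene-level Wang/BMA
#' similarity) to the interaction channels, over all unordered pairs of
#' `genes`. A pair is present in the output if it carries at least one
#' channel; a gene unannotated in a database contributes a missing (`NA`)
#' channel there, not a zero.
#'
#' @param interaction A [evidence_channels()] object or `NULL`.
#' @param semantic_maps List of `mimir_annotations` objects.
#' @param dags List of [ontology_dag()] objects, one per map (recycled if
#'   length one).
#' @param genes Gene universe; defaults to all genes seen in any source.
#' @param weights Relation weights for the Wang measure.
#' @param prior Prior for the combination (default: the interaction
#'   object's prior, else 0.41).
#'
#' @return A [evidence_channels()] object.
#' @export
assemble_channels <- function(interaction = NULL, semantic_maps = list(),
                              dags = list(), genes = NULL,
                              weights = c(is_a = 0.8, part_of = 0.6),
                              prior = NULL) {
  if (length(semantic_maps) > 0 && length(dags) == 1) {
    dags <- rep(dags, length(semantic_maps))
  }
  stopifnot(length(dags) == length(semantic_maps))
  db_names <- map_chr(semantic_maps, "database_name")
  inter_channels <- if (!is.null(interaction)) {
    channel_names(interaction$pairs)
  } else character()
  if (anyDuplicated(c(db_names, inter_channels))) {
    mimir_abort("channel name collision between sources",
                class = "mimir_channel_error")
  }
  genes <- genes %||% unique(c(
    if (!is.null(interaction)) c(interaction$pairs$gene_a,
                                 interaction$pairs$gene_b),
    unlist(map(semantic_maps, ~ .x$gene_to_terms$gene))
  ))
  genes <- sort(genes)

  inter <- if (!is.null(interaction)) {
    filter(interaction$pairs, .data$gene_a %in% genes,
           .data$gene_b %in% genes)
  } else NULL

  sem_tables <- purrr::map2(semantic_maps, dags, function(amap, dag) {
    cache <- term_similarity_cache(dag, weights)
    g2t <- filter(amap$gene_to_terms, .data$gene %in% genes)
    terms_by_gene <- split(g2t$term, g2t$gene)
    annotated <- sort(names(terms_by_gene))
    if (length(annotated) < 2) {
      return(tibble(gene_a = character(), gene_b = character(),
                    value = numeric()))
    }
    idx <- utils::combn(annotated, 2)
    tibble(
      gene_a = idx[1, ],
      gene_b = idx[2, ],
      value = map2(idx[1, ], idx[2, ], function(ga, gb) {
        bma_gene_similarity(terms_by_gene[[ga]], terms_by_gene[[gb]], cache)
      }) |> unlist()
    )
  })
  names(sem_tables) <- db_names

  out <- inter %||% tibble(gene_a = character(), gene_b = character())
  for (db in db_names) {
    tab <- sem_tables[[db]]
    names(tab)[names(tab) == "value"] <- db
    out <- dplyr::full_join(out, tab, by = c("gene_a", "gene_b"))
  }
  if (nrow(out) == 0) {
    mimir_abort("no evidence found for any gene pair",
                class = "mimir_channel_error")
  }
  evidence_channels(out, prior = prior %||%
                      (if (!is.null(interaction)) interaction$prior
                       else 0.41))
}

#' Combine evidence channels into a functional similarity
#'
#' Each channel score is first corrected for the shared prior,
#' `s_i' = max(0, (S_i - p) / (1 - p))`, then the corrected channels are
#' combined as `S = 1 - (1 - p) * prod_i (1 - s_i')` over the channels
#' present for the pair. Pairs with no evidence get similarity 0.
#'
#' @param ev A [evidence_channels()] object.
#' @param genes Gene universe of the output matrix; defaults to all genes
#'   in `ev`.
#' @return A [similarity_matrix()] of kind `"functional"` (diagonal 1).
#' @export
combine_channels <- function(ev, genes = NULL) {
  stopifnot(inherits(ev, "mimir_channels"))
  p <- ev$prior
  pr <- ev$pairs
  chans <- channel_names(pr)
  if (length(chans) == 0) mimir_abort("no channels to combine")
  prod_term <- rep(1, nrow(pr))
  n_present <- rep(0L, nrow(pr))
  for (ch in chans) {
    x <- pr[[ch]]
    check_range(x, 0, 1, sprintf("channel %s", ch))
    s <- pmax(0, (x - p) / (1 - p))
    miss <- is.na(s)
    s[miss] <- 0
    prod_term <- prod_term * (1 - s)
    n_present <- n_present + !miss
  }
  total <- ifelse(n_present == 0, 0, 1 - (1 - p) * prod_term)
  genes <- genes %||% sort(unique(c(pr$gene_a, pr$gene_b)))
  m <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  keep <- pr$gene_a %in% genes & pr$gene_b %in% genes
  m[cbind(pr$gene_a[keep], pr$gene_b[keep])] <- total[keep]
  m[cbind(pr$gene_b[keep], pr$gene_a[keep])] <- total[keep]
  diag(m) <- 1
  similarity_matrix(m, kind = "functional")
}
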