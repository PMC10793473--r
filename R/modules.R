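#' Fuse expression and functional similarity
#'
#' `and` multiplies the two scores, linking genes only when both modes
#' agree; `or` takes the probabilistic union, linking genes when either
#' mode is high; `plus` is the plain sum (unbounded above).
#'
#' @param s_exp,s_fun [similarity_matrix()] objects over the same genes.
#' @param logic `"and"`, `"or"` or `"plus"`.
#' @return A [similarity_matrix()] of kind `"combined"`.
#' @export
combine_similarities <- function(s_exp, s_fun, logic = c("and", "or",
                                                         "plus")) {
  logic <- match.arg(logic)
  stopifnot(inherits(s_exp, "mimir_similarity"),
            inherits(s_fun, "mimir_similarity"))
  if (!identical(sort(rownames(s_exp)), sort(rownames(s_fun)))) {
    mimir_abort("gene sets of the two similarities differ",
                class = "mimir_gene_error")
  }
  b <- unclass(s_fun)[rownames(s_exp), colnames(s_exp)]
  a <- unclass(s_exp)
  s <- switch(logic,
              and = a * b,
              or = 1 - (1 - a) * (1 - b),
              plus = a + b)
  out <- similarity_matrix(s, kind = "combined")
  attr(out, "logic") <- logic
  out
}

#' Build the weighted gene graph from a similarity matrix
#'
#' Nodes are all genes; undirected edges carry the similarity as weight and
#' are materialized only where the similarity is strictly positive (under
#' the `and` logic, absent functional evidence therefore removes the edge).
#'
#' @param s A [similarity_matrix()].
#' @return An [igraph::graph] with a `weight` edge attribute.
#' @export
build_gene_graph <- function(s) {
  stopifnot(inherits(s, "mimir_similarity"))
  m <- unclass(s)
  diag(m) <- 0
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g
}

#' Cluster the gene graph into modules
#'
#' Leiden optimizes the RB-configuration modularity at the given
#' resolution; Louvain and Infomap are provided for comparison. Isolated
#' genes become singleton modules. The partition is deterministic given
#' `seed`.
#'
#' @param g An igraph graph (from [build_gene_graph()]) or a
#'   [similarity_matrix()].
#' @param algorithm `"leiden"`, `"louvain"` or `"infomap"`.
#' @param resolution Resolution parameter (default 4; ignored by infomap).
#' @param seed Integer seed (default 0).
#' @param n_iterations Leiden refinement iterations (default 10).
#' @return A [module_partition()] with config provenance.
#' @export
cluster_graph <- function(g, algorithm = c("leiden", "louvain", "infomap"),
                          resolution = 4, seed = 0, n_iterations = 10) {
  algorithm <- match.arg(algorithm)
  if (inherits(g, "mimir_similarity")) g <- build_gene_graph(g)
  stopifnot(inherits(g, "igraph"))
  if (igraph::vcount(g) == 0) mimir_abort("empty graph")
  w <- igraph::E(g)$weight
  comm <- withr::with_seed(seed, switch(
    algorithm,
    leiden = igraph::cluster_leiden(
      g, objective_function = "modularity", weights = w,
      resolution = resolution, n_iterations = n_iterations),
    louvain = igraph::cluster_louvain(g, weights = w,
                                      resolution = resolution),
    infomap = igraph::cluster_infomap(g, e.weights = w)
  ))
  membership <- igraph::membership(comm)
  module_partition(
    tibble(gene = names(membership),
           module = paste0("M", as.integer(membership))),
    config = list(algorithm = algorithm, resolution = resolution,
                  seed = seed)
  )
}

#' Evaluate a module partition
#'
#' Computes structural metrics, the selection-criteria flags (>85% of genes
#' in non-singlet modules, fewer than 150 modules, largest module below 150
#' genes), and -- when a reference partition is supplied -- the adjusted
#' mutual information against it, restricted to the shared genes.
#'
#' @param p A [module_partition()].
#' @param reference Optional reference: a `mimir_partition` or a data frame
#'   with `gene`, `module`.
#' @param non_singlet_min,max_modules,max_size Criteria thresholds.
#' @return A one-row tibble: `ami`, `n_genes_compared`, `n_modules`,
#'   `non_singlet_fraction`, `max_module_size`, per-criterion flags and
#'   `eligible`.
#' @export
evaluate_partition <- function(p, reference = NULL,
                               non_singlet_min = 0.85,
                               max_modules = 150, max_size = 150) {
  stopifnot(inherits(p, "mimir_partition"))
  g <- glance(p)
  ami <- NA_real_
  n_shared <- NA_integer_
  if (!is.null(reference)) {
    ref <- if (inherits(reference, "mimir_partition")) {
      reference$assignment
    } else {
      as_tibble(reference)[, c("gene", "module")]
    }
    shared <- intersect(p$assignment$gene, ref$gene)
    if (length(shared) == 0) {
      mimir_abort("no genes shared with the reference partition",
                  class = "mimir_gene_error")
    }
    pa <- p$assignment$module[match(shared, p$assignment$gene)]
    pb <- ref$module[match(shared, ref$gene)]
    ami <- adjusted_mutual_information(pa, pb)
    n_shared <- length(shared)
  }
  tibble(
    ami = ami,
    n_genes_compared = n_shared,
    n_modules = g$n_modules,
    non_singlet_fraction = g$non_singlet_fraction,
    max_module_size = g$max_module_size,
    crit_non_singlet = g$non_singlet_fraction > non_singlet_min,
    crit_n_modules = g$n_modules < max_modules,
    crit_max_size = g$max_module_size < max_size
  ) |>
    mutate(eligible = .data$crit_non_singlet & .data$crit_n_modules &
             .data$crit_max_size)
}

#' Run a grid of clustering configurations and rank them
#'
#' Each configuration names a distance metric, a similarity-fusion logic
#' (including the single-source baselines `expression` and `functional`),
#' a clustering algorithm and a resolution. Every configuration is run
#' end-to-end from the pseudotime profiles and the functional similarity;
#' configurations failing any structural criterion are marked ineligible;
#' eligible ones are ranked by AMI against the reference (ties broken by
#' fewer modules).
#'
#' @param profile A `mimir_profile` (for the expression side).
#' @param s_fun A functional [similarity_matrix()].
#' @param reference Reference partition for AMI.
#' @param configs Tibble with columns `metric`, `logic`, `algorithm`,
#'   `resolution`; defaults to a small standard grid.
#' @param cap Distance scaling cap (default 0.95).
#' @param seed Seed forwarded to the clustering.
#' @inheritParams evaluate_partition
#' @return The `configs` tibble augmented with evaluation columns, ranked
#'   with eligible configurations first.
#' @export
grid_select <- function(profile, s_fun, reference = NULL,
                        configs = NULL, cap = 0.95, seed = 0,
                        non_singlet_min = 0.85, max_modules = 150,
                        max_size = 150) {
  configs <- configs %||% tidyr::expand_grid(
    metric = "jsd",
    logic = c("and", "or", "plus", "expression", "functional"),
    algorithm = "leiden",
    resolution = 4
  )
  configs <- as_tibble(configs)
  stopifnot(nrow(configs) >= 1)
  rows <- pmap(configs, function(metric, logic, algorithm, resolution,
                                 ...) {
    s_exp <- expression_similarity(profile_distance(profile, metric),
                                   cap = cap)
    s <- switch(logic,
                expression = s_exp,
                functional = s_fun,
                combine_similarities(s_exp, s_fun, logic))
    part <- cluster_graph(s, algorithm = algorithm,
                          resolution = resolution, seed = seed)
    ev <- evaluate_partition(part, reference,
                             non_singlet_min = non_singlet_min,
                             max_modules = max_modules,
                             max_size = max_size)
    ev$partition <- list(part)
    ev
  })
  out <- dplyr::bind_cols(configs, bind_rows(rows))
  arrange(out, dplyr::desc(.data$eligible), dplyr::desc(.data$ami),
          .data$n_modules)
}

#' Apply curated edits to a partition
#'
#' Supports out-of-band manual curation: a table of `(gene, new_module)`
#' reassignments is applied and the partition re-emitted. No curation
#' decisions are made by the package itself.
#'
#' @param partition A [module_partition()].
#' @param edits Data frame with columns `gene`, `new_module`.
#' @return An edited [module_partition()].
#' @export
apply_module_edits <- function(partition, edits) {
  stopifnot(inherits(partition, "mimir_partition"))
  edits <- as_tibble(edits)
  stopifnot(all(c("gene", "new_module") %in% names(edits)))
  unknown <- setdiff(edits$gene, partition$assignment$gene)
  if (length(unknown) > 0) {
    rlang::warn(sprintf("edit(s) for unknown gene(s) ignored: %s",
                        paste(utils::head(unknown, 5), collapse = ", ")))
    edits <- filter(edits, !.data$gene %in% unknown)
  }
  a <- partition$assignment
  i <- match(edits$gene, a$gene)
  a$module[i] <- as.character(edits$new_module)
  module_partition(a, annotations = partition$annotations,
                   config = c(partition$config, list(edited = TRUE)))
}
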