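sim_mat <- function(m, kind = "expression") {
  similarity_matrix(m, kind = kind)
}

test_that("similarity fusion follows the and/or/plus arithmetic", {
  g <- c("g1", "g2")
  a <- sim_mat(matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(g, g)))
  b <- sim_mat(matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(g, g)),
               "functional")
  expect_equal(combine_similarities(a, b, "and")["g1", "g2"], 0.40)
  expect_equal(combine_similarities(a, b, "or")["g1", "g2"], 0.90)
  expect_equal(combine_similarities(a, b, "plus")["g1", "g2"], 1.30)
  # commutative; and <= min <= or; bounded
  for (logic in c("and", "or")) {
    ab <- combine_similarities(a, b, logic)
    ba <- combine_similarities(b, a, logic)
    expect_equal(unclass(ab), unclass(ba), ignore_attr = TRUE)
    expect_true(all(ab >= 0 & ab <= 1))
  }
  expect_lte(combine_similarities(a, b, "and")["g1", "g2"], 0.5)
  expect_gte(combine_similarities(a, b, "or")["g1", "g2"], 0.8)
  # mismatched gene universes are refused
  g3 <- c("g1", "g3")
  cmat <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(g3, g3))
  expect_error(combine_similarities(a, sim_mat(cmat, "functional"), "and"),
               class = "mimir_gene_error")
})

test_that("disconnected cliques cluster into their components, deterministically", {
  g <- paste0("g", 1:10)
  m <- matrix(0, 10, 10, dimnames = list(g, g))
  m[1:5, 1:5] <- 1
  m[6:10, 6:10] <- 1
  s <- sim_mat(m, "combined")
  p1 <- cluster_graph(s, "leiden", resolution = 1, seed = 0)
  expect_equal(glance(p1)$n_modules, 2)
  mod <- setNames(p1$assignment$module, p1$assignment$gene)
  expect_length(unique(mod[g[1:5]]), 1)
  expect_length(unique(mod[g[6:10]]), 1)
  expect_false(mod[["g1"]] == mod[["g6"]])
  # same graph, same seed: identical partitions
  p2 <- cluster_graph(s, "leiden", resolution = 1, seed = 0)
  expect_identical(p1$assignment, p2$assignment)
  # no module ever spans two graph components, at any resolution
  for (res in c(0.5, 2, 4)) {
    pr <- cluster_graph(s, "leiden", resolution = res, seed = 1)
    mm <- setNames(pr$assignment$module, pr$assignment$gene)
    expect_length(intersect(unique(mm[g[1:5]]), unique(mm[g[6:10]])), 0)
  }
})

test_that("a planted partition is recovered almost perfectly", {
  set.seed(11)
  blocks <- rep(paste0("B", 1:10), each = 20)
  g <- paste0("n", seq_along(blocks))
  m <- matrix(0, 200, 200, dimnames = list(g, g))
  same <- outer(blocks, blocks, "==")
  edge <- matrix(runif(200 * 200), 200) < ifelse(same, 0.9, 0.02)
  edge[lower.tri(edge)] <- t(edge)[lower.tri(edge)]
  m[edge] <- 1
  diag(m) <- 1
  part <- cluster_graph(sim_mat(m, "combined"), "leiden",
                        resolution = 1, seed = 0)
  truth <- tibble::tibble(gene = g, module = blocks)
  expect_gte(evaluate_partition(part, truth)$ami, 0.95)
})

test_that("louvain and infomap also partition the clique graph", {
  g <- paste0("g", 1:10)
  m <- matrix(0, 10, 10, dimnames = list(g, g))
  m[1:5, 1:5] <- 1; m[6:10, 6:10] <- 1
  for (alg in c("louvain", "infomap")) {
    p <- cluster_graph(sim_mat(m, "combined"), alg, resolution = 1,
                       seed = 0)
    expect_equal(glance(p)$n_modules, 2)
  }
})

test_that("adjusted mutual information behaves as a chance-corrected score", {
  a <- rep(1:4, each = 5)
  expect_equal(adjusted_mutual_information(a, a), 1)
  # relabeling leaves the score unchanged
  relab <- c("d", "c", "b", "a")[a]
  expect_equal(adjusted_mutual_information(a, relab), 1)
  # an uninformative one-cluster partition scores ~0 against structure
  expect_lt(abs(adjusted_mutual_information(a, rep(1, 20))), 1e-9)
  # two single-cluster partitions agree trivially
  expect_equal(adjusted_mutual_information(rep(1, 5), rep(2, 5)), 1)
})

test_that("AMI matches an independent reference implementation", {
  # expected values frozen from scikit-learn's
  # adjusted_mutual_info_score (arithmetic averaging) on the same labels
  cases <- list(
    list(a = c(1, 1, 2, 2, 3, 3), b = c(1, 1, 2, 3, 3, 3),
         e = 0.5023607027202738),
    list(a = c(1, 1, 1, 2, 2, 3), b = c(3, 3, 1, 1, 2, 2),
         e = 0.08372678378671243),
    list(a = c(1, 2, 1, 2, 1, 2, 1, 2), b = c(1, 1, 2, 2, 1, 1, 2, 2),
         e = -0.12974472642510582),
    list(a = c(1, 1, 1, 1, 2, 2, 2, 3, 3, 4),
         b = c(1, 1, 2, 2, 2, 2, 3, 3, 4, 4),
         e = 0.20820309950195168)
  )
  for (cs in cases) {
    expect_equal(adjusted_mutual_information(cs$a, cs$b), cs$e,
                 tolerance = 1e-10)
  }
})

test_that("partition evaluation flags the selection criteria", {
  # 40% of genes in singletons: ineligible whatever the AMI
  genes <- paste0("g", 1:10)
  p <- module_partition(tibble::tibble(
    gene = genes,
    module = c(rep("M1", 6), paste0("S", 1:4))))
  ev <- evaluate_partition(p, reference = tibble::tibble(
    gene = genes, module = c(rep("M1", 6), paste0("S", 1:4))))
  expect_equal(ev$ami, 1)
  expect_false(ev$crit_non_singlet)
  expect_false(ev$eligible)
  expect_error(
    evaluate_partition(p, tibble::tibble(gene = "zz", module = "M")),
    class = "mimir_gene_error")
})

test_that("grid selection ranks eligible configurations by AMI", {
  set.seed(5)
  v <- matrix(rexp(40 * 6), 40, dimnames = list(paste0("g", 1:40), NULL))
  blocks <- rep(c("A", "B"), each = 20)
  v[blocks == "A", 1:3] <- v[blocks == "A", 1:3] + 5
  v[blocks == "B", 4:6] <- v[blocks == "B", 4:6] + 5
  prof <- make_profile(v)
  fun <- matrix(0.0, 40, 40, dimnames = dimnames(v)[c(1, 1)])
  fun[outer(blocks, blocks, "==")] <- 0.9
  diag(fun) <- 1
  s_fun <- sim_mat(fun, "functional")
  ref <- tibble::tibble(gene = rownames(v), module = blocks)
  res <- grid_select(prof, s_fun, reference = ref,
                     configs = tibble::tibble(
                       metric = "jsd", logic = "and",
                       algorithm = "leiden", resolution = 1))
  expect_equal(nrow(res), 1)
  expect_gte(res$ami, 0.9)
  expect_s3_class(res$partition[[1]], "mimir_partition")
})

test_that("curated edits reassign genes without touching the rest", {
  p <- module_partition(tibble::tibble(gene = paste0("g", 1:4),
                                       module = c("M1", "M1", "M2", "M2")))
  edited <- apply_module_edits(
    p, tibble::tibble(gene = "g3", new_module = "M1"))
  expect_equal(edited$assignment$module,
               c("M1", "M1", "M1", "M2"))
  expect_warning(
    apply_module_edits(p, tibble::tibble(gene = "zz", new_module = "M9")),
    "unknown")
})
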