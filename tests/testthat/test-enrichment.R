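test_that("uniformly filled pseudotime yields the full set of equal segments", {
  # 100 cells per initial bin, all above the minimum: no fusion
  pt <- unlist(lapply(seq_len(15), function(b) {
    seq((b - 1) / 15 + 1e-4, b / 15 - 1e-4, length.out = 100)
  }))
  pt <- setNames(pt, paste0("c", seq_along(pt)))
  segs <- segment_pseudotime(pt, n_segments = 15, min_cells = 60)
  expect_equal(nrow(segs), 15)
  expect_equal(segs$n_cells, rep(100L, 15))
})

test_that("consecutive under-filled segments fuse as evenly as possible", {
  # 15 equal-width bins; bins 7-9 hold 20 cells each, the rest 60
  counts_per_bin <- c(rep(60, 6), rep(20, 3), rep(60, 6))
  pt <- unlist(lapply(seq_len(15), function(b) {
    seq((b - 1) / 15 + 1e-4, b / 15 - 1e-4,
        length.out = counts_per_bin[b])
  }))
  segs <- segment_pseudotime(setNames(pt, paste0("c", seq_along(pt))))
  # expected: the three 20-cell bins fuse into one 60-cell segment
  expect_equal(nrow(segs), 13)
  expect_equal(sort(segs$n_cells), sort(c(rep(60L, 6), 60L, rep(60L, 6))))
  expect_true(all(segs$n_cells >= 60))
})

test_that("a trajectory below the cell minimum becomes a single segment", {
  pt <- setNames(runif(40), paste0("c", 1:40))
  segs <- segment_pseudotime(pt)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_cells, 40L)
})

test_that("segmentation invariants hold across random cell configurations", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(80:900, 1)
    pt <- setNames(rbeta(n, sample(1:3, 1), sample(1:3, 1)),
                   paste0("c", seq_len(n)))
    segs <- segment_pseudotime(pt, n_segments = 15, min_cells = 60)
    # disjoint and jointly covering
    all_cells <- unlist(segs$cells)
    expect_equal(sort(all_cells), sort(names(pt)))
    expect_false(anyDuplicated(all_cells) > 0)
    # ordered intervals; every segment at least min_cells (or one segment)
    expect_true(all(diff(segs$t_lo) > 0))
    if (nrow(segs) > 1) expect_true(all(segs$n_cells >= 60))
  }
})

test_that("average precision matches hand-enumerated rankings and tie rule", {
  expect_equal(aucpr(c(3, 2, 1, 0), c(1, 1, 0, 0)), 1)
  expect_equal(aucpr(c(3, 2, 1, 0), c(1, 0, 1, 0)), (1 / 2) * (1 + 2 / 3))
  # fully tied scores collapse to the uninformative baseline: prevalence
  expect_equal(aucpr(rep(1, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  expect_error(aucpr(1:4, c(1, 1, 1, 1)), class = "mimir_label_error")
})

test_that("average precision agrees with the brute-force integrator, ties included", {
  set.seed(42)
  for (k in 1:30) {
    n <- sample(3:12, 1)
    scores <- sample(1:5, n, replace = TRUE)  # heavy ties
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (sum(labels) %in% c(0, n)) next
    expect_equal(aucpr(scores, labels), ap_oracle(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("permuted labels concentrate average precision at prevalence", {
  set.seed(7)
  scores <- rnorm(300)
  labels <- c(rep(1, 100), rep(0, 200))
  perms <- replicate(1000, aucpr(scores, sample(labels)))
  expect_lt(abs(mean(perms) - 1 / 3), 0.02)
})

test_that("marker criteria gate on detection, AUCPR fold and logFC", {
  n_g <- 40; n_b <- 60
  m <- matrix(0, 3, n_g + n_b,
              dimnames = list(c("perfect", "rare", "weak"),
                              paste0("c", seq_len(n_g + n_b))))
  grp <- paste0("c", 1:n_g); bg <- paste0("c", (n_g + 1):(n_g + n_b))
  m["perfect", grp] <- 40                       # on in every group cell
  m["rare", grp[1:2]] <- 50                     # detected in 5% only
  m["weak", ] <- c(rep(8, n_g), rep(7, n_b))    # high AUCPR, tiny logFC
  # housekeeping filler keeps every cell at the same total so
  # normalization is the identity scaling
  hk <- 200 - colSums(m)
  cm <- make_counts(rbind(m, hk = hk))
  nm <- normalize_counts(cm, scale_total = 200)
  calls <- call_markers(nm, grp, bg, mode = "trajectory")

  perfect <- calls[calls$gene == "perfect", ]
  expect_equal(perfect$detect_frac, 1)
  expect_true(perfect$passes)
  expect_false(calls$passes[calls$gene == "rare"])     # detect_frac 0.05
  expect_false(calls$passes[calls$gene == "weak"])     # logfc below 0.3
  expect_gt(calls$aucpr[calls$gene == "weak"], 0.9)
})

test_that("enrichment rules: last segment, two segments, any stage", {
  mk <- function(gene, window, passes) {
    tibble::tibble(gene = gene, window = window, detect_frac = 1,
                   aucpr = 1, aucpr_ratio = 10, logfc = 1, passes = passes)
  }
  calls <- dplyr::bind_rows(
    mk("last_only", 9, TRUE),
    mk("two_mid", 2, TRUE), mk("two_mid", 5, TRUE),
    mk("first_only", 1, TRUE),
    lapply(1:9, function(w) mk(c("last_only", "two_mid", "first_only"),
                               w, FALSE))
  )
  enr <- define_enriched(calls, mode = "trajectory", cell_type = "noto")
  expect_setequal(enr$genes, c("last_only", "two_mid"))
  expect_false("first_only" %in% enr$genes)
  rules <- setNames(enr$provenance$rule, enr$provenance$gene)
  expect_match(rules[["last_only"]], "last-segment")
  expect_match(rules[["two_mid"]], ">=2-segments")

  stage <- define_enriched(mk("any1", "shield", TRUE), mode = "stage",
                           cell_type = "noto")
  expect_equal(stage$genes, "any1")
})

test_that("enriched-set union merges genes and refuses cell-type mixups", {
  mk_set <- function(genes, ct) {
    structure(list(cell_type = ct, genes = genes,
                   provenance = tibble::tibble(
                     gene = genes, rule = "last-segment",
                     n_windows = 1L)),
              class = "mimir_enriched")
  }
  u <- union_enriched(mk_set(c("g1", "g2"), "noto"),
                      mk_set(c("g2", "g3"), "noto"))
  expect_setequal(u$genes, c("g1", "g2", "g3"))
  empty <- structure(list(cell_type = "noto", genes = character(),
                          provenance = tibble::tibble(
                            gene = character(), rule = character(),
                            n_windows = integer())),
                     class = "mimir_enriched")
  expect_setequal(union_enriched(empty, mk_set("g1", "noto"))$genes, "g1")
  expect_error(union_enriched(mk_set("g1", "noto"), mk_set("g1", "hg")),
               class = "mimir_celltype_error")
})

test_that("Fisher term enrichment equals the exact hypergeometric tail", {
  # 100-gene background, term T carried by 10 genes, 5 of them in the set
  background <- paste0("g", 1:100)
  genes <- paste0("g", 1:10)
  carriers <- paste0("g", c(1:5, 51:55))
  ann <- annotation_map(
    tibble::tibble(gene = c(carriers, "g60"), term = c(rep("T", 10), "U")),
    "toy")
  res <- fisher_enrichment(genes, ann, background)
  pT <- res$p_value[res$term == "T"]
  expect_equal(pT, hyper_tail_oracle(5, 10, 100, 10), tolerance = 1e-12)
  expect_equal(pT, 6.7e-4, tolerance = 0.01)
  # cross-check against the standard exact test
  ft <- stats::fisher.test(matrix(c(5, 5, 5, 85), 2),
                           alternative = "greater")
  expect_equal(pT, ft$p.value, tolerance = 1e-10)
  # genes outside the background are a contract violation
  expect_error(fisher_enrichment(c("g1", "zzz"), ann, background),
               class = "mimir_background_error")
})

test_that("extreme and absent terms behave at the boundaries", {
  background <- paste0("g", 1:50)
  genes <- paste0("g", 1:10)
  ann <- annotation_map(
    tibble::tibble(gene = genes, term = "ALL"), "toy")
  res <- fisher_enrichment(genes, ann, background)
  # term annotating exactly the gene set: minimal possible p
  expect_equal(res$p_value[res$term == "ALL"],
               1 / choose(50, 10), tolerance = 1e-10)
  # a term with no background carrier never appears
  expect_false("absent" %in% res$term)
})
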