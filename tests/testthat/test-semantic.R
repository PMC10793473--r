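test_that("Wang similarity reproduces hand-propagated toy values", {
  dag <- toy_dag()
  expect_equal(wang_term_similarity(dag, "A", "A"), 1)
  expect_equal(wang_term_similarity(dag, "A", "B"),
               (0.8 + 0.8) / (1.8 + 1.8))
  expect_equal(wang_term_similarity(dag, "A", "B"),
               wang_term_similarity(dag, "B", "A"))
  expect_error(wang_term_similarity(dag, "A", "nope"),
               class = "mimir_term_error")
})

test_that("terms under disjoint roots share nothing", {
  dag <- ontology_dag(
    tibble::tibble(term_id = c("R1", "R2", "A", "B"),
                   name = c("R1", "R2", "A", "B")),
    tibble::tibble(child = c("A", "B"), parent = c("R1", "R2"),
                   relation = "is_a")
  )
  expect_equal(wang_term_similarity(dag, "A", "B"), 0)
})

test_that("Wang agrees with a path-enumeration oracle on random small DAGs", {
  for (seed in 1:12) {
    for (n_terms in 3:6) {
      rd <- random_dag(n_terms, seed * 100 + n_terms)
      dag <- ontology_dag(
        tibble::tibble(term_id = rd$terms, name = rd$terms),
        tibble::as_tibble(rd$edges)
      )
      pairs <- utils::combn(rd$terms, 2)
      for (k in seq_len(ncol(pairs))) {
        a <- pairs[1, k]; b <- pairs[2, k]
        expect_equal(wang_term_similarity(dag, a, b),
                     wang_oracle(rd$edges, a, b),
                     tolerance = 1e-12,
                     info = sprintf("seed %d n %d pair %s-%s",
                                    seed, n_terms, a, b))
      }
    }
  }
})

test_that("best-match-average combines term similarities and flags no-evidence", {
  # a hand-held cache fixes sim(t1,t2) = 0.4 to exercise the formula alone
  cache <- structure(
    list(sim = function(a, b) if (a == b) 1 else 0.4),
    class = "mimir_term_cache")
  expect_equal(bma_gene_similarity("t1", "t1", cache), 1)
  expect_equal(bma_gene_similarity("t1", c("t1", "t2"), cache),
               (1 + 1 + 0.4) / 3)   # = 0.8
  expect_equal(bma_gene_similarity(c("t1", "t2"), "t1", cache),
               bma_gene_similarity("t1", c("t1", "t2"), cache))
  expect_true(is.na(bma_gene_similarity(character(), "t1", cache)))
  # bounded by the best pairwise term similarity
  real <- term_similarity_cache(toy_dag())
  expect_lte(bma_gene_similarity(c("A", "B"), c("A", "B"), real), 1)
})

test_that("the term cache returns the same values as fresh computation", {
  dag <- toy_dag()
  cache <- term_similarity_cache(dag)
  for (a in c("R", "A", "B")) for (b in c("R", "A", "B")) {
    expect_equal(cache$sim(a, b), wang_term_similarity(dag, a, b))
    expect_equal(cache$sim(a, b), cache$sim(a, b))  # memoized path
  }
})

test_that("channel combination hits its closed-form fixed points", {
  mk <- function(...) {
    evidence_channels(tibble::tibble(gene_a = "x", gene_b = "y", ...))
  }
  # every channel at the prior: the prior is returned unchanged
  expect_equal(combine_channels(mk(c1 = 0.41, c2 = 0.41))["x", "y"], 0.41)
  # one certain channel absorbs everything
  expect_equal(combine_channels(mk(c1 = 1, c2 = 0.2))["x", "y"], 1)
  # the worked two-channel example, against the direct-formula oracle
  s <- combine_channels(mk(c1 = 0.7, c2 = 0.5))["x", "y"]
  expect_equal(s, combine_oracle(c(0.7, 0.5)), tolerance = 1e-12)
  expect_equal(s, 0.7458, tolerance = 1e-4)
})

test_that("channel combination is monotone, order-free, and ignores sub-prior noise", {
  base <- combine_channels(evidence_channels(
    tibble::tibble(gene_a = "x", gene_b = "y", c1 = 0.7, c2 = 0.5)))["x", "y"]
  # adding a channel at or below the prior changes nothing
  with_noise <- combine_channels(evidence_channels(
    tibble::tibble(gene_a = "x", gene_b = "y", c1 = 0.7, c2 = 0.5,
                   c3 = 0.3)))["x", "y"]
  expect_equal(with_noise, base)
  # permutation invariance over channels
  perm <- combine_channels(evidence_channels(
    tibble::tibble(gene_a = "x", gene_b = "y", c1 = 0.5, c2 = 0.7)))["x", "y"]
  expect_equal(perm, base)
  # monotone non-decreasing in every channel
  set.seed(9)
  for (k in 1:20) {
    ch <- runif(3)
    lo <- combine_oracle(ch)
    hi <- combine_oracle(pmin(ch + runif(3, 0, 0.2), 1))
    expect_gte(hi, lo - 1e-12)
  }
  # a pair with no evidence at all gets similarity zero, not the prior
  ev <- evidence_channels(tibble::tibble(gene_a = "x", gene_b = "y",
                                         c1 = NA_real_))
  expect_equal(combine_channels(ev, genes = c("x", "y", "z"))["x", "z"], 0)
  expect_equal(combine_channels(ev)["x", "y"], 0)
})

test_that("assembled channels carry one semantic channel per database", {
  dag <- toy_dag()
  annA <- annotation_map(tibble::tibble(gene = c("g1", "g2"),
                                        term = c("A", "A")), "dbA")
  annB <- annotation_map(tibble::tibble(gene = c("g1", "g3"),
                                        term = c("A", "B")), "dbB")
  inter <- evidence_channels(tibble::tibble(gene_a = "g1", gene_b = "g4",
                                            experiments = 0.9))
  ev <- assemble_channels(inter, list(annA, annB), list(dag),
                          genes = paste0("g", 1:5))
  expect_setequal(setdiff(names(ev$pairs), c("gene_a", "gene_b")),
                  c("experiments", "dbA", "dbB"))
  p12 <- ev$pairs[ev$pairs$gene_a == "g1" & ev$pairs$gene_b == "g2", ]
  expect_equal(p12$dbA, 1)                  # identical annotation
  expect_true(is.na(p12$dbB))               # g2 unannotated in dbB
  p13 <- ev$pairs[ev$pairs$gene_a == "g1" & ev$pairs$gene_b == "g3", ]
  expect_equal(p13$dbB, (0.8 + 0.8) / (1.8 + 1.8))
  # g5 carries no evidence anywhere: absent entirely
  expect_false(any(ev$pairs$gene_a == "g5" | ev$pairs$gene_b == "g5"))
  # channel name collisions are refused
  annX <- annotation_map(tibble::tibble(gene = "g1", term = "A"),
                         "experiments")
  expect_error(assemble_channels(inter, list(annX), list(dag)),
               class = "mimir_channel_error")
})
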