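make_design <- function(n = 200, seed = 1, batch = TRUE) {
  # direct construction of a design for unit tests
  set.seed(seed)
  tf <- pmax(0, rnorm(n, 3, 1))
  X <- cbind(tf1 = tf, injection = rep(c(0, 1), length.out = n),
             batch = if (batch) rep(c(0, 1), each = n / 2) else rep(0, n))
  rownames(X) <- paste0("c", seq_len(n))
  structure(list(X = X, tfs = "tf1", cell_ids = rownames(X)),
            class = "mimir_design")
}

test_that("the Andrew's wave weights redescend and are unit at zero", {
  a <- 1.339
  expect_equal(psi_andrew(0), 1)
  expect_equal(psi_andrew(1e-12), 1, tolerance = 1e-6)
  # beyond a*pi the influence vanishes entirely
  expect_equal(psi_andrew(a * pi + 0.01), 0)
  expect_equal(psi_andrew(-a * pi - 5), 0)
  # symmetric weights
  u <- seq(0.1, 4, by = 0.3)
  expect_equal(psi_andrew(u), psi_andrew(-u))
  # derivative matches the influence function's slope
  expect_equal(psi_andrew(1, deriv = 1), cos(1 / a))
})

test_that("the design zeroes knocked-out TFs and codes injection 0/1/1.5", {
  counts <- matrix(
    rpois(4 * 90, lambda = 20), 4,
    dimnames = list(c("tfA", "tfB", "g1", "g2"), paste0("c", 1:90)))
  meta <- tibble::tibble(
    cell_id = paste0("c", 1:90),
    cell_type = "ct",
    condition = rep(c("control", "ko_A", "ko_AB"), each = 30),
    batch = rep(c("harvard", "basel", "basel"), each = 30))
  cm <- count_matrix(counts, meta)
  nm <- normalize_counts(cm)
  ko <- list(control = character(), ko_A = "tfA", ko_AB = c("tfA", "tfB"))
  d <- build_design(nm, c("tfA", "tfB"), ko)
  expect_equal(unname(d$X[1:30, "injection"]), rep(0, 30))
  expect_equal(unname(d$X[31:60, "injection"]), rep(1, 30))
  expect_equal(unname(d$X[61:90, "injection"]), rep(1.5, 30))
  expect_true(all(d$X[31:90, "tfA"] == 0))
  expect_true(all(d$X[61:90, "tfB"] == 0))
  expect_true(all(d$X[1:30, "tfA"] > 0))
  expect_setequal(unique(d$X[, "batch"]), c(0, 1))
  expect_error(build_design(nm, c("tfA", "tfB"), ko[-1]),
               class = "mimir_condition_error")
  expect_error(build_design(nm, "tfA", list(control = "tfZ")),
               class = "mimir_condition_error")
})

test_that("a noiseless linear response is recovered exactly", {
  d <- make_design()
  y <- 2 + 0.5 * d$X[, "tf1"]
  fit <- fit_robust(y, d, "g")
  expect_equal(fit$estimate[fit$term == "tf1"], 0.5, tolerance = 1e-6)
  expect_equal(fit$r2[1], 1, tolerance = 1e-9)
  expect_true(all(fit$converged))
})

test_that("constant responses are degenerate: r2 zero, nothing callable", {
  d <- make_design()
  fit <- fit_robust(rep(3, nrow(d$X)), d, "gc")
  expect_equal(fit$r2[1], 0)
  expect_equal(nrow(call_targets(fit)), 0)
})

test_that("rank-deficient columns are dropped with a warning", {
  d <- make_design(batch = FALSE)  # batch column all zero
  y <- 1 + 0.3 * d$X[, "tf1"] + rnorm(nrow(d$X), 0, 0.05)
  expect_warning(fit <- fit_robust(y, d, "g"), "batch")
  expect_true(is.na(fit$estimate[fit$term == "batch"]))
  expect_equal(fit$estimate[fit$term == "tf1"], 0.3, tolerance = 0.05)
})

test_that("gross outliers barely move the robust fit but bias least squares", {
  d <- make_design(n = 400, seed = 3)
  set.seed(33)
  errs <- t(replicate(10, {
    y <- 2 + 0.5 * d$X[, "tf1"] + rnorm(400, 0, 0.1)
    out_idx <- sample(400, 20)            # 5% gross outliers
    y[out_idx] <- y[out_idx] + 10
    fit <- fit_robust(y, d, "g")
    c(rob = abs(fit$estimate[fit$term == "tf1"] - 0.5),
      ols = abs(unname(coef(lm(y ~ d$X))["d$Xtf1"]) - 0.5))
  }))
  expect_lt(mean(errs[, "rob"]), 0.05)
  expect_gt(mean(errs[, "ols"]), mean(errs[, "rob"]))
})

test_that("target calls follow the three-way threshold rule", {
  mk_fit <- function(gene, r2, coef, p) {
    tibble::tibble(gene = gene, term = "tf1", estimate = coef,
                   std_error = 0.01, p_value = p, r2 = r2,
                   converged = TRUE, cell_type = "ct")
  }
  fits <- dplyr::bind_rows(
    mk_fit("hit", 0.2, 0.1, 1e-12),
    mk_fit("low_r2", 0.10, 0.3, 1e-20),
    mk_fit("repressed", 0.3, -0.2, 1e-15),
    mk_fit("weak_p", 0.3, 0.2, 1e-6)
  )
  calls <- call_targets(fits)
  expect_equal(calls$direction[calls$gene == "hit"], "positive")
  expect_false("low_r2" %in% calls$gene)
  expect_false("weak_p" %in% calls$gene)
  expect_equal(calls$direction[calls$gene == "repressed"], "negative")
})

test_that("induced targets require agreement across cell types", {
  mk_call <- function(gene, ct) {
    tibble::tibble(tf = "tf1", gene = gene, cell_type = ct,
                   direction = "positive", estimate = 0.3,
                   p_value = 1e-12, r2 = 0.3)
  }
  calls <- dplyr::bind_rows(
    mk_call("three_ct", "nc"), mk_call("three_ct", "hg"),
    mk_call("three_ct", "skin"),
    mk_call("one_ct", "nc")
  )
  ind <- call_induced_targets(calls, min_cell_types = 2)
  expect_equal(ind$gene, "three_ct")
  expect_equal(ind$n_cell_types, 3L)
})

test_that("targets classify into shared and cell-type-specific groups", {
  enrich <- tibble::tibble(
    gene = c("shared1", "a_only", "b_only", "misfit"),
    preferred = c("noto", "noto", "hg", "hg"))
  cls <- classify_targets(
    targets_a = c("shared1", "a_only", "misfit"),
    targets_b = c("shared1", "b_only"),
    enrichment = enrich, cell_type_1 = "noto", cell_type_2 = "hg")
  got <- setNames(cls$class, cls$gene)
  expect_equal(got[["shared1"]], "shared")
  expect_equal(got[["a_only"]], "A_specific")
  expect_equal(got[["b_only"]], "B_specific")
  # in set A but preferring the other cell type: reported unclassified
  expect_equal(got[["misfit"]], "unclassified")
})

test_that("modules rank by their target percentage", {
  part <- module_partition(tibble::tibble(
    gene = paste0("g", 1:20),
    module = rep(c("M1", "M2"), each = 10)))
  ov <- target_module_overlap(paste0("g", 1:5), part)
  expect_equal(ov$target_pct, c(50, 0))
  expect_equal(ov$module, c("M1", "M2"))
  expect_error(target_module_overlap(c("zz1", "zz2"), part),
               class = "mimir_gene_error")
})
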