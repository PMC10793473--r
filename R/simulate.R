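#' Simulation configuration
#'
#' Bundles the knobs shared by the synthetic-data generators. Defaults
#' emulate a desk-scale developmental trajectory: 10 modules of 20 genes
#' riding impulse-shaped expression waves over a unit pseudotime axis, 200
#' flat background genes, a matched non-target background cell population,
#' negative-binomial count noise, and a perturbation arm with linear TF
#' effects and occasional gross outliers.
#'
#' @param seed Integer seed; every generator is a pure function of the
#'   config (including this seed).
#' @param n_modules,genes_per_module,n_background_genes Gene layout.
#' @param n_cells Trajectory cells (an equally sized background population
#'   is added); for the perturbation generator, total cells across
#'   conditions.
#' @param n_bins Pseudotime resolution used by downstream segmentation.
#' @param noise_sd Log-normal sd of per-cell multiplicative noise on the
#'   mean (0 disables).
#' @param dispersion Negative-binomial size parameter; `Inf` gives
#'   noise-free rounded counts.
#' @param annotation_purity Probability a module gene is annotated with
#'   its own module term (else a random other term).
#' @param annotation_coverage Fraction of genes each annotation database
#'   covers at all (default 0.4; curated databases annotate well under
#'   half of a vertebrate genome's genes).
#' @param confounder_mode `"none"`, `"co_expressed_split_function"` (two
#'   modules share timing but not function), `"co_function_split_time"`
#'   (two modules share function but not timing), or `"both"`.
#' @param effect_size Target regression coefficient scale.
#' @param outlier_frac Fraction of cells per gene receiving gross additive
#'   outliers in the perturbation data.
#' @return A `mimir_sim_config` list.
#' @export
simulation_config <- function(seed = 0, n_modules = 10,
                              genes_per_module = 20,
                              n_background_genes = 200, n_cells = 1000,
                              n_bins = 15, noise_sd = 0.1, dispersion = 10,
                              annotation_purity = 0.9,
                              annotation_coverage = 0.4,
                              confounder_mode = c("none",
                                                  "co_expressed_split_function",
                                                  "co_function_split_time",
                                                  "both"),
                              effect_size = 0.5, outlier_frac = 0.05) {
  confounder_mode <- match.arg(confounder_mode)
  stopifnot(n_modules >= 1, genes_per_module >= 1, n_background_genes >= 0,
            n_cells >= 1, n_bins >= 2, noise_sd >= 0, dispersion > 0,
            annotation_purity >= 0, annotation_purity <= 1,
            annotation_coverage >= 0, annotation_coverage <= 1,
            outlier_frac >= 0, outlier_frac <= 1)
  structure(
    list(seed = as.integer(seed), n_modules = n_modules,
         genes_per_module = genes_per_module,
         n_background_genes = n_background_genes, n_cells = n_cells,
         n_bins = n_bins, noise_sd = noise_sd, dispersion = dispersion,
         annotation_purity = annotation_purity,
         annotation_coverage = annotation_coverage,
         confounder_mode = confounder_mode, effect_size = effect_size,
         outlier_frac = outlier_frac),
    class = "mimir_sim_config"
  )
}

# impulse-shaped mean in [0, 1]: steep rise at `on`, fall at `off`
impulse_shape <- function(t, on, off, slope = 30) {
  sigmoid(slope * (t - on)) * sigmoid(slope * (off - t))
}

nb_counts <- function(mu, dispersion) {
  if (is.infinite(dispersion)) return(round(mu))
  rnbinom(length(mu), mu = mu, size = dispersion)
}

#' Simulate a pseudotime trajectory dataset with planted modules
#'
#' Module genes follow impulse-shaped mean curves (module-shared onset and
#' offset plus per-gene jitter) in the trajectory cells and are silent in
#' an equally sized background cell population; background genes are flat
#' at a common low level in both populations. Counts are drawn from a
#' negative-binomial noise model around the means. Under
#' `confounder_mode` `"co_expressed_split_function"` (or `"both"`) the
#' first two modules share their timing exactly.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `data` (a [count_matrix()]) and `truth` (a list:
#'   `true_partition`, `timing`, `true_markers`, `background_genes`,
#'   `module_timing`).
#' @export
simulate_trajectory_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "mimir_sim_config"))
  withr::with_seed(cfg$seed, {
    M <- cfg$n_modules; Gm <- cfg$genes_per_module
    module_ids <- sprintf("M%02d", seq_len(M))
    onset <- if (M == 1) 0.3 else 0.05 + 0.60 * (seq_len(M) - 1) / (M - 1)
    offset <- pmin(onset + 0.30, 1.05)
    if (cfg$confounder_mode %in% c("co_expressed_split_function", "both") &&
        M >= 2) {
      onset[2] <- onset[1]; offset[2] <- offset[1]
    }
    genes <- sprintf("%s_g%02d", rep(module_ids, each = Gm),
                     rep(seq_len(Gm), M))
    gene_module <- rep(module_ids, each = Gm)
    g_on <- pmax(0, onset[rep(seq_len(M), each = Gm)] +
                   rnorm(M * Gm, 0, 0.02))
    g_off <- pmax(g_on + 0.05,
                  offset[rep(seq_len(M), each = Gm)] +
                    rnorm(M * Gm, 0, 0.02))
    bg_genes <- if (cfg$n_background_genes > 0) {
      sprintf("bg%03d", seq_len(cfg$n_background_genes))
    } else character()

    n_traj <- cfg$n_cells; n_bg <- cfg$n_cells
    pt_traj <- runif(n_traj)
    pt_bg <- runif(n_bg)
    cell_ids <- c(sprintf("traj_%04d", seq_len(n_traj)),
                  sprintf("bg_%04d", seq_len(n_bg)))
    cell_type <- c(rep("trajectory", n_traj), rep("background", n_bg))
    pt <- c(pt_traj, pt_bg)

    amp <- 60  # peak counts of a module gene
    bg_mu <- 5 # flat background-gene counts everywhere
    n_genes <- length(genes) + length(bg_genes)
    n_cells_tot <- n_traj + n_bg
    counts <- matrix(0L, n_genes, n_cells_tot,
                     dimnames = list(c(genes, bg_genes), cell_ids))
    # module genes: impulse in trajectory cells, near-silent in background
    for (i in seq_along(genes)) {
      mu_traj <- amp * impulse_shape(pt_traj, g_on[i], g_off[i])
      if (cfg$noise_sd > 0) {
        mu_traj <- mu_traj * exp(rnorm(n_traj, 0, cfg$noise_sd))
      }
      mu <- c(mu_traj, rep(0.02, n_bg))
      counts[i, ] <- nb_counts(mu, cfg$dispersion)
    }
    for (j in seq_along(bg_genes)) {
      mu <- rep(bg_mu, n_cells_tot)
      if (cfg$noise_sd > 0) mu <- mu * exp(rnorm(n_cells_tot, 0,
                                                 cfg$noise_sd))
      counts[length(genes) + j, ] <- nb_counts(mu, cfg$dispersion)
    }
    # guard against zero-total cells (possible at tiny configs)
    zero <- colSums(counts) == 0
    if (any(zero)) counts[1, zero] <- 1L

    meta <- tibble(
      cell_id = cell_ids, pseudotime = pt,
      stage = paste0("S", findInterval(pt, c(0.25, 0.5, 0.75)) + 1),
      cell_type = cell_type, condition = "control", batch = "b0"
    )
    truth <- list(
      true_partition = tibble(gene = genes, module = gene_module),
      timing = tibble(gene = genes, onset = g_on, offset = g_off),
      true_markers = genes,
      background_genes = bg_genes,
      module_timing = tibble(module = module_ids, onset = onset,
                             offset = offset)
    )
    list(data = count_matrix(counts, meta), truth = truth)
  })
}

#' Simulate functional annotations and interaction evidence
#'
#' Builds a shallow synthetic ontology (one branch and leaf term per
#' module under a common root). Each database covers a random
#' `annotation_coverage` fraction of the module genes; a covered gene is
#' annotated with its module term with probability `annotation_purity`
#' (else a random other module's term). Interaction evidence is elevated
#' within modules. Under `confounder_mode` `"co_function_split_time"` (or
#' `"both"`) module 3 and the last module share one term -- functionally
#' alike but temporally separated -- and their cross-module interaction
#' evidence is elevated too; under
#' `"co_expressed_split_function"` modules 1 and 2 keep disjoint terms
#' despite sharing timing.
#'
#' @param cfg A [simulation_config()].
#' @param truth Ground truth from [simulate_trajectory_dataset()].
#' @param n_databases Number of independent annotation databases to emit
#'   (default 2).
#' @return A list: `dag` ([ontology_dag()]), `annotations` (list of
#'   `mimir_annotations`), `channels` ([evidence_channels()]).
#' @export
simulate_annotations <- function(cfg, truth, n_databases = 2) {
  stopifnot(inherits(cfg, "mimir_sim_config"))
  withr::with_seed(cfg$seed + 1L, {
    M <- cfg$n_modules
    module_ids <- truth$module_timing$module
    term_of_module <- setNames(sprintf("T:%s", module_ids), module_ids)
    if (cfg$confounder_mode %in% c("co_function_split_time", "both") &&
        M >= 4) {
      # temporally distant pair: same term, disjoint on-intervals
      term_of_module[[M]] <- term_of_module[[3]]
    }
    leaf_terms <- unique(unname(term_of_module))
    branch_terms <- sub("^T:", "B:", leaf_terms)
    terms <- tibble(
      term_id = c("T:root", branch_terms, leaf_terms),
      name = c("root", branch_terms, leaf_terms)
    )
    edges <- bind_rows(
      tibble(child = branch_terms, parent = "T:root", relation = "is_a"),
      tibble(child = leaf_terms, parent = branch_terms, relation = "is_a")
    )
    dag <- ontology_dag(terms, edges)

    assign_terms <- function() {
      g <- truth$true_partition$gene
      covered <- runif(length(g)) <= cfg$annotation_coverage
      own <- unname(term_of_module[truth$true_partition$module])
      corrupted <- runif(length(g)) > cfg$annotation_purity
      rand <- sample(leaf_terms, length(g), replace = TRUE)
      tibble(gene = g,
             term = ifelse(corrupted, rand, own))[covered, ]
    }
    annotations <- map(seq_len(n_databases), function(k) {
      annotation_map(assign_terms(), sprintf("db%s", LETTERS[k]))
    })

    # interaction evidence: elevated within modules (and across the
    # shared-function module pair), absent elsewhere
    same_fn_modules <- split(module_ids, unname(term_of_module[module_ids]))
    pair_rows <- map(same_fn_modules, function(mods) {
      g <- truth$true_partition$gene[
        truth$true_partition$module %in% mods]
      if (length(g) < 2) return(NULL)
      idx <- utils::combn(sort(g), 2)
      tibble(gene_a = idx[1, ], gene_b = idx[2, ],
             experiments = pmin(1, pmax(0, rnorm(ncol(idx), 0.85, 0.05))))
    })
    channels <- evidence_channels(bind_rows(pair_rows), prior = 0.41)
    list(dag = dag, annotations = annotations, channels = channels)
  })
}

#' Simulate a perturbation scRNA-seq dataset with planted TF targets
#'
#' Target-gene log2 means are a linear combination of baseline, TF levels,
#' and injection and batch offsets; non-target genes depend on injection
#' and batch but not on any TF. Knockout conditions force the affected
#' TF's expression to near zero. A fraction `outlier_frac` of cells per
#' gene receives gross additive outliers on the log scale. Housekeeping
#' genes stabilize per-cell totals so count normalization does not distort
#' the linear structure.
#'
#' @param cfg A [simulation_config()]; `n_cells` is the total across
#'   conditions, `effect_size` the TF coefficient, `outlier_frac` the
#'   outlier rate.
#' @param n_tfs Number of transcription factors (default 4).
#' @param conditions Optional tibble with `condition`, `tfs`
#'   (comma-separated knocked-out TFs, `""` for none), `injection`
#'   (0/1/1.5), `batch` (0/1), `n_cells`. Defaults to one uninjected
#'   control, one single-TF crispant per TF, and one all-TF crispant.
#' @param n_genes Non-TF response genes (default 200).
#' @param n_targets How many of them are true targets (default 40).
#' @param n_housekeeping Flat high-expression genes (default 20).
#' @return A list with `data` (a [count_matrix()]), `truth`
#'   (`true_targets`, `tfs`, `nontarget_genes`, and `outlier_cells`
#'   marking the planted gross outliers per gene), `knockout_map`,
#'   `injection_map`.
#' @export
simulate_perturbation_dataset <- function(cfg, n_tfs = 4, conditions = NULL,
                                          n_genes = 200, n_targets = 40,
                                          n_housekeeping = 20) {
  stopifnot(inherits(cfg, "mimir_sim_config"), n_targets <= n_genes)
  tfs <- sprintf("tf%d", seq_len(n_tfs))
  if (is.null(conditions)) {
    n_cond <- n_tfs + 2
    per <- max(10, cfg$n_cells %/% n_cond)
    conditions <- tibble(
      condition = c("control", sprintf("ko_%s", tfs), "ko_all"),
      tfs = c("", tfs, paste(tfs, collapse = ",")),
      injection = c(0, rep(1, n_tfs), 1.5),
      batch = rep_len(c(0, 1), n_cond),
      n_cells = per
    )
  }
  conditions <- as_tibble(conditions)
  ko_list <- map(strsplit(conditions$tfs, ","),
                 function(x) setdiff(trimws(x), ""))
  unknown <- setdiff(unlist(ko_list), tfs)
  if (length(unknown) > 0) {
    mimir_abort(sprintf("condition names unknown TF(s): %s",
                        paste(unknown, collapse = ", ")),
                class = "mimir_condition_error")
  }
  withr::with_seed(cfg$seed + 2L, {
    resp <- sprintf("gene%03d", seq_len(n_genes))
    hk <- if (n_housekeeping > 0) {
      sprintf("hk%02d", seq_len(n_housekeeping))
    } else character()
    target_genes <- sample(resp, n_targets)
    target_tf <- sample(tfs, n_targets, replace = TRUE)
    coef_map <- matrix(0, n_genes, n_tfs, dimnames = list(resp, tfs))
    coef_map[cbind(target_genes, target_tf)] <- cfg$effect_size
    baseline <- runif(n_genes, 1.5, 3.5)
    inj_coef <- runif(n_genes, -0.3, 0.3)
    batch_coef <- runif(n_genes, -0.3, 0.3)

    rows <- map(seq_len(nrow(conditions)), function(ci) {
      nc <- conditions$n_cells[ci]
      ko <- ko_list[[ci]]
      tf_log <- matrix(pmax(0, rnorm(nc * n_tfs, 3, 0.8)), nc, n_tfs,
                       dimnames = list(NULL, tfs))
      tf_log[, ko] <- 0
      logmean <- matrix(baseline, nc, n_genes, byrow = TRUE) +
        tf_log %*% t(coef_map) +
        conditions$injection[ci] * matrix(inj_coef, nc, n_genes,
                                          byrow = TRUE) +
        conditions$batch[ci] * matrix(batch_coef, nc, n_genes,
                                      byrow = TRUE)
      if (cfg$noise_sd > 0) {
        logmean <- logmean + matrix(rnorm(nc * n_genes, 0, cfg$noise_sd),
                                    nc, n_genes)
      }
      hit <- NULL
      if (cfg$outlier_frac > 0) {
        hit <- matrix(runif(nc * n_genes) < cfg$outlier_frac, nc, n_genes,
                      dimnames = list(NULL, resp))
        logmean[hit] <- logmean[hit] + 4  # 16-fold gross outliers
      }
      mu_resp <- pmax(2^logmean - 1, 0)
      mu_tf <- pmax(2^(tf_log + if (cfg$noise_sd > 0) {
        matrix(rnorm(nc * n_tfs, 0, cfg$noise_sd), nc, n_tfs)
      } else 0) - 1, 0)
      mu_hk <- matrix(180, nc, length(hk))
      mu <- cbind(mu_tf, mu_resp, mu_hk)
      cnt <- matrix(nb_counts(as.vector(mu), cfg$dispersion), nc,
                    ncol(mu))
      colnames(cnt) <- c(tfs, resp, hk)
      list(counts = cnt, hit = hit,
           condition = conditions$condition[ci],
           batch = conditions$batch[ci])
    })
    counts <- t(do.call(rbind, map(rows, "counts")))
    cell_ids <- sprintf("cell_%05d", seq_len(ncol(counts)))
    colnames(counts) <- cell_ids
    meta <- tibble(
      cell_id = cell_ids,
      pseudotime = NA_real_,
      stage = NA_character_,
      cell_type = "ct1",
      condition = rep(conditions$condition, conditions$n_cells),
      batch = as.character(rep(conditions$batch, conditions$n_cells))
    )
    zero <- colSums(counts) == 0
    if (any(zero)) counts[length(tfs) + 1, zero] <- 1
    # which (gene, cell) entries carry planted gross outliers
    hits <- do.call(rbind, map(rows, "hit"))
    outlier_cells <- if (!is.null(hits)) {
      idx <- which(hits, arr.ind = TRUE)
      tibble(gene = colnames(hits)[idx[, 2]], cell_id = cell_ids[idx[, 1]])
    } else {
      tibble(gene = character(), cell_id = character())
    }
    truth <- list(
      true_targets = tibble(tf = target_tf, gene = target_genes,
                            coefficient = cfg$effect_size),
      tfs = tfs,
      nontarget_genes = setdiff(resp, target_genes),
      housekeeping = hk,
      outlier_cells = outlier_cells
    )
    list(
      data = count_matrix(counts, meta),
      truth = truth,
      knockout_map = setNames(ko_list, conditions$condition),
      injection_map = setNames(conditions$injection, conditions$condition)
    )
  })
}
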