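# mimir

Temporally resolved gene module identification from developmental
single-cell trajectories, and robust inference of transcription-factor
target genes from perturbation scRNA-seq.

During differentiation, a cell type executes a cascade of cellular
remodeling processes — specification, cytoskeletal rearrangement,
secretory pathway expansion, cargo production. Each process is carried by
a set of genes that are *co-expressed in pseudotime* and *functionally
related*. Either signal alone is ambiguous: genes with unrelated
functions can share timing, and functionally similar genes can act at
different times. `mimir` is for developmental biologists who have a
reconstructed pseudotime trajectory (e.g. from URD) and want to resolve
its transcriptome into interpretable, temporally ordered functional
modules — and, given CRISPR loss-of-function or mRNA mis-expression
scRNA-seq, to identify which genes a transcription factor regulates.

## The method

**Trajectory-enriched genes.** The pseudotime axis is split into 15
equal segments, fusing adjacent segments below 60 cells as evenly as
possible. Per segment, each gene is scored as a classifier of trajectory
vs non-trajectory cells by the area under the precision–recall curve
(AUCPR). A gene is a segment marker when it is detected in ≥ 10% of the
segment's cells, its AUCPR is ≥ 2× the uninformative expectation
(positive-class prevalence; 7.5× in stage mode), and its log2 fold
change exceeds 0.3. Enriched genes pass in the final segment or in at
least two segments.

**Expression similarity.** Counts are scaled to 15,000 per cell and
log2(x+1)-transformed. Per-gene pseudotime profiles (per-segment means,
earliest pre-specification segment excluded) are compared by
Jensen–Shannon divergence (base-2, bounded by 1); distances are scaled
so the largest equals 0.95 and `S_exp = 1 − dist`.

**Functional similarity.** Per annotation database, gene pairs are
scored by Wang graph-based semantic similarity between their annotated
terms (edge weights: `is_a` 0.8, `part_of` 0.6) combined by
best-match-average (BMA). These semantic channels join the
interaction-evidence channels (STRING-style, with the opaque `database`
channels excluded) under the standard prior-corrected combination with
prior *p* = 0.41:

    S_fun = 1 − (1 − p) · Π_i (1 − max(0, (S_i − p)/(1 − p)))

**Module detection.** The fused similarity `S_final = S_exp · S_fun`
("AND" logic; "OR" and "+" are available) defines a weighted gene graph
clustered by Leiden under the RB-configuration quality at resolution 4.
Partitions are screened by structural criteria (> 85% of genes in
non-singlet modules, < 150 modules, largest module < 150 genes) and
ranked by adjusted mutual information (AMI) against a reference
partition when one is provided.

**Temporal ordering.** Each gene's profile is fit with an impulse model
— a product of a rising and a falling sigmoid,
`y(t) = (1/h1)·[h0 + (h1−h0)σ(b1(t−t1))]·[h2 + (h1−h2)σ(b2(t2−t))]` —
with sigmoid and flat fallbacks. Modules are ordered by the mean onset
time of their members, and module activity (fraction of member genes
"on") is tracked across pseudotime.

**TF target inference.** Each detected gene is modeled across single
cells as a linear combination of TF expression levels (set to 0 where
the TF was mutated or CRISPR-targeted), an injection covariate (0 /
1 / 1.5 for uninjected / single-gene / multi-gene injections) and a
batch covariate, fit by robust M-estimation with the Andrew's-wave
criterion. Targets require `R² > 0.15`, coefficient > 0.05 and
p < 1e-9; induced (mis-expression) targets additionally require
positive calls in ≥ 2 cell types.

Every stage is exercised end-to-end by synthetic-data generators with
planted ground truth (modules, timing, markers, targets, confounders).

## Worked example

```r
library(mimir)
library(dplyr)

cfg <- simulation_config(seed = 1, noise_sd = 0.05)
sim <- simulate_trajectory_dataset(cfg)   # 10 planted modules x 20 genes
ann <- simulate_annotations(cfg, sim$truth)

norm <- normalize_counts(sim$data)
traj <- filter(sim$data$cell_meta, cell_type == "trajectory")
segs <- segment_pseudotime(traj[, c("cell_id", "pseudotime")])

calls <- bind_rows(lapply(seq_len(nrow(segs)), function(i) {
  win <- with(sim$data$cell_meta,
              pseudotime >= segs$t_lo[i] & pseudotime <= segs$t_hi[i])
  bg  <- intersect(
    filter(sim$data$cell_meta, cell_type == "background")$cell_id,
    sim$data$cell_meta$cell_id[win])
  call_markers(norm, segs$cells[[i]], bg, mode = "trajectory", window = i)
}))
enriched <- define_enriched(calls, mode = "trajectory",
                            cell_type = "trajectory")
enriched
#> <mimir_enriched> trajectory: 200 genes

prof  <- build_profiles(norm, segs, genes = enriched$genes,
                        exclude_presegment = TRUE)
s_exp <- expression_similarity(profile_distance(prof, "jsd"))
ch    <- assemble_channels(ann$channels, ann$annotations, list(ann$dag),
                           genes = enriched$genes)
s_fun <- combine_channels(ch, genes = enriched$genes)
part  <- cluster_graph(combine_similarities(s_exp, s_fun, "and"),
                       algorithm = "leiden", resolution = 4, seed = 0)
glance(part)
#> # A tibble: 1 × 4
#>   n_genes n_modules max_module_size non_singlet_fraction
#>     <int>     <int>           <int>                <dbl>
#> 1     200        31              20                0.895

evaluate_partition(part, sim$truth$true_partition)[, c("ami", "eligible")]
#> # A tibble: 1 × 2
#>     ami eligible
#>   <dbl> <lgl>
#> 1 0.899 TRUE

fits <- fit_impulse_profiles(prof, seed = 0, n_starts = 10)
casc <- order_modules(fits, part, prof$bins)
casc
#> <mimir_cascade> 31 modules: M1 -> M2 -> M3 -> M7 -> M6 -> M8 -> M5 -> M4
autoplot(casc)   # module-by-pseudotime activity heatmap
```

All 200 planted module genes are recovered as enriched; the fused
("AND") similarity clustered at resolution 4 assigns 89.5% of them to
non-singlet modules and agrees with the planted partition at AMI 0.899;
the cascade orders early-onset modules (M1–M3, onset ≈ 0.10) before the
later waves. The three modules covering 20 genes each correspond to
planted modules recovered intact; the remaining small modules are
singleton stragglers from annotation-sparse genes.

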