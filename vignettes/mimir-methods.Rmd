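---
title: "Methods and design choices in mimir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in mimir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mimir` resolves a developmental single-cell trajectory into temporally
ordered functional gene modules, and infers transcription-factor target
genes from perturbation scRNA-seq. This vignette describes the models,
the parameters that matter, the synthetic data used for validation, and
the places where the design was genuinely open and a choice had to be
made.

## Normalization

Counts are scaled per cell to a fixed total (default `scale_total =
15000`), incremented by 1, and log2-transformed. Zero counts map to
exactly zero, so sparsity is preserved, and the inverse transform
`2^v - 1` recovers column sums equal to `scale_total` — an invariant the
test suite checks. Cells with zero total counts are a hard error naming
the cell: they indicate an upstream filtering problem, not something to
silently patch.

## Trajectory-enriched genes

The pseudotime axis is divided into `n_segments = 15` equal-width
intervals. Segments below `min_cells = 60` are fused with neighbours.
"Fuse as evenly as possible" is under-determined, and the naive reading
— minimize the variance of final segment counts subject to all segments
reaching the minimum — degenerates: a single all-encompassing segment
has zero variance. The implemented objective is therefore
lexicographic: **first** maximize the number of final segments, **then**
minimize the variance of their cell counts. For up to 16 initial
segments all `2^(k-1)` contiguous fusion plans are enumerated
exhaustively (at most 32,768 plans, trivially fast); beyond that a
greedy smallest-into-smaller-neighbour merge is used. On the canonical
case — three consecutive 20-cell segments flanked by full ones — this
fuses exactly those three into one 60-cell segment.

Marker calling uses the area under the precision–recall curve of each
gene as a classifier between the trajectory cells of a segment and the
non-trajectory cells in the same pseudotime window. Average precision is
computed over distinct score thresholds, so tied expression values
contribute as one block; fully tied (constant) scores then yield exactly
the positive-class prevalence. That prevalence is also the analytic
expectation of an uninformative ranking, and is the default null for
the AUCPR fold criterion (`aucpr_ratio = aucpr / prevalence`). A
permutation null (`aucpr_null = "permutation"`) is available; it is
slightly above prevalence at small cell numbers (the mean of a maximum
is not the maximum of a mean), which is why the analytic default is
both faster and less biased. The passing rule is detection in ≥ 10% of
group cells, AUCPR ≥ 2× the null (trajectory mode; 7.5× in stage mode,
where fewer cells make the empirical AUCPR noisier), and log2 fold
change > 0.3 computed on the normalized values without an extra
pseudocount (the normalization already added one).

Term over-representation uses the exact hypergeometric tail (one-sided,
no multiple-testing correction — results are reported as ranked
candidate labels, not as calibrated discoveries).

## Expression similarity

Profiles are per-segment means of log2-normalized expression; the
earliest segment can be excluded (`exclude_presegment`) because its
cells precede lineage specification. Jensen–Shannon divergence is used
as the divergence itself (not its square root), with base-2 logarithms
on sum-normalized profiles so it is bounded by 1. Euclidean, cosine and
Canberra distances are available for comparison.

Distances are scaled **zero-preservingly** — divide by the observed
maximum, multiply by `cap = 0.95` — rather than min–max scaled. Min–max
would destroy the identity case: whenever the smallest observed
distance is positive, two genes with identical dynamics would no longer
attain similarity 1. With the zero-preserving rule, `S_exp = 1 - d'`
ranges over `[0.05, 1]` and identical profiles always score 1. A
consequence worth knowing: `S_exp` is a *complete* graph — every gene
pair has positive similarity — so expression similarity alone, clustered
at high resolution, fragments into singletons (the resolution-4 null
model penalizes the dense uniform background). This is precisely why
fusing with the sparse functional evidence is effective.

## Functional similarity

Semantic similarity between ontology terms follows the Wang graph-based
measure: a term contributes semantic value 1 to itself and
weight-decayed values to its ancestors (per-edge weights `is_a = 0.8`,
`part_of = 0.6`, the measure's standard constants; multiple paths take
the maximum). Gene-level similarity is the best-match average of the
two term sets. An implementation detail with scientific content: a gene
unannotated in a database yields a **missing** channel, not a zero —
absence of evidence is not evidence of dissimilarity.

Evidence channels (interaction channels plus one semantic channel per
database) are combined under the standard prior-corrected rule with
`p = 0.41`. Fixed points of this rule: all channels at the prior give
exactly the prior; any channel at 1 gives 1; channels below the prior
are clamped and contribute nothing. Pairs carrying *no* channel at all
get `S_fun = 0` rather than `p`: the prior encodes the baseline
probability for an *observed* pair, and emitting it for every possible
pair would connect the entire graph. The opaque `database` and
`database_transferred` interaction channels are dropped at parse time
(their underlying databases are undisclosed and would double-count the
self-computed semantic channels); `combined_score` is never treated as
a channel.

## Module detection

The fused similarity (`and` = product, `or` = probabilistic union,
`plus` = sum) defines a weighted graph with edges only where the score
is strictly positive; under `and`, absent functional evidence removes
the edge, which keeps the graph sparse. Clustering uses igraph's Leiden
implementation with the modularity (RB-configuration) objective at
resolution 4 by default; Louvain and Infomap are exposed for
comparison. The seed is explicit (`seed = 0` default) and clustering is
reproducible given it.

AMI uses the exact hypergeometric expected-MI correction with the
average-entropy normalization (the common default; the implementation
is cross-checked in the tests against values frozen from an independent
reference implementation). Partition screening applies the structural
criteria — non-singlet fraction > 0.85, fewer than 150 modules, largest
module under 150 genes — before AMI ranking; ties are broken toward
fewer modules. Manual curation is supported only as data:
`apply_module_edits()` ingests a `(gene, new_module)` table and
re-emits the partition; the package makes no curation decisions.

## Impulse dynamics and the cascade

The temporal model is the product of a rising and a falling sigmoid
with baseline/peak/final levels `h0, h1, h2`, onset/offset times
`t1 ≤ t2` (enforced by parameterizing the offset as `t1 + dt`,
`dt ≥ 0`) and slopes `b1, b2`. Fitting is least squares via L-BFGS-B
(Nelder–Mead fallback) from 20 random starts seeded deterministically
from the gene name, so refits are reproducible without global state.
Simpler models — a single rising sigmoid and a flat mean — are always
fit too; a richer model is kept only if it improves the residual sum of
squares by more than 5% per extra parameter pair, and the selected fit
can never lose to the flat baseline (flat is in the search space).
Near-constant profiles (amplitude < 1e-8) are forced flat.

"On" is defined by threshold crossing: the fitted curve is evaluated on
a 1024-point grid and the gene is on wherever it reaches
`level_fraction = 0.5` of its amplitude. The fitted `t1` parameter is
also exported for users who prefer the parametric onset. Modules are
ordered by mean onset over members with on-intervals; all-flat modules
are placed last with a warning rather than dropped.

## Robust target inference

The design matrix holds observed TF log2 expression (zeroed in
conditions where that TF was mutated or targeted), an injection
covariate (0 uninjected, 1 single-gene, 1.5 multi-gene) and a 0/1 batch
covariate. Fitting is iteratively reweighted M-estimation with the
Andrew's-wave influence function at its standard tuning constant
`a = 1.339`, MAD scale, at most 50 iterations at tolerance 1e-8.
P-values are asymptotic normal tests on the robust coefficients — no
multiple-testing correction, matching the deliberately stringent fixed
cutoff p < 1e-9. `R²` is computed from the **raw** residuals
(`1 - SSres/SStot`), so heavy contamination honestly depresses it.
Degenerate cases are defined, not fudged: a constant response gets
`R² = 0` and can never be a target; an exactly collinear or constant
column is dropped with a warning; an (almost) exact linear fit — where
the residual scale collapses and M-estimation is undefined — reports
the least-squares solution with p = 0 on its nonzero coefficients.
Responses are restricted to genes detected in ≥ 1% of cells to avoid
all-zero regressions.

Target calls are symmetric in sign (negative targets use coefficient
< −0.05) even though biologically few repressed targets are expected —
keeping the rule unbiased costs nothing. Induced targets from
mis-expression data require positive calls in at least 2 cell types.

## What the synthetic data emulates — and what it does not

The trajectory generator plants `n_modules = 10` modules of
`genes_per_module = 20` genes whose negative-binomial counts
(`dispersion = 10`) follow impulse-shaped means with module-shared
timing plus per-gene jitter (sd 0.02 in pseudotime), over `n_cells =
1000` trajectory cells and an equal background population; 200
background genes are flat at a common low mean in both populations.
The annotation generator emits a shallow ontology (root → branch →
leaf per module: sibling leaf terms then fall below the combination
prior, so wrong-module semantic evidence is cleanly clamped), two
databases each covering `annotation_coverage = 0.4` of genes with
`annotation_purity = 0.9`, and within-module interaction evidence.
The coverage default reflects that curated databases annotate well
under half of a vertebrate genome's genes; it also keeps the fused
graph realistically sparse — full coverage would put every annotated
pair at or above the 0.41 prior floor and densify the graph beyond
what resolution-4 clustering can resolve at this gene count.

Two confounders can be planted: a co-expressed pair of modules with
identical timing but disjoint terms (defeats expression-only
clustering), and a shared-function pair — module 3 and the last module,
chosen to be temporally distant — with one common term and elevated
cross-interaction evidence (defeats function-only clustering). Mode
`"both"` plants them simultaneously; this combined value extends the
single-confounder modes because the integration claim is only testable
when both failure modes are present at once.

The perturbation generator emits 6 conditions (uninjected control, one
crispant per TF, one all-TF crispant) of 300 cells each, with linear TF
effects (`effect_size = 0.5` on the log2 scale) on 40 of 200 response
genes, additive injection/batch offsets on *all* genes (so confound
control is actually exercised), 5% gross outliers (+4 log2, i.e.
16-fold) per gene, and 20 high-expression housekeeping genes that
stabilize per-cell totals so count normalization does not distort the
planted linear structure. The planted outlier positions are recorded in
the ground truth so estimator drift under contamination can be measured
against each estimator's own clean-data fit.

Not emulated: ambient RNA, doublets, library-size confounding,
branch-structured trajectories, dropout beyond what the
negative-binomial implies, errors-in-variables in TF measurement
(present implicitly through count noise — coefficient estimates on
observed TF levels are mildly attenuated relative to the generative
values, which is why recovery is asserted on target *calls* rather
than on raw coefficient equality). Passing tests therefore demonstrate
correctness of the machinery under the stated generative model, not
performance on any real dataset.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen so a
full run stays in tens of seconds: 400 genes × 2000 cells for marker
recovery and module detection, 6 modules × 8 genes × 1600 cells for the
cascade, 224 genes × 1800 cells for target inference, and exhaustive
oracle comparisons at n ≤ 8 (average precision) and ≤ 6 terms (Wang
similarity).

## Known limitations

* Wang/BMA scales quadratically in annotated genes per database; for
  genome-wide universes the term-similarity cache matters and a
  pre-restriction to the enriched gene set is assumed.
* The impulse model is unimodal; genes with two expression waves fit
  poorly and land on the broader envelope.
* AMI-based configuration ranking needs a reference partition; without
  one, only the structural criteria order configurations.
* STRING-style identifiers must be pre-mapped to the expression data's
  gene ids; the package treats identifiers as opaque strings.
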