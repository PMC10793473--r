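# Independent brute-force oracles used to validate the package
# implementations. Deliberately written with naive loops / direct formula
# evaluation, sharing no code with the implementation paths they check.

# Average precision by explicit threshold sweep and rectangle integration
# over recall, with precision/recall recomputed from scratch at each
# distinct score value.
ap_oracle <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  thresholds <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels)
  prev_recall <- 0
  ap <- 0
  for (th in thresholds) {
    pred <- scores >= th
    tp <- 0
    for (i in seq_along(labels)) if (pred[i] && labels[i] == 1) tp <- tp + 1
    precision <- tp / sum(pred)
    recall <- tp / P
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# Wang S-values by exhaustive path enumeration: for every ancestor, the
# semantic value is the max over all upward paths of the product of edge
# weights along the path.
wang_svalues_oracle <- function(edges, term,
                                weights = c(is_a = 0.8, part_of = 0.6)) {
  sv <- c()
  walk <- function(node, value) {
    if (is.null(sv[node]) || is.na(sv[node]) || value > sv[node]) {
      sv[node] <<- value
    }
    up <- edges[edges$child == node, , drop = FALSE]
    if (nrow(up) == 0) return()
    for (k in seq_len(nrow(up))) {
      walk(up$parent[k], value * weights[[up$relation[k]]])
    }
  }
  walk(term, 1)
  sv
}

wang_oracle <- function(edges, a, b,
                        weights = c(is_a = 0.8, part_of = 0.6)) {
  sa <- wang_svalues_oracle(edges, a, weights)
  sb <- wang_svalues_oracle(edges, b, weights)
  common <- intersect(names(sa), names(sb))
  if (length(common) == 0) return(0)
  sum(sa[common] + sb[common]) / (sum(sa) + sum(sb))
}

# Evidence combination by direct evaluation of the stated formula.
combine_oracle <- function(channels, p = 0.41) {
  acc <- 1
  for (s in channels) {
    sp <- (s - p) / (1 - p)
    if (sp < 0) sp <- 0
    acc <- acc * (1 - sp)
  }
  1 - (1 - p) * acc
}

# Jensen-Shannon divergence by direct formula (base-2 KL to the mixture).
jsd_oracle <- function(x, y) {
  p <- x / sum(x); q <- y / sum(y)
  m <- (p + q) / 2
  kl <- function(a, b) {
    tot <- 0
    for (i in seq_along(a)) if (a[i] > 0) tot <- tot + a[i] * log2(a[i] / b[i])
    tot
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

# Hypergeometric upper tail by explicit combinatorial sum.
hyper_tail_oracle <- function(k, K, N, n) {
  tot <- 0
  for (x in k:min(K, n)) {
    tot <- tot + choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }
  tot
}

# Random small ontology DAG generator for the Wang oracle corpus: terms
# t1..tn, each non-root term gets 1-2 parents among earlier terms.
random_dag <- function(n_terms, seed) {
  set.seed(seed)
  terms <- paste0("t", seq_len(n_terms))
  rows <- list()
  for (i in 2:n_terms) {
    n_par <- sample(1:min(2, i - 1), 1)
    pars <- sample(terms[seq_len(i - 1)], n_par)
    for (p in pars) {
      rows[[length(rows) + 1]] <- data.frame(
        child = terms[i], parent = p,
        relation = sample(c("is_a", "part_of"), 1),
        stringsAsFactors = FALSE
      )
    }
  }
  edges <- do.call(rbind, rows)
  list(terms = terms, edges = edges)
}
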