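#' Adjusted mutual information between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items:
#' `AMI = (MI - E[MI]) / (mean(H(U), H(V)) - E[MI])`, with the expected
#' mutual information taken over the exact hypergeometric model of random
#' contingency tables with fixed marginals, and the average-entropy
#' normalization. Equals 1 iff the partitions are identical up to
#' relabeling; is ~0 for independent partitions.
#'
#' @param a,b Vectors of cluster labels over the same items, aligned by
#'   position.
#' @return A number (at most 1; can be slightly negative in finite
#'   samples).
#' @export
adjusted_mutual_information <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n == 0) mimir_abort("empty label vectors")
  tab <- table(a, b)
  ai <- rowSums(tab); bj <- colSums(tab)
  # mutual information and entropies (natural logs)
  pij <- tab / n
  pi_ <- ai / n; pj_ <- bj / n
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  hu <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hv <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  if (hu == 0 && hv == 0) return(1)
  # exact expected MI under the permutation (hypergeometric) model
  emi <- 0
  for (i in seq_along(ai)) {
    for (j in seq_along(bj)) {
      lo <- max(1, ai[i] + bj[j] - n)
      hi <- min(ai[i], bj[j])
      if (hi < lo) next
      nij <- lo:hi
      probs <- stats::dhyper(nij, ai[i], n - ai[i], bj[j])
      emi <- emi + sum((nij / n) * log(n * nij / (ai[i] * bj[j])) * probs)
    }
  }
  denom <- (hu + hv) / 2 - emi
  if (abs(denom) < 1e-12) {
    return(if (abs(mi - emi) < 1e-12) 1 else 0)
  }
  (mi - emi) / denom
}
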