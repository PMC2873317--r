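# Independent reference implementations used as oracles. Deliberately naive:
# direct formulas and exhaustive enumeration, no shared code with the package.

# composition entropy of one window, via table()
entropy_direct <- function(window) {
  f <- table(strsplit(window, "")[[1]])
  f <- f / sum(f)
  -sum(f * log2(f))
}

random_protein <- function(len, residues = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(residues, len, replace = TRUE), collapse = "")
}

random_proteome <- function(n, len_range) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  seqs <- vapply(lens, random_protein, character(1))
  names(seqs) <- sprintf("S%04d", seq_len(n))
  seqs
}

# Mann-Whitney U as a pair count: pairs with a > b plus half the ties
u_brute <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# hypergeometric upper tail P(X >= k) by direct summation
hyper_tail <- function(k, K, n, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# BH step-up by the textbook formula
bh_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Declarative check of greedy overlap resolution for one protein:
# enumerate all pairwise-disjoint candidate subsets and keep the unique one in
# which every excluded candidate overlaps a kept candidate of higher priority
# (priority: lower Z, then longer window, then smaller start).
resolve_exhaustive <- function(cand) {
  n <- nrow(cand)
  pri <- order(cand$Z, -cand$w, cand$start)
  rank_of <- integer(n)
  rank_of[pri] <- seq_len(n)
  overlaps <- function(i, j) cand$start[i] <= cand$end[j] & cand$end[i] >= cand$start[j]
  sets <- list()
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) > 1) {
      pairs <- combn(idx, 2)
      if (any(overlaps(pairs[1, ], pairs[2, ]))) next
    }
    out <- setdiff(seq_len(n), idx)
    ok <- TRUE
    for (j in out) {
      blockers <- idx[overlaps(idx, j)]
      if (!any(rank_of[blockers] < rank_of[j])) { ok <- FALSE; break }
    }
    if (ok) sets[[length(sets) + 1]] <- idx
  }
  stopifnot(length(sets) == 1L)   # the greedy-consistent subset is unique
  sort(sets[[1]])
}
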