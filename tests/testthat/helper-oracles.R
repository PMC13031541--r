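# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force or closed form, never by calling the code paths
# they check.

# Union of all minimum spanning trees by exhaustive spanning-tree
# enumeration (feasible for <= 7 nodes).
bruteForceMstUnion <- function(d) {
  k <- nrow(d)
  if (k < 2) return(data.frame(from = integer(0), to = integer(0),
                               steps = integer(0)))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  nE <- nrow(pairs)
  combos <- utils::combn(nE, k - 1)
  spanning <- function(edgeIdx) {
    parent <- seq_len(k)
    findRoot <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    for (e in edgeIdx) {
      r1 <- findRoot(pairs[e, 1]); r2 <- findRoot(pairs[e, 2])
      if (r1 == r2) return(FALSE)
      parent[r1] <- r2
    }
    TRUE
  }
  best <- Inf
  bestSets <- list()
  for (ci in seq_len(ncol(combos))) {
    idx <- combos[, ci]
    if (!spanning(idx)) next
    w <- sum(d[pairs[idx, , drop = FALSE]])
    if (w < best - 1e-9) {
      best <- w
      bestSets <- list(idx)
    } else if (abs(w - best) < 1e-9) {
      bestSets[[length(bestSets) + 1]] <- idx
    }
  }
  edges <- unique(do.call(rbind, lapply(bestSets, function(idx)
    data.frame(from = pairs[idx, 1], to = pairs[idx, 2]))))
  edges$steps <- d[cbind(edges$from, edges$to)]
  edges[order(edges$from, edges$to), ]
}

# random DNA haplotypes of a given length
randomHaplotypes <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# brute-force binomial log-likelihood of an aggregated logit cline
clineLogLik <- function(beta0, beta1, x, successes, failures) {
  p <- 1 / (1 + exp(-(beta0 + beta1 * x)))
  sum(successes * log(p) + failures * log(1 - p))
}

# Jaccard overlap of two GRanges intervals
rangeJaccard <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(0)
  ov <- GenomicRanges::intersect(a, b)
  un <- GenomicRanges::union(a, b)
  sum(GenomicRanges::width(ov)) / sum(GenomicRanges::width(un))
}
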