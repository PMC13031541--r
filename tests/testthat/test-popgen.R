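test_that("per-site Hudson FST matches the closed form", {
  # fixed difference at large samples: FST = 1
  r <- hudsonFstSite(1, 0, 1000, 1000)
  expect_equal(r$numerator / r$denominator, 1)
  # identical intermediate frequencies: numerator -> 0 as n grows
  r2 <- hudsonFstSite(0.5, 0.5, 1e6, 1e6)
  expect_lt(abs(r2$numerator), 1e-5)
  # hand evaluation of the stated formula
  r3 <- hudsonFstSite(0.9, 0.1, 50, 50)
  expect_equal(r3$numerator, 0.64 - 2 * (0.09 / 49), tolerance = 1e-12)
  expect_equal(r3$denominator, 0.82, tolerance = 1e-12)
  expect_equal(r3$numerator / r3$denominator, 0.7760, tolerance = 1e-4)
  # monomorphic in both -> (0, 0)
  r4 <- hudsonFstSite(0, 0, 10, 10)
  expect_identical(c(r4$numerator, r4$denominator), c(0, 0))
})

test_that("windowed FST: identity, label symmetry, single-site ratio", {
  sim <- simulateInversionDataset(simulationConfig(
    latitudes = c(50, 62), samplesPerLocation = 15, nSites = 400,
    chromosomeLength = 100000, inversionStart = 20001, inversionEnd = 80000,
    seed = 41))
  g <- sim$genotypes
  ids <- colnames(g)
  # same samples on both sides: the unbiased numerator makes every usable
  # site contribute exactly -2*pq/(n-1) over 2*pq, so the ratio of
  # averages is exactly -1/(n-1) = -1/19 with 10 diploids: ~ 0, slightly
  # negative by the sampling correction
  same <- windowedFst(g, ids[1:10], ids[1:10])
  expect_true(all(abs(same@windows$fst + 1 / 19) < 1e-12, na.rm = TRUE))
  expect_lt(abs(globalFst(same) + 1 / 19), 1e-12)
  # swapping group labels leaves the global ratio unchanged
  a <- ids[1:15]
  b <- ids[16:30]
  expect_equal(globalFst(windowedFst(g, a, b)),
               globalFst(windowedFst(g, b, a)), tolerance = 1e-12)
  # with a single polymorphic site the ratio of averages is the site value
  d <- matrix(c(0L, 1L, 1L, 2L), 1, 4,
              dimnames = list(NULL, c("a1", "a2", "b1", "b2")))
  gs <- toyGenotypes(d, positions = 100L)
  res <- windowedFst(gs, c("a1", "a2"), c("b1", "b2"))
  site <- hudsonFstSite(mean(d[1, 1:2]) / 2, mean(d[1, 3:4]) / 2, 4, 4)
  expect_equal(globalFst(res), site$numerator / site$denominator,
               tolerance = 1e-12)
})

test_that("pairwise divergence counts substitutions like brute force", {
  # the reported headline arithmetic: 16 differences over 488 bp = 3.3%
  set.seed(7)
  base <- paste(sample(c("A", "C", "G", "T"), 488, replace = TRUE),
                collapse = "")
  v <- strsplit(base, "")[[1]]
  idx <- sample(488, 16)
  v[idx] <- vapply(v[idx], function(b) sample(setdiff(c("A", "C", "G", "T"),
                                                      b), 1), character(1))
  div <- pairwiseDivergence(c(s = base, n = paste(v, collapse = "")))
  expect_equal(div$counts["s", "n"], 16)
  expect_equal(div$percent["s", "n"], 3.3)

  # identical sequences
  div0 <- pairwiseDivergence(c(a = "ACGT", b = "ACGT"))
  expect_equal(div0$counts["a", "b"], 0)
  expect_equal(div0$percent["a", "b"], 0)

  # brute-force position-by-position oracle on random 100-mers
  seqs <- randomHaplotypes(5, 100, seed = 12)
  names(seqs) <- paste0("h", 1:5)
  div2 <- pairwiseDivergence(seqs)
  for (i in 1:4) for (j in (i + 1):5) {
    brute <- sum(strsplit(seqs[i], "")[[1]] != strsplit(seqs[j], "")[[1]])
    expect_equal(unname(div2$counts[i, j]), brute)
  }
  # triangle inequality for Hamming distances
  cnt <- div2$counts
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_lte(cnt[i, j], cnt[i, k] + cnt[k, j])

  # IUPAC handling: compatible ambiguity = match, N = excluded position
  divA <- pairwiseDivergence(c(x = "ARGT", y = "AAGT"))
  expect_equal(divA$counts["x", "y"], 0)
  divN <- pairwiseDivergence(c(x = "ANGT", y = "AAGA"))
  expect_equal(divN$counts["x", "y"], 1)
  expect_equal(divN$lengthUsed["x", "y"], 3)
  expect_error(pairwiseDivergence(c("ACGT", "ACG")), "equal length")
})

test_that("epsilon = 0 MSN collapses duplicates and unions all MSTs", {
  # {A, A, C}: two nodes, multiplicity 2 on A, one edge of weight 1
  net <- minimumSpanningNetwork(c("A", "A", "C"))
  expect_equal(length(net@haplotypes), 2)
  expect_equal(sort(net@multiplicity), c(1L, 2L))
  expect_equal(nrow(networkEdges(net)), 1)
  expect_equal(networkEdges(net)$steps, 1L)

  # star: two haplotypes at distance 1 from a hub, distance 2 apart
  star <- minimumSpanningNetwork(c(hub = "AA", x = "CA", y = "AG"))
  e <- networkEdges(star)
  expect_equal(nrow(e), 2)
  expect_true(all(e$steps == 1))
  oracle <- bruteForceMstUnion(pairwiseDivergence(c("AA", "CA", "AG"))$counts)
  expect_equal(nrow(oracle), 2)

  # equidistant triple: union of all MSTs is the full triangle
  tri <- minimumSpanningNetwork(c("AA", "AC", "AG"))
  expect_equal(nrow(networkEdges(tri)), 3)
})

test_that("MSN equals the brute-force union of all MSTs on random inputs", {
  for (seed in 1:6) {
    n <- 4 + (seed %% 4)  # 4..7 haplotypes
    seqs <- randomHaplotypes(n, 6, seed = 100 + seed)
    seqs <- unique(seqs)
    net <- minimumSpanningNetwork(seqs)
    d <- pairwiseDivergence(seqs)$counts
    oracle <- bruteForceMstUnion(d)
    got <- networkEdges(net)
    gotIdx <- data.frame(
      from = as.integer(sub("H", "", got$from)),
      to = as.integer(sub("H", "", got$to)), steps = got$steps)
    key <- function(df) sort(paste(pmin(df$from, df$to),
                                   pmax(df$from, df$to), df$steps))
    expect_identical(key(gotIdx), key(oracle))
  }
})

test_that("MSN is a superset of a standard MST and connects all nodes", {
  skip_if_not_installed("ape")
  seqs <- randomHaplotypes(6, 8, seed = 202)
  seqs <- unique(seqs)
  d <- pairwiseDivergence(seqs)$counts
  net <- minimumSpanningNetwork(seqs)
  e <- networkEdges(net)
  # connectivity via union-find over the returned edges
  parent <- seq_along(seqs)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(e))) {
    i <- as.integer(sub("H", "", e$from[r]))
    j <- as.integer(sub("H", "", e$to[r]))
    parent[findRoot(i)] <- findRoot(j)
  }
  expect_equal(length(unique(vapply(seq_along(seqs), findRoot,
                                    integer(1)))), 1)
  # ape's MST edges are all contained in the network
  m <- ape::mst(as.dist(d))
  mstPairs <- which(as.matrix(m) == 1 & upper.tri(m), arr.ind = TRUE)
  netKey <- paste(pmin(as.integer(sub("H", "", e$from)),
                       as.integer(sub("H", "", e$to))),
                  pmax(as.integer(sub("H", "", e$from)),
                       as.integer(sub("H", "", e$to))))
  for (r in seq_len(nrow(mstPairs)))
    expect_true(paste(min(mstPairs[r, ]), max(mstPairs[r, ])) %in% netKey)
})
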