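#' @import Biostrings
#' @import IRanges
NULL

#' Per-site Hudson FST components
#'
#' Hudson's estimator in the Bhatia et al. form:
#' numerator N = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1),
#' denominator D = p1(1-p2) + p2(1-p1), with n1, n2 the non-missing allele
#' counts. The site FST is N/D where D > 0; sites monomorphic in both groups
#' (D = 0) are excluded from ratio-of-averages aggregation.
#'
#' @param p1,p2 allele frequencies in the two groups (vectors allowed).
#' @param n1,n2 allele counts the frequencies were computed from (>= 2).
#' @return list with numeric vectors \code{numerator} and \code{denominator}.
#' @export
hudsonFstSite <- function(p1, p2, n1, n2) {
  stopifnot(all(n1 >= 2), all(n2 >= 2),
            all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  num[den == 0] <- 0
  list(numerator = num, denominator = den)
}

#' Windowed and global Hudson FST between two sample groups
#'
#' Per-site components are aggregated as a ratio of averages: window FST is
#' the sum of numerators over the sum of denominators across the window's
#' usable sites, and likewise globally. Sample allele frequencies use
#' non-missing dosages only; sites with fewer than 4 non-missing alleles in
#' either group are excluded, as are sites monomorphic in both groups.
#' Windows with no usable site get a missing FST, not zero.
#'
#' @param g a [GenotypeData-class] object.
#' @param groupA,groupB character vectors of sample IDs (>= 2 each).
#' @param region optional GRanges or "chrom:start-end" restricting the sites.
#' @param windowSize window width in bp (default 25 kb, non-overlapping).
#' @return An [FstResult-class] object.
#' @export
windowedFst <- function(g, groupA, groupB, region = NULL,
                        windowSize = 25000) {
  stopifnot(is(g, "GenotypeData"))
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("both groups need at least 2 diploid samples")
  if (!is.null(region)) g <- subsetByRegion(g, region)
  d <- dosages(g)
  pos <- GenomicRanges::start(siteRanges(g))
  dA <- d[, groupA, drop = FALSE]
  dB <- d[, groupB, drop = FALSE]
  nA <- 2L * rowSums(!is.na(dA))
  nB <- 2L * rowSums(!is.na(dB))
  pA <- rowSums(dA, na.rm = TRUE) / nA
  pB <- rowSums(dB, na.rm = TRUE) / nB
  usable <- nA >= 4 & nB >= 4
  comp <- hudsonFstSite(pA[usable], pB[usable], nA[usable], nB[usable])
  posU <- pos[usable]
  poly <- comp$denominator > 0
  perSite <- S4Vectors::DataFrame(position = posU[poly],
                                  numerator = comp$numerator[poly],
                                  denominator = comp$denominator[poly])
  lo <- min(pos)
  starts <- seq(lo, max(pos), by = windowSize)
  widx <- findInterval(perSite$position, starts)
  winFst <- rep(NA_real_, length(starts))
  winN <- integer(length(starts))
  for (w in seq_along(starts)) {
    sel <- widx == w
    winN[w] <- sum(sel)
    if (winN[w] > 0)
      winFst[w] <- sum(perSite$numerator[sel]) /
        sum(perSite$denominator[sel])
  }
  windows <- S4Vectors::DataFrame(start = starts,
                                  end = starts + windowSize - 1,
                                  nSites = winN, fst = winFst)
  globalVal <- if (nrow(perSite)) sum(perSite$numerator) /
    sum(perSite$denominator) else NA_real_
  new("FstResult", groups = c("A", "B"), perSite = perSite,
      windows = windows, global = globalVal)
}

# per-pair substitution count between two character vectors of bases,
# honouring IUPAC ambiguity compatibility; N and gaps excluded pairwise
.pairDiff <- function(a, b) {
  excluded <- a %in% c("N", "-") | b %in% c("N", "-")
  a <- a[!excluded]
  b <- b[!excluded]
  same <- a == b
  mism <- !same
  if (any(mism)) {
    compat <- mapply(function(x, y) {
      sx <- IUPAC_SETS[[x]]
      sy <- IUPAC_SETS[[y]]
      !is.null(sx) && !is.null(sy) && length(intersect(sx, sy)) > 0
    }, a[mism], b[mism])
    count <- sum(!compat)
  } else count <- 0L
  c(count = count, length = length(a))
}

#' Pairwise divergence between aligned sequences
#'
#' Counts substitutions position by position on equal-length sequences.
#' Positions where either base is N or a gap are excluded (the pairwise
#' alignment length is reduced accordingly); IUPAC ambiguity codes
#' compatible with the other base count as a match. Percent divergence is
#' count / alignment length x 100, reported to 1 decimal.
#'
#' @param seqs named DNAStringSet or character vector of aligned sequences.
#' @return list with matrices \code{counts} (integer substitution counts),
#'   \code{percent} (1-decimal percent divergence) and \code{lengthUsed}
#'   (pairwise effective alignment lengths).
#' @export
pairwiseDivergence <- function(seqs) {
  nms <- names(seqs)
  seqs <- as.character(seqs)
  if (length(unique(nchar(seqs))) != 1)
    stop("sequences must be aligned to equal length")
  n <- length(seqs)
  chars <- strsplit(toupper(seqs), "")
  counts <- matrix(0L, n, n, dimnames = list(nms, nms))
  lens <- matrix(nchar(seqs)[1], n, n,
                 dimnames = dimnames(counts))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        r <- .pairDiff(chars[[i]], chars[[j]])
        counts[i, j] <- counts[j, i] <- r["count"]
        lens[i, j] <- lens[j, i] <- r["length"]
      }
    }
  }
  percent <- round(100 * counts / lens, 1)
  diag(percent) <- 0
  list(counts = counts, percent = percent, lengthUsed = lens)
}

#' Minimum spanning network of haplotypes (epsilon = 0)
#'
#' Identical sequences are collapsed into nodes with multiplicities. For
#' epsilon = 0 the network is the union of all minimum spanning trees of the
#' complete graph weighted by substitution counts: distinct edge weights are
#' processed in increasing order, and within a weight class every edge
#' joining components that were distinct before the class was opened is
#' added.
#'
#' @param seqs named DNAStringSet or character vector of aligned sequences
#'   (one entry per sampled haplotype; duplicates supply multiplicity).
#' @param epsilon only 0 is supported.
#' @return A [HaplotypeNetwork-class] object.
#' @export
minimumSpanningNetwork <- function(seqs, epsilon = 0) {
  if (epsilon != 0) stop("only epsilon = 0 is implemented")
  seqChar <- toupper(as.character(seqs))
  if (!length(seqChar)) stop("need at least one haplotype")
  uniq <- unique(seqChar)
  membership <- match(seqChar, uniq)
  multiplicity <- as.integer(tabulate(membership, nbins = length(uniq)))
  hap <- Biostrings::DNAStringSet(uniq)
  names(hap) <- sprintf("H%02d", seq_along(uniq))
  k <- length(uniq)
  edges <- data.frame(from = character(0), to = character(0),
                      steps = integer(0))
  if (k > 1) {
    dmat <- pairwiseDivergence(uniq)$counts
    # sequences distinct as strings but at distance 0 (ambiguity-compatible
    # everywhere) are collapsed into one node
    if (any(dmat[upper.tri(dmat)] == 0)) {
      grp <- seq_len(k)
      for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
        if (dmat[i, j] == 0) grp[grp == grp[j]] <- grp[i]
      reps <- match(unique(grp), grp)
      membership <- match(grp[membership], grp[reps])
      uniq <- uniq[reps]
      multiplicity <- as.integer(tabulate(membership, nbins = length(uniq)))
      hap <- Biostrings::DNAStringSet(uniq)
      names(hap) <- sprintf("H%02d", seq_along(uniq))
      k <- length(uniq)
      if (k == 1)
        return(new("HaplotypeNetwork", haplotypes = hap,
                   multiplicity = multiplicity, membership = membership,
                   edges = edges, epsilon = epsilon))
      dmat <- pairwiseDivergence(uniq)$counts
    }
    pairs <- which(upper.tri(dmat), arr.ind = TRUE)
    ew <- dmat[pairs]
    ord <- order(ew)
    pairs <- pairs[ord, , drop = FALSE]
    ew <- ew[ord]
    parent <- seq_len(k)
    findRoot <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    keep <- logical(length(ew))
    for (wval in unique(ew)) {
      cls <- which(ew == wval)
      # component structure before this weight class is opened
      snapshot <- vapply(seq_len(k), findRoot, integer(1))
      add <- cls[snapshot[pairs[cls, 1]] != snapshot[pairs[cls, 2]]]
      keep[add] <- TRUE
      for (e in add) {
        r1 <- findRoot(pairs[e, 1])
        r2 <- findRoot(pairs[e, 2])
        if (r1 != r2) parent[r1] <- r2
      }
    }
    edges <- data.frame(from = names(hap)[pairs[keep, 1]],
                        to = names(hap)[pairs[keep, 2]],
                        steps = as.integer(ew[keep]))
  }
  new("HaplotypeNetwork", haplotypes = hap, multiplicity = multiplicity,
      membership = membership, edges = edges, epsilon = epsilon)
}
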