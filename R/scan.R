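# Centering / imputation shared by windowPca and regionPca: dosages are
# centered at 2p per site, missing entries mean-imputed (0 after centering),
# optionally scaled by sqrt(2p(1-p)).
.pcaInput <- function(d, scale = FALSE) {
  p <- rowMeans(d, na.rm = TRUE) / 2
  # a usable site needs intermediate frequency AND dosage variance (a site
  # where every individual is heterozygous has p = 0.5 but zero variance)
  dvar <- apply(d, 1, function(r) {
    r <- r[!is.na(r)]
    length(r) > 1 && any(r != r[1])
  })
  poly <- !is.na(p) & p > 0 & p < 1 & dvar
  d <- d[poly, , drop = FALSE]
  p <- p[poly]
  x <- sweep(d, 1, 2 * p)
  x[is.na(x)] <- 0
  if (scale) x <- x / sqrt(2 * p * (1 - p))
  list(x = t(x), nSites = sum(poly))  # samples x sites
}

# Leading principal components of centered sample x site matrix.
# Sign convention: the sample with the lexicographically smallest ID gets a
# non-negative score on each PC (eigenvectors are sign-ambiguous).
.leadingPcs <- function(x, k = 1) {
  sv <- svd(x, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- rownames(x)
  refSample <- sort(rownames(x))[1]
  for (j in seq_len(k)) {
    if (scores[refSample, j] < 0) scores[, j] <- -scores[, j]
  }
  lambda <- sv$d^2
  list(scores = scores, pctVar = 100 * lambda[seq_len(k)] / sum(lambda))
}

#' Sliding-window PCA along a chromosome
#'
#' For each window, dosages are centered at twice the allele frequency,
#' missing entries mean-imputed, and the PC1 score of every sample computed
#' from the leading eigenvector of the sample covariance. An inversion shows
#' as three PC1 clusters confined to the inverted interval. Windows with
#' fewer than \code{minSites} usable polymorphic sites (including
#' zero-variance windows) are flagged skipped.
#'
#' @param g a [GenotypeData-class] object on a single chromosome.
#' @param windowSize window width in bp (default 50 kb, the scale at which
#'   three-cluster structure is expected to be visible).
#' @param step step between window starts (default: non-overlapping).
#' @param minSites minimum usable polymorphic sites per window.
#' @param scale scale centered dosages by sqrt(2p(1-p)) before the PCA.
#' @return A [WindowPcaSet-class] object.
#' @export
windowPca <- function(g, windowSize = 50000, step = windowSize,
                      minSites = 10, scale = FALSE) {
  stopifnot(is(g, "GenotypeData"))
  if (ncol(g) < 2) stop("need at least 2 samples")
  rr <- siteRanges(g)
  chroms <- unique(as.character(GenomicRanges::seqnames(rr)))
  if (length(chroms) != 1)
    stop("windowPca expects a single chromosome; subset first")
  pos <- GenomicRanges::start(rr)
  maxPos <- max(pos)
  starts <- seq(1L, maxPos, by = step)
  d <- dosages(g)
  nW <- length(starts)
  scores <- matrix(NA_real_, nW, ncol(g), dimnames = list(NULL, colnames(g)))
  nSites <- integer(nW)
  pctVar <- rep(NA_real_, nW)
  skipped <- logical(nW)
  for (w in seq_len(nW)) {
    idx <- which(pos >= starts[w] & pos <= starts[w] + windowSize - 1L)
    inp <- if (length(idx)) .pcaInput(d[idx, , drop = FALSE], scale = scale)
           else list(x = NULL, nSites = 0L)
    nSites[w] <- inp$nSites
    if (inp$nSites < minSites) {
      skipped[w] <- TRUE
      next
    }
    pc <- .leadingPcs(inp$x, k = 1)
    scores[w, ] <- pc$scores[colnames(g), 1]
    pctVar[w] <- pc$pctVar[1]
  }
  windows <- GenomicRanges::GRanges(
    chroms, IRanges::IRanges(starts, width = windowSize),
    nSites = nSites, pctVar = pctVar, skipped = skipped)
  new("WindowPcaSet", windows = windows, scores = scores)
}

# Equal-variance Gaussian-mixture BIC of a k-means partition of 1-D scores.
.kmeansBic <- function(x, k, seed) {
  n <- length(x)
  if (length(unique(x)) < k) return(list(bic = Inf, cluster = NULL))
  km <- withSeed(seed, kmeans(x, centers = k, nstart = 20))
  sigma2 <- max(km$tot.withinss / n, 1e-12)
  w <- km$size / n
  dens <- vapply(seq_len(k), function(j) {
    w[j] * dnorm(x, km$centers[j], sqrt(sigma2))
  }, numeric(n))
  ll <- sum(log(pmax(rowSums(as.matrix(dens)), 1e-300)))
  list(bic = -2 * ll + 2 * k * log(n), cluster = km$cluster,
       centers = as.numeric(km$centers))
}

# mean heterozygosity (proportion of dosage == 1) per cluster over given sites
.clusterHet <- function(d, cluster) {
  het <- colMeans(d == 1L, na.rm = TRUE)
  vapply(sort(unique(cluster)), function(j) mean(het[cluster == j]),
         numeric(1))
}

#' Call the inversion interval from windowed PCA trimodality
#'
#' Per window, 1-D k-means with k in \{1, 2, 3\} is fitted to the PC1 scores
#' and k chosen by minimal BIC under an equal-variance Gaussian mixture
#' approximation. A window is inversion-like when k = 3 and the middle
#' cluster's mean heterozygosity over that window's sites exceeds both outer
#' clusters' (heterokaryotypes are heterozygous at arrangement-fixed sites).
#' The call is the longest run of inversion-like windows tolerating at most
#' \code{gapMax} non-qualifying windows; the interval spans the qualifying
#' windows of that run.
#'
#' @param wp a [WindowPcaSet-class] from [windowPca()].
#' @param g the [GenotypeData-class] object the windows were computed from.
#' @param gapMax non-qualifying windows tolerated inside a run.
#' @param seed sub-seed for the k-means restarts.
#' @return A [RegionCall-class] object (empty region when nothing qualifies).
#' @export
detectInversionRegion <- function(wp, g, gapMax = 1, seed = 1) {
  stopifnot(is(wp, "WindowPcaSet"), is(g, "GenotypeData"))
  win <- wp@windows
  if (length(win) < 3) stop("need at least 3 windows")
  pos <- GenomicRanges::start(siteRanges(g))
  d <- dosages(g)
  nW <- length(win)
  kChosen <- rep(NA_integer_, nW)
  hetMid <- rep(NA_real_, nW)
  hetOuterMax <- rep(NA_real_, nW)
  inversionLike <- logical(nW)
  for (w in seq_len(nW)) {
    if (win$skipped[w]) next
    x <- wp@scores[w, ]
    fits <- lapply(1:3, function(k)
      .kmeansBic(x, k, deriveSeed(seed, paste0("win", w, "k", k))))
    bics <- vapply(fits, `[[`, numeric(1), "bic")
    kChosen[w] <- which.min(bics)
    if (kChosen[w] == 3) {
      cl <- fits[[3]]$cluster
      idx <- which(pos >= GenomicRanges::start(win)[w] &
                     pos <= GenomicRanges::end(win)[w])
      het <- .clusterHet(d[idx, , drop = FALSE], cl)
      ord <- order(fits[[3]]$centers)
      hetMid[w] <- het[ord[2]]
      hetOuterMax[w] <- max(het[ord[c(1, 3)]])
      inversionLike[w] <- hetMid[w] > hetOuterMax[w]
    }
  }
  diag <- S4Vectors::DataFrame(
    start = GenomicRanges::start(win), end = GenomicRanges::end(win),
    nSites = win$nSites, skipped = win$skipped, k = kChosen,
    hetMid = hetMid, hetOuterMax = hetOuterMax,
    inversionLike = inversionLike)
  q <- which(inversionLike)
  if (!length(q))
    return(new("RegionCall", region = GenomicRanges::GRanges(),
               windows = diag, note = "no inversion-like window"))
  # longest run of qualifying windows allowing <= gapMax gaps inside
  best <- c(q[1], q[1])
  bestCount <- 1
  for (i in seq_along(q)) {
    for (j in seq(i, length(q))) {
      gaps <- (q[j] - q[i] + 1) - (j - i + 1)
      if (gaps <= gapMax && (j - i + 1) > bestCount) {
        bestCount <- j - i + 1
        best <- c(q[i], q[j])
      }
    }
  }
  chrom <- as.character(GenomicRanges::seqnames(win))[1]
  region <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(GenomicRanges::start(win)[best[1]],
                            GenomicRanges::end(win)[best[2]]))
  new("RegionCall", region = region, windows = diag,
      note = sprintf("%d qualifying windows, longest run %d",
                     length(q), bestCount))
}

#' PCA of the inversion region
#'
#' Same centering and mean imputation as [windowPca()], returning the first
#' two principal components: PC1 separates the three karyotype clusters,
#' PC2 typically separates continents when background differentiation is
#' present.
#'
#' @param g a [GenotypeData-class] object.
#' @param region GRanges of length 1 or "chrom:start-end" string.
#' @param scale scale centered dosages by sqrt(2p(1-p)).
#' @return list with \code{scores} (samples x 2 matrix), \code{pctVar}
#'   (percent variance of PC1 and PC2) and \code{nSites}.
#' @export
regionPca <- function(g, region, scale = FALSE) {
  sub <- subsetByRegion(g, region)
  inp <- .pcaInput(dosages(sub), scale = scale)
  if (inp$nSites < 2) stop("region is (nearly) monomorphic: ",
                           inp$nSites, " polymorphic site(s)")
  k <- min(2, nrow(inp$x) - 1)
  pc <- .leadingPcs(inp$x, k = k)
  list(scores = pc$scores, pctVar = pc$pctVar, nSites = inp$nSites)
}

#' Assign SS/SN/NN karyotypes from the inversion-region PCA
#'
#' k-means with k = 3 (20 restarts, fixed sub-seed) partitions the PC1
#' scores; clusters are ordered by mean PC1 and the middle cluster labelled
#' SN. Outer clusters are labelled from \code{anchors} when provided,
#' otherwise the outer cluster whose members are more frequent at the
#' lowest-latitude location is labelled SS (the southern arrangement).
#' The SN cluster must maximise mean heterozygosity at the region's sites,
#' else the assignment is flagged low-confidence.
#'
#' @param g a [GenotypeData-class] object.
#' @param region GRanges or "chrom:start-end" string of the inversion.
#' @param anchors optional named character vector (sample -> "SS"/"NN")
#'   anchoring the orientation of the outer clusters.
#' @param seed sub-seed for the k-means restarts.
#' @param scale passed to [regionPca()].
#' @return A [KaryotypeCalls-class] object; when fewer than 3 distinct PC1
#'   values exist the assignment fails explicitly rather than forcing a
#'   3-way split.
#' @export
assignKaryotypes <- function(g, region, anchors = NULL, seed = 1,
                             scale = FALSE) {
  stopifnot(is(g, "GenotypeData"))
  if (ncol(g) < 3) stop("need at least 3 samples")
  pca <- regionPca(g, region, scale = scale)
  x <- pca$scores[, 1]
  ids <- rownames(pca$scores)
  kLevels <- c("SS", "SN", "NN")
  if (length(unique(round(x, 10))) < 3) {
    return(new("KaryotypeCalls", sample = ids,
               karyotype = factor(rep(NA_character_, length(ids)),
                                  levels = kLevels),
               pc1 = unname(x), clusterMeans = numeric(0),
               clusterHet = numeric(0), confidence = "failed",
               note = "fewer than 3 distinct PC1 scores (monomorphic arrangement?)"))
  }
  km <- withSeed(deriveSeed(seed, "karyotype-kmeans"),
                 kmeans(x, centers = 3, nstart = 20))
  ord <- order(km$centers)  # low, middle, high mean PC1
  rank <- match(km$cluster, ord)  # 1 = low outer, 2 = middle, 3 = high outer
  sub <- subsetByRegion(g, if (is.character(region)) parseRegion(region)
                        else region)
  het <- .clusterHet(dosages(sub)[, ids, drop = FALSE], rank)
  # orientation of the outer clusters
  lowIsSS <- NA
  note <- ""
  if (!is.null(anchors)) {
    anchorRank <- rank[match(names(anchors), ids)]
    votes <- c(lowSS = sum(anchors == "SS" & anchorRank == 1, na.rm = TRUE) +
                 sum(anchors == "NN" & anchorRank == 3, na.rm = TRUE),
               highSS = sum(anchors == "SS" & anchorRank == 3, na.rm = TRUE) +
                 sum(anchors == "NN" & anchorRank == 1, na.rm = TRUE))
    lowIsSS <- votes["lowSS"] >= votes["highSS"]
    note <- "orientation from anchors"
  } else if ("latitude" %in% names(sampleInfo(g))) {
    latv <- sampleInfo(g)[ids, "latitude"]
    low <- latv == min(latv)
    fLow <- mean(rank[low] == 1)
    fHigh <- mean(rank[low] == 3)
    lowIsSS <- fLow >= fHigh
    note <- "orientation from lowest-latitude location"
  } else {
    lowIsSS <- TRUE
    note <- "no anchors or latitude metadata; arbitrary S/N orientation"
  }
  labels <- if (lowIsSS) c("SS", "SN", "NN") else c("NN", "SN", "SS")
  karyotype <- factor(labels[rank], levels = kLevels)
  confidence <- if (het[2] >= het[1] && het[2] >= het[3]) "ok" else "low"
  if (confidence == "low")
    note <- paste(note, "| SN cluster does not maximise heterozygosity")
  clusterMeans <- setNames(as.numeric(km$centers[ord]), labels)
  new("KaryotypeCalls", sample = ids, karyotype = karyotype,
      pc1 = unname(x), clusterMeans = clusterMeans,
      clusterHet = setNames(het, labels), confidence = confidence,
      note = note)
}
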