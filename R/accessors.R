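#' Dosage matrix of a GenotypeData object
#'
#' @param x a [GenotypeData-class] object.
#' @return Integer matrix, sites x samples, values in \{0, 1, 2, NA\}.
#' @export
dosages <- function(x) {
  stopifnot(is(x, "GenotypeData"))
  SummarizedExperiment::assay(x, "dosage")
}

#' Site positions of a GenotypeData object
#'
#' @param x a [GenotypeData-class] object.
#' @return Width-1 GRanges with \code{ref}/\code{alt} metadata columns.
#' @export
siteRanges <- function(x) {
  stopifnot(is(x, "GenotypeData"))
  SummarizedExperiment::rowRanges(x)
}

#' Sample metadata of a GenotypeData object
#'
#' @param x a [GenotypeData-class] object.
#' @return DataFrame of per-sample metadata.
#' @export
sampleInfo <- function(x) {
  stopifnot(is(x, "GenotypeData"))
  SummarizedExperiment::colData(x)
}

#' Per-site alternate-allele frequencies
#'
#' Frequencies are computed over non-missing dosages only.
#'
#' @param x a [GenotypeData-class] object.
#' @param samples optional character vector restricting to a sample subset.
#' @return Numeric vector, one frequency per site (NaN where all missing).
#' @export
alleleFrequencies <- function(x, samples = NULL) {
  d <- dosages(x)
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(d))
    if (length(missing))
      stop("unknown samples: ", paste(missing, collapse = ", "))
    d <- d[, samples, drop = FALSE]
  }
  rowMeans(d, na.rm = TRUE) / 2
}

#' Restrict a GenotypeData object to a genomic interval
#'
#' @param x a [GenotypeData-class] object.
#' @param region a GRanges of length 1, or a string "chrom:start-end"
#'   (1-based inclusive).
#' @return GenotypeData with the sites falling inside the interval.
#' @export
subsetByRegion <- function(x, region) {
  if (is.character(region)) region <- parseRegion(region)
  hits <- IRanges::overlapsAny(siteRanges(x), region)
  if (!any(hits)) stop("no sites in the requested region")
  x[hits, ]
}

# "chrom:start-end" (1-based inclusive) -> GRanges
parseRegion <- function(spec) {
  m <- regmatches(spec, regexec("^([^:]+):([0-9]+)-([0-9]+)$", spec))[[1]]
  if (length(m) != 4) stop("malformed region '", spec, "'; use chrom:start-end")
  GenomicRanges::GRanges(m[2], IRanges::IRanges(as.integer(m[3]),
                                               as.integer(m[4])))
}

#' Filter sites by minor-allele frequency and missingness
#'
#' Standard pre-PCA site filtering: sites with minor-allele frequency below
#' \code{maf} (computed over non-missing dosages) or with a missing-call
#' fraction above \code{maxMissing} are dropped.
#'
#' @param x a [GenotypeData-class] object.
#' @param maf minimum minor-allele frequency (default 0.05).
#' @param maxMissing maximum fraction of missing dosages per site
#'   (default 0.2).
#' @return GenotypeData restricted to the passing sites.
#' @export
filterSites <- function(x, maf = 0.05, maxMissing = 0.2) {
  d <- dosages(x)
  p <- rowMeans(d, na.rm = TRUE) / 2
  minor <- pmin(p, 1 - p)
  missFrac <- rowMeans(is.na(d))
  keep <- !is.na(minor) & minor >= maf & missFrac <= maxMissing
  if (!any(keep)) stop("no sites pass the filters")
  x[keep, ]
}
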