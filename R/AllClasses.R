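#' @import methods
#' @import S4Vectors
#' @import GenomicRanges
#' @import SummarizedExperiment
NULL

#' GenotypeData: a genotype dosage matrix with site and sample annotation
#'
#' Extends \linkS4class{RangedSummarizedExperiment}. Rows are biallelic SNP
#' sites (a width-1 \linkS4class{GRanges} with \code{ref}/\code{alt} metadata
#' columns), columns are samples, and the single assay \code{"dosage"} holds
#' alternate-allele dosages in \{0, 1, 2, NA\}. Sample metadata (continent,
#' location, latitude) lives in \code{colData}.
#'
#' @seealso [GenotypeData()] for construction, [dosages()], [siteRanges()],
#'   [sampleInfo()] for access.
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
  msg <- NULL
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  if (nrow(object) < 1L || ncol(object) < 1L)
    msg <- c(msg, "need at least one site and one sample")
  if ("dosage" %in% SummarizedExperiment::assayNames(object)) {
    d <- SummarizedExperiment::assay(object, "dosage")
    if (!all(d %in% c(0L, 1L, 2L) | is.na(d)))
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  rr <- SummarizedExperiment::rowRanges(object)
  if (length(rr)) {
    if (!all(GenomicRanges::width(rr) == 1L))
      msg <- c(msg, "sites must be width-1 positions")
    bychr <- split(GenomicRanges::start(rr),
                   as.character(GenomicRanges::seqnames(rr)))
    if (!all(vapply(bychr, function(p) all(diff(p) > 0), logical(1))))
      msg <- c(msg, "positions must be strictly increasing within a chromosome")
    if (!all(c("ref", "alt") %in% names(S4Vectors::mcols(rr))))
      msg <- c(msg, "siteRanges need 'ref' and 'alt' metadata columns")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a GenotypeData object
#'
#' @param dosage integer matrix of alternate-allele dosages, sites x samples,
#'   values in \{0, 1, 2, NA\}.
#' @param sites width-1 [GenomicRanges::GRanges] with metadata columns
#'   \code{ref} and \code{alt} (single bases), one per row of \code{dosage}.
#' @param sampleInfo optional [S4Vectors::DataFrame] (or data.frame) of
#'   per-sample metadata; rownames (or a \code{sample} column) must match
#'   \code{colnames(dosage)}. Conventional columns: \code{continent},
#'   \code{location}, \code{latitude}.
#' @return A [GenotypeData-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr4", IRanges::IRanges(c(10, 20), width = 1),
#'                              ref = "A", alt = "G")
#' gd <- GenotypeData(matrix(c(0L, 1L, 2L, 1L), 2,
#'                    dimnames = list(NULL, c("s1", "s2"))), gr)
#' dosages(gd)
#' @export
GenotypeData <- function(dosage, sites, sampleInfo = NULL) {
  dosage <- as.matrix(dosage)
  mode(dosage) <- "integer"
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("S%03d", seq_len(ncol(dosage)))
  if (is.null(sampleInfo)) {
    sampleInfo <- S4Vectors::DataFrame(row.names = colnames(dosage))
  } else {
    sampleInfo <- as(sampleInfo, "DataFrame")
    if (is.null(rownames(sampleInfo)) && "sample" %in% names(sampleInfo))
      rownames(sampleInfo) <- sampleInfo$sample
    sampleInfo <- sampleInfo[colnames(dosage), , drop = FALSE]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage), rowRanges = sites, colData = sampleInfo)
  new("GenotypeData", se)
}

#' @describeIn GenotypeData compact display
#' @param object a GenotypeData object
#' @export
setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object), "sites x", ncol(object), "samples\n")
  chr <- unique(as.character(GenomicRanges::seqnames(rowRanges(object))))
  cat("  chromosomes:", paste(chr, collapse = ", "), "\n")
  d <- SummarizedExperiment::assay(object, "dosage")
  cat(sprintf("  missing dosages: %.2f%%\n", 100 * mean(is.na(d))))
  if (ncol(colData(object)) > 0)
    cat("  sample metadata:", paste(names(colData(object)), collapse = ", "),
        "\n")
})

#' KaryotypeCalls: per-sample inversion karyotypes from region PCA clustering
#'
#' @slot sample character sample identifiers.
#' @slot karyotype factor with levels SS/SN/NN (NA when assignment failed).
#' @slot pc1 numeric per-sample PC1 score in the inversion region.
#' @slot clusterMeans named numeric, mean PC1 per karyotype cluster.
#' @slot clusterHet named numeric, mean site heterozygosity per cluster.
#' @slot confidence "ok", "low" (heterozygosity check failed) or "failed".
#' @slot note character diagnostic message.
#' @export
setClass("KaryotypeCalls", representation(
  sample = "character", karyotype = "factor", pc1 = "numeric",
  clusterMeans = "numeric", clusterHet = "numeric",
  confidence = "character", note = "character"))

setValidity("KaryotypeCalls", function(object) {
  msg <- NULL
  if (length(object@sample) != length(object@karyotype) ||
      length(object@sample) != length(object@pc1))
    msg <- c(msg, "sample, karyotype and pc1 must have equal length")
  if (!all(levels(object@karyotype) == c("SS", "SN", "NN")))
    msg <- c(msg, "karyotype levels must be SS, SN, NN")
  if (is.null(msg)) TRUE else msg
})

#' @rdname KaryotypeCalls-class
#' @param object a KaryotypeCalls object
#' @export
setMethod("show", "KaryotypeCalls", function(object) {
  cat("KaryotypeCalls for", length(object@sample), "samples\n")
  if (object@confidence == "failed") {
    cat("  assignment FAILED:", object@note, "\n")
  } else {
    print(table(object@karyotype))
    cat("  cluster PC1 means:",
        paste(sprintf("%s=%.3f", names(object@clusterMeans),
                      object@clusterMeans), collapse = ", "), "\n")
    cat("  confidence:", object@confidence, "\n")
  }
})

#' Extract karyotype labels
#'
#' @param x a [KaryotypeCalls-class] object.
#' @return Named factor of SS/SN/NN labels.
#' @export
karyotypes <- function(x) {
  stopifnot(is(x, "KaryotypeCalls"))
  setNames(x@karyotype, x@sample)
}

#' RegionCall: inversion interval called from windowed PCA trimodality
#'
#' @slot region GRanges of length 1 (empty when nothing qualified).
#' @slot windows DataFrame of per-window diagnostics (chosen k, BIC values,
#'   cluster heterozygosities, qualification flag).
#' @slot note character.
#' @export
setClass("RegionCall", representation(
  region = "GRanges", windows = "DataFrame", note = "character"))

#' @rdname RegionCall-class
#' @param object a RegionCall object
#' @export
setMethod("show", "RegionCall", function(object) {
  if (length(object@region) == 0) {
    cat("RegionCall: no inversion-like region.", object@note, "\n")
  } else {
    cat("RegionCall:", as.character(object@region), "\n")
    cat("  qualifying windows:", sum(object@windows$inversionLike), "of",
        nrow(object@windows), "\n")
  }
})

#' Called inversion interval
#' @param x a [RegionCall-class] object.
#' @return GRanges (possibly empty).
#' @export
calledRegion <- function(x) {
  stopifnot(is(x, "RegionCall"))
  x@region
}

#' WindowPcaSet: sliding-window PCA results along one chromosome
#'
#' @slot windows GRanges of windows with metadata nSites, pctVar, skipped.
#' @slot scores matrix windows x samples of PC1 scores (NA rows = skipped).
#' @export
setClass("WindowPcaSet",
         representation(windows = "GRanges", scores = "matrix"))

#' @rdname WindowPcaSet-class
#' @param object a WindowPcaSet object
#' @export
setMethod("show", "WindowPcaSet", function(object) {
  cat("WindowPcaSet:", length(object@windows), "windows,",
      ncol(object@scores), "samples;",
      sum(object@windows$skipped), "skipped\n")
})

#' FstResult: Hudson FST components per site, per window and global
#'
#' @slot groups character(2), labels of the compared groups.
#' @slot perSite DataFrame: position, numerator, denominator.
#' @slot windows DataFrame: window start/end, nSites, fst.
#' @slot global numeric, ratio-of-averages FST over all usable sites.
#' @export
setClass("FstResult", representation(
  groups = "character", perSite = "DataFrame", windows = "DataFrame",
  global = "numeric"))

#' @rdname FstResult-class
#' @param object an FstResult object
#' @export
setMethod("show", "FstResult", function(object) {
  cat(sprintf("FstResult %s vs %s: global FST = %.4f (%d sites, %d windows)\n",
              object@groups[1], object@groups[2], object@global,
              nrow(object@perSite), nrow(object@windows)))
})

#' Global ratio-of-averages FST
#' @param x an [FstResult-class] object.
#' @return numeric scalar.
#' @export
globalFst <- function(x) {
  stopifnot(is(x, "FstResult"))
  x@global
}

#' HaplotypeNetwork: epsilon = 0 minimum spanning network
#'
#' Nodes are unique haplotypes (identical sequences collapsed, with
#' multiplicity); edges carry integer substitution counts. For epsilon = 0 the
#' edge set is the union of all minimum spanning trees of the complete
#' haplotype distance graph.
#'
#' @slot haplotypes DNAStringSet of unique haplotypes.
#' @slot multiplicity integer count per unique haplotype.
#' @slot membership integer index mapping each input sequence to its node.
#' @slot edges data.frame with columns from, to, steps.
#' @slot epsilon numeric (only 0 supported).
#' @export
setClass("HaplotypeNetwork", representation(
  haplotypes = "DNAStringSet", multiplicity = "integer",
  membership = "integer", edges = "data.frame", epsilon = "numeric"))

setValidity("HaplotypeNetwork", function(object) {
  msg <- NULL
  if (length(object@haplotypes) != length(object@multiplicity))
    msg <- c(msg, "one multiplicity per unique haplotype required")
  if (nrow(object@edges) && any(object@edges$steps < 1))
    msg <- c(msg, "edge step counts must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' @rdname HaplotypeNetwork-class
#' @param object a HaplotypeNetwork object
#' @export
setMethod("show", "HaplotypeNetwork", function(object) {
  cat("HaplotypeNetwork:", length(object@haplotypes), "unique haplotypes (",
      sum(object@multiplicity), "sequences ),", nrow(object@edges),
      "edges, epsilon =", object@epsilon, "\n")
})

#' Network edge list
#' @param x a [HaplotypeNetwork-class] object.
#' @return data.frame with columns from, to, steps.
#' @export
networkEdges <- function(x) {
  stopifnot(is(x, "HaplotypeNetwork"))
  x@edges
}

#' ClineFit: aggregated binomial regression of arrangement frequency
#'
#' @slot predictor character, name of the predictor column.
#' @slot coefficients named numeric(2): intercept and slope.
#' @slot se named numeric(2) standard errors.
#' @slot lrtChisq numeric, null minus residual deviance (df = 1).
#' @slot lrtP numeric p-value of the likelihood-ratio test.
#' @slot devianceR2 numeric, 1 - residual/null deviance.
#' @slot nullDeviance,residDeviance numeric.
#' @slot separation logical, quasi-complete separation flag.
#' @slot model the underlying stats::glm fit.
#' @slot data data.frame used for the fit.
#' @export
setClass("ClineFit", representation(
  predictor = "character", coefficients = "numeric", se = "numeric",
  lrtChisq = "numeric", lrtP = "numeric", devianceR2 = "numeric",
  nullDeviance = "numeric", residDeviance = "numeric",
  separation = "logical", model = "ANY", data = "data.frame"))

#' @rdname ClineFit-class
#' @param object a ClineFit object
#' @export
setMethod("show", "ClineFit", function(object) {
  cat(sprintf(
    "ClineFit (logit link) on %s:\n  slope %.4f (SE %.4f), LRT chisq %.2f (df 1, p %.3g), deviance R2 %.2f\n",
    object@predictor, object@coefficients[2], object@se[2],
    object@lrtChisq, object@lrtP, object@devianceR2))
  if (object@separation)
    cat("  WARNING: quasi-complete separation; coefficients unstable\n")
})

#' Cline slope on the logit scale
#' @param x a [ClineFit-class] object.
#' @return numeric scalar (per unit of the predictor).
#' @export
clineSlope <- function(x) {
  stopifnot(is(x, "ClineFit"))
  unname(x@coefficients[2])
}

#' TpcFit: quadratic thermal performance curve and derived thermal traits
#'
#' Viability is modelled as \eqn{a T^2 + b T + c}. Derived traits (for a < 0):
#' rmax = c - b^2/(4a); Topt = -b/(2a); CTmin/CTmax the real roots; tolerance
#' = CTmax - CTmin; breadth = width where viability >= 0.8 rmax.
#'
#' @slot group character label of the fitted group.
#' @slot coefficients named numeric(3): a, b, c.
#' @slot traits named numeric: rmax, Topt, CTmin, CTmax, tolerance, breadth
#'   (NA when undefined, e.g. non-concave fit or complex roots).
#' @slot rss numeric residual sum of squares (weighted).
#' @slot n integer number of observations.
#' @export
setClass("TpcFit", representation(
  group = "character", coefficients = "numeric", traits = "numeric",
  rss = "numeric", n = "integer"))

#' @rdname TpcFit-class
#' @param object a TpcFit object
#' @export
setMethod("show", "TpcFit", function(object) {
  co <- object@coefficients
  cat(sprintf("TpcFit [%s]: viability = %.4g T^2 + %.4g T + %.4g (n = %d)\n",
              object@group, co["a"], co["b"], co["c"], object@n))
  tr <- object@traits
  cat(sprintf(
    "  rmax %.3f | Topt %.2f | CTmin %.2f | CTmax %.2f | tolerance %.2f | breadth %.2f\n",
    tr["rmax"], tr["Topt"], tr["CTmin"], tr["CTmax"], tr["tolerance"],
    tr["breadth"]))
})

#' Derived thermal traits of a fitted TPC
#' @param x a [TpcFit-class] object.
#' @return Named numeric vector (rmax, Topt, CTmin, CTmax, tolerance, breadth).
#' @export
thermalTraits <- function(x) {
  stopifnot(is(x, "TpcFit"))
  x@traits
}

#' ConcordanceResult: marker-vs-PCA karyotype agreement
#'
#' @slot nCompared,nConcordant integer.
#' @slot rate numeric, percent concordant rounded to the nearest integer.
#' @slot discordant character, sample IDs with disagreeing calls.
#' @export
setClass("ConcordanceResult", representation(
  nCompared = "integer", nConcordant = "integer", rate = "numeric",
  discordant = "character"))

#' @rdname ConcordanceResult-class
#' @param object a ConcordanceResult object
#' @export
setMethod("show", "ConcordanceResult", function(object) {
  cat(sprintf("Concordance: %d/%d = %d%%\n", object@nConcordant,
              object@nCompared, object@rate))
  if (length(object@discordant))
    cat("  discordant:", paste(object@discordant, collapse = ", "), "\n")
})

#' SimulationConfig: parameters of the synthetic inversion dataset
#'
#' Defaults emulate the study conditions: a two-continent sample with
#' background differentiation FST ~ 0.13 (Balding-Nichols), an inversion
#' segment in which the two arrangements are deeply diverged
#' (analytic arrangement-FST target ~ 0.62 at the defaults), logistic
#' karyotype-frequency clines along latitude (slope -0.11 per degree on the
#' logit scale), and Hardy-Weinberg karyotype proportions within locations.
#'
#' @slot latitudes numeric, one latitude (degrees) per location.
#' @slot samplesPerLocation integer.
#' @slot nSites integer number of SNP sites on the chromosome.
#' @slot chromosomeLength integer bp.
#' @slot inversionStart,inversionEnd integer bp (1-based closed interval).
#' @slot beta0,beta1 numeric cline intercept/slope on the logit scale.
#' @slot fBg numeric Balding-Nichols differentiation parameter in [0, 1).
#' @slot dInv numeric proportion of inversion sites fixed between arrangements.
#' @slot muPoly numeric shared-polymorphism rate inside the inversion.
#' @slot seed integer, mandatory.
#' @export
setClass("SimulationConfig", representation(
  latitudes = "numeric", samplesPerLocation = "integer", nSites = "integer",
  chromosomeLength = "integer", inversionStart = "integer",
  inversionEnd = "integer", beta0 = "numeric", beta1 = "numeric",
  fBg = "numeric", dInv = "numeric", muPoly = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- NULL
  if (object@fBg < 0 || object@fBg >= 1) msg <- c(msg, "fBg must be in [0, 1)")
  if (object@dInv < 0 || object@dInv > 1) msg <- c(msg, "dInv in [0, 1]")
  if (object@muPoly < 0 || object@muPoly > 1) msg <- c(msg, "muPoly in [0, 1]")
  if (object@inversionStart < 1 ||
      object@inversionEnd > object@chromosomeLength ||
      object@inversionStart >= object@inversionEnd)
    msg <- c(msg, "inversion interval must lie within the chromosome")
  if (!is.finite(object@beta1)) msg <- c(msg, "beta1 must be finite")
  if (object@samplesPerLocation < 1) msg <- c(msg, "need >= 1 sample/location")
  if (is.null(msg)) TRUE else msg
})

#' @rdname SimulationConfig-class
#' @param object a SimulationConfig object
#' @export
setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", length(object@latitudes), "locations x",
      object@samplesPerLocation, "samples;", object@nSites, "sites on",
      object@chromosomeLength, "bp\n")
  cat(sprintf("  inversion %d-%d; cline logit(p) = %.2f %+.2f lat\n",
              object@inversionStart, object@inversionEnd, object@beta0,
              object@beta1))
  cat(sprintf("  fBg %.2f, dInv %.2f, muPoly %.3f, seed %d (FST target %.2f)\n",
              object@fBg, object@dInv, object@muPoly, object@seed,
              targetArrangementFst(object)))
})
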