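# Shared fixture builders (all generated in code; nothing binary on disk).

locationTablePath <- function() {
  system.file("extdata", "european_locations.tsv", package = "KaryoCline")
}

enzymeCatalogue <- function() {
  readEnzymeCatalogue(system.file("extdata", "enzymes.tsv",
                                  package = "KaryoCline"))
}

ecoRI <- function() {
  data.frame(name = "EcoRI", site = "GAATTC", cutOffset = 1L)
}

# small GenotypeData built by hand
toyGenotypes <- function(dosage, positions = NULL, chrom = "chr4",
                         sampleInfo = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(positions)) positions <- seq_len(nrow(dosage)) * 10L
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("s%02d", seq_len(ncol(dosage)))
  sites <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(positions, width = 1),
    ref = "A", alt = "G")
  GenotypeData(dosage, sites, sampleInfo = sampleInfo)
}

# genotype matrix over the arrangement-difference positions of a simulated
# marker region: reference (= S arrangement) is REF, the N base is ALT
markerRegionGenotypes <- function(mr, nSS = 4, nSN = 4, nNN = 4) {
  diffs <- sort(c(mr$truth$snpPos, mr$truth$backgroundPositions))
  sC <- strsplit(mr$sSeq, "")[[1]]
  nC <- strsplit(mr$nSeq, "")[[1]]
  k <- rep(c("SS", "SN", "NN"), c(nSS, nSN, nNN))
  dos <- c(SS = 0L, SN = 1L, NN = 2L)[k]
  dosage <- matrix(rep(dos, each = length(diffs)), length(diffs), length(k),
                   dimnames = list(NULL, sprintf("M%02d", seq_along(k))))
  sites <- GenomicRanges::GRanges(
    "contig1", IRanges::IRanges(diffs, width = 1),
    ref = sC[diffs], alt = nC[diffs])
  list(genotypes = GenotypeData(dosage, sites),
       karyotypes = setNames(k, colnames(dosage)))
}

# four homokaryotypic lines with an opposite-sign karyotype-by-continent
# viability effect (SS advantage in America, NN advantage in Europe)
crossedViabilityTable <- function(seed, strongScale = 1.35,
                                  weakScale = 0.77) {
  base <- c(a = -0.00215, b = 0.086, c = -0.6)
  mk <- function(scale, karyotype, continent, s)
    simulateViabilityExperiment(a = base["a"] * scale, b = base["b"] * scale,
                                c = base["c"] * scale, seed = s,
                                karyotype = karyotype, continent = continent)
  rbind(mk(strongScale, "SS", "America", seed),
        mk(weakScale, "NN", "America", seed + 1),
        mk(weakScale, "SS", "Europe", seed + 2),
        mk(strongScale, "NN", "Europe", seed + 3))
}
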