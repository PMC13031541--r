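#' Construct a simulation configuration
#'
#' Defaults are the study conditions the package is validated against:
#' six locations spanning the European latitudinal range, 40 diploids per
#' location split between two continents, a 1 Mb chromosome carrying a
#' 400 kb inversion, background continental differentiation fBg = 0.13,
#' a logit cline with slope -0.11 per degree latitude, and an inversion
#' divergence calibrated so the analytic between-arrangement FST target is
#' 0.62 (dInv = 0.3 fixed differences, shared polymorphism rate 0.668).
#'
#' @param latitudes numeric vector of location latitudes (degrees).
#' @param samplesPerLocation diploid individuals per location.
#' @param nSites number of SNP sites.
#' @param chromosomeLength chromosome length in bp.
#' @param inversionStart,inversionEnd inversion interval (1-based closed).
#' @param beta0,beta1 cline intercept/slope on the logit scale
#'   (p_S = plogis(beta0 + beta1 * latitude)).
#' @param fBg Balding-Nichols background differentiation parameter.
#' @param dInv proportion of inversion sites fixed between arrangements.
#' @param muPoly shared-polymorphism rate among non-fixed inversion sites.
#' @param seed integer RNG seed (mandatory).
#' @return A [SimulationConfig-class] object.
#' @export
simulationConfig <- function(latitudes = seq(48.7, 68.4, length.out = 6),
                             samplesPerLocation = 40,
                             nSites = 2000,
                             chromosomeLength = 1000000,
                             inversionStart = 300001,
                             inversionEnd = 700000,
                             beta0 = 6.23, beta1 = -0.11,
                             fBg = 0.13, dInv = 0.3, muPoly = 0.668,
                             seed) {
  if (missing(seed)) stop("a seed is mandatory in the simulation config")
  new("SimulationConfig", latitudes = as.numeric(latitudes),
      samplesPerLocation = as.integer(samplesPerLocation),
      nSites = as.integer(nSites),
      chromosomeLength = as.integer(chromosomeLength),
      inversionStart = as.integer(inversionStart),
      inversionEnd = as.integer(inversionEnd),
      beta0 = beta0, beta1 = beta1, fBg = fBg, dInv = dInv, muPoly = muPoly,
      seed = as.integer(seed))
}

#' Analytic between-arrangement FST target of a configuration
#'
#' Ratio-of-averages Hudson FST expected between the two homokaryote groups
#' inside the inversion: fixed sites contribute (numerator, denominator)
#' = (1, 1); shared polymorphic sites contribute (0, 2pq) in expectation with
#' p ~ U(0.1, 0.9), so E[2pq] = 0.3933. The target is
#' dInv / (dInv + (1 - dInv) * muPoly * 0.3933).
#'
#' @param config a [SimulationConfig-class] object.
#' @return numeric scalar.
#' @export
targetArrangementFst <- function(config) {
  e2pq <- 2 * (0.5 - (0.25 + 0.8^2 / 12))  # E[2p(1-p)], p ~ U(0.1, 0.9)
  d <- config@dInv
  d / (d + (1 - d) * config@muPoly * e2pq)
}

#' Simulate a two-continent genotype dataset carrying a polymorphic inversion
#'
#' Per location, each individual's karyotype is drawn from Hardy-Weinberg
#' proportions with p_S = plogis(beta0 + beta1 * latitude). Outside the
#' inversion, allele frequencies are continent-specific Balding-Nichols draws
#' around a shared ancestral frequency (parameter fBg). Inside the inversion
#' there is no recombination between arrangement backgrounds: a fraction dInv
#' of sites is fixed between the S and N arrangements, a fraction muPoly of
#' the remainder is polymorphic with the same frequency in both arrangements,
#' and the rest is monomorphic.
#'
#' @param config a [SimulationConfig-class] object.
#' @return list with elements \code{genotypes} (a [GenotypeData-class]) and
#'   \code{truth} (per-individual karyotype, the inversion interval, the
#'   cline coefficients, and per-site arrangement allele frequencies).
#' @export
simulateInversionDataset <- function(config) {
  validObject(config)
  withSeed(deriveSeed(config@seed, "inversion-dataset"), {
    nLoc <- length(config@latitudes)
    nInd <- nLoc * config@samplesPerLocation
    positions <- sort(sample.int(config@chromosomeLength, config@nSites))
    inInv <- positions >= config@inversionStart &
      positions <= config@inversionEnd
    if (sum(inInv) < 2)
      stop("config error: inversion interval contains fewer than 2 sites")

    continents <- rep(c("America", "Europe"), length.out = nLoc)
    loc <- rep(seq_len(nLoc), each = config@samplesPerLocation)
    lat <- config@latitudes[loc]
    continent <- continents[loc]
    pS <- invLogit(config@beta0 + config@beta1 * lat)
    # number of S arrangements per individual: HWE = Binomial(2, pS)
    nS <- rbinom(nInd, 2L, pS)
    karyotype <- c("NN", "SN", "SS")[nS + 1L]

    nSites <- config@nSites
    # background: ancestral freq + Balding-Nichols continent-specific freqs
    pAnc <- runif(nSites, 0.05, 0.95)
    drawBN <- function(p) {
      if (config@fBg == 0) return(p)
      shape <- (1 - config@fBg) / config@fBg
      rbeta(length(p), shape * p, shape * (1 - p))
    }
    pAm <- drawBN(pAnc)
    pEu <- drawBN(pAnc)

    # inversion site classes and arrangement-specific frequencies
    nIn <- sum(inInv)
    cls <- sample(c("fixed", "shared", "mono"), nIn, replace = TRUE,
                  prob = c(config@dInv, (1 - config@dInv) * config@muPoly,
                           (1 - config@dInv) * (1 - config@muPoly)))
    fS <- numeric(nIn)
    fN <- numeric(nIn)
    isFix <- cls == "fixed"
    sCarriesAlt <- sample(c(TRUE, FALSE), sum(isFix), replace = TRUE)
    fS[isFix] <- as.numeric(sCarriesAlt)
    fN[isFix] <- as.numeric(!sCarriesAlt)
    isShared <- cls == "shared"
    fShared <- runif(sum(isShared), 0.1, 0.9)
    fS[isShared] <- fShared
    fN[isShared] <- fShared
    # monomorphic sites stay at frequency 0 in both arrangements

    dosage <- matrix(NA_integer_, nSites, nInd)
    idxIn <- which(inInv)
    idxOut <- which(!inInv)
    for (i in seq_len(nInd)) {
      pBg <- if (continent[i] == "America") pAm[idxOut] else pEu[idxOut]
      dosage[idxOut, i] <- rbinom(length(idxOut), 2L, pBg)
      # one allele per arrangement copy, no recombination between backgrounds
      f1 <- if (nS[i] >= 1) fS else fN
      f2 <- if (nS[i] == 2) fS else fN
      dosage[idxIn, i] <- rbinom(nIn, 1L, f1) + rbinom(nIn, 1L, f2)
    }
    ids <- sprintf("IND%03d", seq_len(nInd))
    colnames(dosage) <- ids
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nSites, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    sites <- GenomicRanges::GRanges("chr4",
                                    IRanges::IRanges(positions, width = 1),
                                    ref = ref, alt = unname(alt))
    info <- S4Vectors::DataFrame(
      sample = ids, location = sprintf("L%02d", loc), latitude = lat,
      continent = continent, row.names = ids)
    genotypes <- GenotypeData(dosage, sites, sampleInfo = info)
    truth <- list(
      karyotype = setNames(karyotype, ids),
      inversion = GenomicRanges::GRanges(
        "chr4", IRanges::IRanges(config@inversionStart,
                                 config@inversionEnd)),
      beta0 = config@beta0, beta1 = config@beta1,
      siteClass = cls, inversionSites = positions[idxIn],
      freqS = fS, freqN = fN,
      fstTarget = targetArrangementFst(config))
    list(genotypes = genotypes, truth = truth)
  })
}

#' Simulate karyotype count tables along a latitudinal cline
#'
#' At each latitude, p = plogis(beta0 + beta1 * latitude) and karyotype counts
#' are multinomial with Hardy-Weinberg proportions (p^2, 2p(1-p), (1-p)^2).
#' The annual mean temperature column is filled with the linear
#' latitude-temperature relation of the European sampling range
#' (temperature = 29.4 - 0.366 * latitude).
#'
#' @param beta0,beta1 cline coefficients on the logit scale.
#' @param latitudes numeric vector of location latitudes.
#' @param n diploid individuals per location (scalar or per-location vector).
#' @param seed integer RNG seed.
#' @return data.frame in the location-table layout of [readLocationTable()].
#' @export
simulateClineCounts <- function(beta0, beta1, latitudes, n, seed) {
  stopifnot(all(n >= 1))
  n <- rep_len(as.integer(n), length(latitudes))
  withSeed(deriveSeed(seed, "cline-counts"), {
    p <- invLogit(beta0 + beta1 * latitudes)
    counts <- t(vapply(seq_along(latitudes), function(i) {
      rmultinom(1, n[i], c(p[i]^2, 2 * p[i] * (1 - p[i]), (1 - p[i])^2))[, 1]
    }, integer(3)))
    data.frame(location = sprintf("L%02d", seq_along(latitudes)),
               latitude = latitudes,
               longitude = 0,
               temperature = 29.4 - 0.366 * latitudes,
               n_SS = counts[, 1], n_SN = counts[, 2], n_NN = counts[, 3])
  })
}

# does `seq` contain a recognition-site match (either strand) overlapping
# positions pos..pos+width-1?
.hasSiteNear <- function(seq, site, pos, width = 1) {
  l <- nchar(site)
  from <- max(1, pos - l + 1)
  to <- min(nchar(seq), pos + width - 1 + l - 1)
  window <- substring(seq, from, to)
  pats <- unique(c(site, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(site)))))
  any(vapply(pats, function(p) {
    length(Biostrings::matchPattern(p, Biostrings::DNAString(window),
                                    fixed = FALSE)) > 0
  }, logical(1)))
}

.countSites <- function(seq, site) {
  pats <- unique(c(site, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(site)))))
  sum(vapply(pats, function(p) {
    length(Biostrings::matchPattern(p, Biostrings::DNAString(seq),
                                    fixed = FALSE))
  }, integer(1)))
}

#' Simulate a marker region with a planted diagnostic PCR-RFLP site
#'
#' Builds a reference contig whose S-arrangement sequence carries the
#' enzyme's recognition site spanning a diagnostic SNP, while the
#' N-arrangement sequence differs at that SNP and lacks the site. Background
#' substitutions between the arrangements are injected at a configurable
#' rate, avoiding positions that would create or destroy a recognition-site
#' match. The reference is the S sequence (the enzyme cuts S, not N). A
#' single CDS covering the amplicon is returned as annotation.
#'
#' @param regionLength contig length in bp.
#' @param snpPos position of the diagnostic SNP (default: contig centre).
#' @param enzyme single-row data.frame with \code{name}, \code{site},
#'   \code{cutOffset} (see [readEnzymeCatalogue()]); default EcoRI G^AATTC.
#' @param ampliconLength diagnostic amplicon length (default 667 bp).
#' @param backgroundRate per-bp substitution rate between arrangements
#'   outside the diagnostic site.
#' @param avoidEnzymes enzyme catalogue whose recognition sites background
#'   substitutions must not touch in either arrangement, so the planted SNP
#'   remains the unique diagnostic restriction contrast (default: the
#'   packaged catalogue of common 6-cutters).
#' @param seed integer RNG seed.
#' @return list: \code{reference} (named DNAStringSet, = S arrangement),
#'   \code{features} (GRanges, one CDS), \code{sSeq}, \code{nSeq},
#'   \code{sAmplicon}, \code{nAmplicon} and \code{truth} (SNP position,
#'   alleles, enzyme, amplicon interval).
#' @export
simulateMarkerRegion <- function(regionLength = 1500, snpPos = NULL,
                                 enzyme = data.frame(name = "EcoRI",
                                                     site = "GAATTC",
                                                     cutOffset = 1L),
                                 ampliconLength = 667,
                                 backgroundRate = 0.01,
                                 avoidEnzymes = NULL, seed) {
  if (is.null(avoidEnzymes))
    avoidEnzymes <- readEnzymeCatalogue(
      system.file("extdata", "enzymes.tsv", package = "KaryoCline"))
  site <- toupper(enzyme$site[1])
  l <- nchar(site)
  if (is.null(snpPos)) snpPos <- regionLength %/% 2
  # the SNP sits on the 4th base of the recognition site
  siteStart <- snpPos - 3L
  if (siteStart < 1 || siteStart + l - 1 > regionLength)
    stop("config error: enzyme site does not fit at the diagnostic position")
  half <- (ampliconLength - 1) %/% 2
  ampStart <- snpPos - half
  ampEnd <- ampStart + ampliconLength - 1
  if (ampStart < 1 || ampEnd > regionLength)
    stop("config error: amplicon does not fit inside the region")
  withSeed(deriveSeed(seed, "marker-region"), {
    bases <- c("A", "C", "G", "T")
    s <- sample(bases, regionLength, replace = TRUE)
    # plant the recognition site (S arrangement carries it)
    siteBases <- strsplit(site, "")[[1]]
    concrete <- vapply(siteBases, function(b) sample(IUPAC_SETS[[b]], 1),
                       character(1))
    s[siteStart:(siteStart + l - 1)] <- concrete
    # remove accidental site matches elsewhere (either strand): mutate one
    # base inside each stray match until only the planted site remains
    planted <- siteStart:(siteStart + l - 1)
    pats <- unique(c(site, as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(site)))))
    for (tries in 1:200) {
      str <- paste(s, collapse = "")
      strays <- integer(0)
      for (p in pats) {
        st <- Biostrings::start(Biostrings::matchPattern(
          p, Biostrings::DNAString(str), fixed = FALSE))
        strays <- c(strays, st[st != siteStart])
      }
      if (!length(strays)) break
      cols <- setdiff(strays[1]:(strays[1] + l - 1), planted)
      j <- cols[sample.int(length(cols), 1)]
      s[j] <- sample(setdiff(bases, s[j]), 1)
    }
    sSeq <- s
    # N arrangement: break the site at the SNP
    nSeq <- s
    sAllele <- s[snpPos]
    repeat {
      nAllele <- sample(setdiff(bases, sAllele), 1)
      nSeq[snpPos] <- nAllele
      if (!.hasSiteNear(paste(nSeq, collapse = ""), site, snpPos)) break
    }
    # background substitutions between arrangements
    nBg <- rbinom(1, regionLength, backgroundRate)
    avoid <- (siteStart - l):(siteStart + 2 * l)
    candidates <- setdiff(seq_len(regionLength), avoid)
    bgPos <- sort(sample(candidates, min(nBg, length(candidates))))
    allSites <- unique(c(site, avoidEnzymes$site))
    touchesAnySite <- function(seqChars, j) {
      str <- paste(seqChars, collapse = "")
      any(vapply(allSites, function(ste) .hasSiteNear(str, ste, j),
                 logical(1)))
    }
    for (j in bgPos) {
      # skip positions already inside a recognition-site match of either
      # arrangement, and reject substitutions that would create one
      if (touchesAnySite(sSeq, j) || touchesAnySite(nSeq, j)) next
      for (tries in 1:8) {
        newBase <- sample(setdiff(bases, nSeq[j]), 1)
        old <- nSeq[j]
        nSeq[j] <- newBase
        if (!touchesAnySite(nSeq, j)) break
        nSeq[j] <- old
      }
    }
    sStr <- paste(sSeq, collapse = "")
    nStr <- paste(nSeq, collapse = "")
    reference <- Biostrings::DNAStringSet(c(contig1 = sStr))
    features <- GenomicRanges::GRanges(
      "contig1", IRanges::IRanges(ampStart, ampEnd),
      type = "CDS", ID = "CDS1", strand = "+")
    list(reference = reference, features = features,
         sSeq = sStr, nSeq = nStr,
         sAmplicon = substring(sStr, ampStart, ampEnd),
         nAmplicon = substring(nStr, ampStart, ampEnd),
         truth = list(snpPos = snpPos, sAllele = sAllele, nAllele = nAllele,
                      enzyme = enzyme, ampliconStart = ampStart,
                      ampliconEnd = ampEnd,
                      backgroundPositions = setdiff(
                        which(sSeq != nSeq), snpPos)))
  })
}

#' Simulate an egg-to-adult viability experiment under a quadratic TPC
#'
#' Survivors per replicate are Binomial(eggs, v(T)) with
#' v(T) = a T^2 + b T + c clipped to [0, 1]. The default quadratic has its
#' vertex at 20 degrees C with rmax 0.26 and zero-crossings near 9 and 31
#' degrees C, so viability at 10 degrees C is below 5 percent.
#'
#' @param a,b,c quadratic coefficients of the thermal performance curve.
#' @param temperatures vector of experimental temperatures (degrees C).
#' @param eggs eggs per replicate batch.
#' @param replicates replicate batches per temperature.
#' @param seed integer RNG seed.
#' @param karyotype,continent labels stamped on every row (for assembling
#'   multi-line designs).
#' @return data.frame with one row per replicate: karyotype, continent,
#'   temperature, replicate, eggs, adults.
#' @export
simulateViabilityExperiment <- function(a = -0.00215, b = 0.086, c = -0.6,
                                        temperatures = c(10, 15, 20, 25, 30),
                                        eggs = 100, replicates = 6, seed,
                                        karyotype = "SS",
                                        continent = "America") {
  stopifnot(eggs >= 1, replicates >= 1)
  withSeed(deriveSeed(seed, paste0("viability-", karyotype, continent)), {
    grid <- expand.grid(replicate = seq_len(replicates),
                        temperature = temperatures)
    v <- a * grid$temperature^2 + b * grid$temperature + c
    v <- pmin(pmax(v, 0), 1)
    data.frame(karyotype = karyotype, continent = continent,
               temperature = grid$temperature, replicate = grid$replicate,
               eggs = as.integer(eggs),
               adults = rbinom(nrow(grid), as.integer(eggs), v))
  })
}
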