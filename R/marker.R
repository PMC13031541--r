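#' Candidate diagnostic SNPs: coding and fixed between homokaryote groups
#'
#' Applies the first two marker-design rules: the SNP must fall inside a CDS
#' feature, and the alternate-allele frequency difference between the SS and
#' NN homokaryote groups (over non-missing calls) must be at least
#' \code{minDiff} (default 0.99, near-fixation).
#'
#' @param g a [GenotypeData-class] object.
#' @param karyotypes named SS/SN/NN labels (a [KaryotypeCalls-class] object
#'   or a named character/factor vector).
#' @param features GRanges of annotation (from [readGff3Features()]); only
#'   type == "CDS" rows are used.
#' @param minDiff minimum |freq_alt(SS) - freq_alt(NN)|.
#' @return DataFrame of retained SNPs with per-group frequencies, host CDS
#'   ID, and the inferred S/N alleles (the allele enriched in SS is the
#'   S-allele).
#' @export
candidateDiagnosticSnps <- function(g, karyotypes, features, minDiff = 0.99) {
  stopifnot(is(g, "GenotypeData"))
  if (is(karyotypes, "KaryotypeCalls")) karyotypes <- karyotypes(karyotypes)
  karyotypes <- setNames(as.character(karyotypes), names(karyotypes))
  ss <- names(karyotypes)[karyotypes == "SS" & !is.na(karyotypes)]
  nn <- names(karyotypes)[karyotypes == "NN" & !is.na(karyotypes)]
  if (length(ss) < 2 || length(nn) < 2)
    stop("need at least 2 SS and 2 NN homokaryotes")
  cds <- features[features$type == "CDS"]
  rr <- siteRanges(g)
  hit <- IRanges::overlapsAny(rr, cds)
  idx <- which(hit)
  d <- dosages(g)
  res <- lapply(idx, function(i) {
    dS <- d[i, ss]
    dN <- d[i, nn]
    if (sum(!is.na(dS)) < 2 || sum(!is.na(dN)) < 2) return(NULL)
    fS <- mean(dS, na.rm = TRUE) / 2
    fN <- mean(dN, na.rm = TRUE) / 2
    if (abs(fS - fN) < minDiff) return(NULL)
    ov <- IRanges::findOverlaps(rr[i], cds)
    cdsId <- cds$ID[S4Vectors::subjectHits(ov)[1]]
    S4Vectors::DataFrame(
      chrom = as.character(GenomicRanges::seqnames(rr))[i],
      position = GenomicRanges::start(rr)[i],
      ref = S4Vectors::mcols(rr)$ref[i], alt = S4Vectors::mcols(rr)$alt[i],
      freqAltSS = fS, freqAltNN = fN, freqDiff = abs(fS - fN),
      sAllele = if (fS > fN) S4Vectors::mcols(rr)$alt[i]
                else S4Vectors::mcols(rr)$ref[i],
      nAllele = if (fS > fN) S4Vectors::mcols(rr)$ref[i]
                else S4Vectors::mcols(rr)$alt[i],
      cdsId = cdsId)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(S4Vectors::DataFrame(chrom = character(0), position = integer(0),
                                ref = character(0), alt = character(0),
                                freqAltSS = numeric(0),
                                freqAltNN = numeric(0),
                                freqDiff = numeric(0),
                                sAllele = character(0),
                                nAllele = character(0), cdsId = character(0)))
  do.call(rbind, res)
}

# recognition-site match intervals (both strands) in a sequence;
# returns IRanges of match start/end on the forward sequence
.siteMatches <- function(seq, site) {
  subj <- Biostrings::DNAString(seq)
  fwd <- Biostrings::matchPattern(site, subj, fixed = FALSE)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(site)))
  out <- IRanges::IRanges(Biostrings::start(fwd), Biostrings::end(fwd))
  if (rc != site) {
    rev <- Biostrings::matchPattern(rc, subj, fixed = FALSE)
    out <- c(out, IRanges::IRanges(Biostrings::start(rev),
                                   Biostrings::end(rev)))
  }
  unique(out)
}

#' In-silico restriction digestion
#'
#' Finds all recognition-site matches on the forward strand and of the
#' reverse complement, places cuts at the enzyme's offset within each match
#' (EcoRI-style G^AATTC has offset 1; reverse-strand matches of
#' non-palindromic sites are cut at the mirrored offset), and returns
#' fragment lengths 5' to 3'. Fragment lengths always sum to the sequence
#' length.
#'
#' @param seq a DNAString/character sequence.
#' @param enzyme single-row data.frame (or list) with \code{name},
#'   \code{site}, \code{cutOffset}.
#' @return Integer vector of fragment lengths (a single full-length fragment
#'   when no site matches).
#' @export
inSilicoDigest <- function(seq, enzyme) {
  seq <- toupper(as.character(seq))
  if (!nchar(seq)) stop("empty sequence")
  site <- toupper(enzyme$site[1])
  if (!isIupac(site)) stop("invalid IUPAC recognition site: ", site)
  offset <- as.integer(enzyme$cutOffset[1])
  l <- nchar(site)
  subj <- Biostrings::DNAString(seq)
  fwd <- Biostrings::start(Biostrings::matchPattern(site, subj,
                                                    fixed = FALSE))
  cuts <- fwd + offset - 1L
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(site)))
  if (rc != site) {
    rev <- Biostrings::start(Biostrings::matchPattern(rc, subj,
                                                      fixed = FALSE))
    cuts <- c(cuts, rev + (l - offset) - 1L)
  }
  cuts <- sort(unique(cuts[cuts >= 1 & cuts < nchar(seq)]))
  as.integer(diff(c(0L, cuts, nchar(seq))))
}

#' Enzymes that cut exactly one allele at a SNP
#'
#' For each catalogue enzyme, the two allele-substituted local sequences are
#' built and scanned for recognition-site matches (both strands) that
#' overlap the SNP position. Enzymes for which exactly one allele's sequence
#' has an overlapping match are reported: such a SNP/enzyme pair
#' discriminates the alleles by digestion.
#'
#' @param reference DNAString/character of the contig (or a DNAStringSet of
#'   length 1).
#' @param pos SNP position (1-based) on the reference.
#' @param alleleA,alleleB the two single-base alleles.
#' @param enzymes enzyme catalogue data.frame (see [readEnzymeCatalogue()]).
#' @param flank bases kept either side of the SNP when scanning.
#' @return data.frame with columns enzyme, site, cutOffset, cutAllele.
#' @export
restrictionContrast <- function(reference, pos, alleleA, alleleB, enzymes,
                                flank = 30) {
  if (is(reference, "DNAStringSet")) reference <- reference[[1]]
  seq <- toupper(as.character(reference))
  if (pos - flank < 1 || pos + flank > nchar(seq))
    stop("SNP too close to the contig edge for a ", flank, " bp flank")
  window <- substring(seq, pos - flank, pos + flank)
  centre <- flank + 1L
  hits <- lapply(seq_len(nrow(enzymes)), function(e) {
    site <- enzymes$site[e]
    overlapping <- function(allele) {
      w <- window
      substring(w, centre, centre) <- allele
      m <- .siteMatches(w, site)
      any(IRanges::start(m) <= centre & IRanges::end(m) >= centre)
    }
    cutA <- overlapping(alleleA)
    cutB <- overlapping(alleleB)
    if (xor(cutA, cutB))
      data.frame(enzyme = enzymes$name[e], site = site,
                 cutOffset = enzymes$cutOffset[e],
                 cutAllele = if (cutA) alleleA else alleleB)
    else NULL
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits))
    return(data.frame(enzyme = character(0), site = character(0),
                      cutOffset = integer(0), cutAllele = character(0)))
  do.call(rbind, hits)
}

#' Design diagnostic PCR-RFLP markers
#'
#' Composes [candidateDiagnosticSnps()] and [restrictionContrast()], places
#' an amplicon of \code{ampliconLength} centred on each retained SNP
#' (clipped to the contig), and predicts digestion fragment patterns per
#' karyotype: the cut homokaryote shows the digest fragments, the uncut one
#' the full amplicon, and the heterokaryote the union of both patterns.
#' Candidates are ranked by allele-frequency difference, then by
#' fragment-length distinguishability (minimum pairwise difference between
#' the two homokaryote patterns; \code{gelResolution} is the usable
#' threshold on a standard agarose gel).
#'
#' @param g a [GenotypeData-class] object.
#' @param karyotypes named SS/SN/NN labels or a [KaryotypeCalls-class].
#' @param reference named DNAStringSet of the reference contigs.
#' @param features GRanges annotation with CDS rows.
#' @param enzymes enzyme catalogue data.frame.
#' @param ampliconLength amplicon width (default 667 bp).
#' @param minDiff minimum homokaryote frequency difference (default 0.99).
#' @param gelResolution minimum distinguishable fragment difference in bp.
#' @return DataFrame of marker candidates ordered best-first, with predicted
#'   fragment patterns as comma-separated strings; zero rows (with a
#'   message) when no SNP qualifies.
#' @export
designMarkers <- function(g, karyotypes, reference, features, enzymes,
                          ampliconLength = 667, minDiff = 0.99,
                          gelResolution = 50) {
  snps <- candidateDiagnosticSnps(g, karyotypes, features, minDiff = minDiff)
  empty <- S4Vectors::DataFrame(
    chrom = character(0), position = integer(0), sAllele = character(0),
    nAllele = character(0), cdsId = character(0), enzyme = character(0),
    site = character(0), ampliconStart = integer(0),
    ampliconEnd = integer(0), fragmentsSS = character(0),
    fragmentsSN = character(0), fragmentsNN = character(0),
    freqDiff = numeric(0), minFragDiff = numeric(0), gelOk = logical(0))
  if (!nrow(snps)) {
    message("designMarkers: no SNP passed the coding/fixation filters")
    return(empty)
  }
  rows <- list()
  for (i in seq_len(nrow(snps))) {
    chrom <- snps$chrom[i]
    if (!chrom %in% names(reference)) next
    contig <- toupper(as.character(reference[[chrom]]))
    pos <- snps$position[i]
    flank <- max(30L, max(nchar(enzymes$site)))
    if (pos - flank < 1 || pos + flank > nchar(contig)) next
    contr <- restrictionContrast(contig, pos, snps$sAllele[i],
                                 snps$nAllele[i], enzymes, flank = flank)
    if (!nrow(contr)) next
    half <- (ampliconLength - 1L) %/% 2L
    aStart <- max(1L, pos - half)
    aEnd <- min(nchar(contig), aStart + ampliconLength - 1L)
    aStart <- max(1L, aEnd - ampliconLength + 1L)
    snpOff <- pos - aStart + 1L
    for (e in seq_len(nrow(contr))) {
      enz <- enzymes[enzymes$name == contr$enzyme[e], , drop = FALSE][1, ]
      withAllele <- function(allele) {
        amp <- substring(contig, aStart, aEnd)
        substring(amp, snpOff, snpOff) <- allele
        amp
      }
      fragS <- inSilicoDigest(withAllele(snps$sAllele[i]), enz)
      fragN <- inSilicoDigest(withAllele(snps$nAllele[i]), enz)
      fragHet <- sort(unique(c(fragS, fragN)))
      cross <- abs(outer(fragS, fragN, "-"))
      distinct <- cross[cross > 0]
      minFragDiff <- if (length(distinct)) min(distinct) else 0
      rows[[length(rows) + 1]] <- S4Vectors::DataFrame(
        chrom = chrom, position = pos, sAllele = snps$sAllele[i],
        nAllele = snps$nAllele[i], cdsId = snps$cdsId[i],
        enzyme = contr$enzyme[e], site = contr$site[e],
        ampliconStart = aStart, ampliconEnd = aEnd,
        fragmentsSS = paste(fragS, collapse = ","),
        fragmentsSN = paste(fragHet, collapse = ","),
        fragmentsNN = paste(fragN, collapse = ","),
        freqDiff = snps$freqDiff[i], minFragDiff = minFragDiff,
        gelOk = minFragDiff >= gelResolution)
    }
  }
  if (!length(rows)) {
    message("designMarkers: no candidate SNP has a discriminating enzyme")
    return(empty)
  }
  out <- do.call(rbind, rows)
  out[order(-out$freqDiff, -as.integer(out$gelOk), -out$minFragDiff), ]
}

#' Concordance between marker-based and PCA-based karyotypes
#'
#' @param markerCalls,pcaCalls named SS/SN/NN labels (named character/factor
#'   vectors or [KaryotypeCalls-class] objects); comparison runs over the
#'   shared sample IDs.
#' @return A [ConcordanceResult-class]: n compared, n concordant, percent
#'   concordance rounded to the nearest integer, and the discordant samples.
#' @export
concordance <- function(markerCalls, pcaCalls) {
  if (is(markerCalls, "KaryotypeCalls")) markerCalls <- karyotypes(markerCalls)
  if (is(pcaCalls, "KaryotypeCalls")) pcaCalls <- karyotypes(pcaCalls)
  markerCalls <- setNames(as.character(markerCalls), names(markerCalls))
  pcaCalls <- setNames(as.character(pcaCalls), names(pcaCalls))
  shared <- intersect(names(markerCalls), names(pcaCalls))
  if (!length(shared)) stop("no overlapping samples to compare")
  agree <- markerCalls[shared] == pcaCalls[shared]
  agree[is.na(agree)] <- FALSE
  new("ConcordanceResult",
      nCompared = length(shared), nConcordant = sum(agree),
      rate = round(100 * sum(agree) / length(shared)),
      discordant = shared[!agree])
}
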