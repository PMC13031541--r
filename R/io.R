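#' Read hard genotypes from a VCF into a GenotypeData object
#'
#' Keeps biallelic SNPs only; multi-allelic or non-SNP records are dropped
#' with a message. Dosage is the count of alternate alleles in the GT field;
#' missing genotypes (\code{./.}) become NA.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param region optional "chrom:start-end" string (1-based inclusive) or
#'   GRanges; sites outside are dropped after reading.
#' @param sampleInfo optional per-sample metadata passed to [GenotypeData()].
#' @return A [GenotypeData-class] object.
#' @export
readGenotypeVcf <- function(path, region = NULL, sampleInfo = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altList <- rr$ALT
  nAlt <- S4Vectors::elementNROWS(altList)
  alt <- rep(NA_character_, length(rr))
  alt[nAlt == 1] <- as.character(unlist(altList[nAlt == 1]))
  keep <- nAlt == 1 & nchar(ref) == 1 & !is.na(alt) & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  nDropped <- sum(!keep)
  if (nDropped > 0)
    message("readGenotypeVcf: dropped ", nDropped,
            " non-biallelic-SNP record(s)")
  if (!any(keep)) stop("no biallelic SNPs in ", path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  gt <- gt[keep, , drop = FALSE]
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt),
                   dimnames = list(NULL, colnames(gt)))
  alleles <- gsub("[|]", "/", gt)
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  dosage[] <- unname(known[alleles])
  sites <- GenomicRanges::granges(rr[keep])
  names(sites) <- NULL
  S4Vectors::mcols(sites) <- S4Vectors::DataFrame(ref = ref[keep],
                                                  alt = alt[keep])
  g <- GenotypeData(dosage, sites, sampleInfo = sampleInfo)
  if (!is.null(region)) g <- subsetByRegion(g, region)
  g
}

#' Write a GenotypeData object as a minimal VCF 4.2 file
#'
#' Emits one biallelic SNP record per site with unphased GT genotypes;
#' the output round-trips through [readGenotypeVcf()].
#'
#' @param x a [GenotypeData-class] object.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeGenotypeVcf <- function(x, path) {
  stopifnot(is(x, "GenotypeData"))
  rr <- siteRanges(x)
  d <- dosages(x)
  gtCode <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(d), ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gtCode[d[ok] + 1L]
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(d)), collapse = "\t"))
  body <- paste(as.character(GenomicRanges::seqnames(rr)),
                GenomicRanges::start(rr), ".",
                S4Vectors::mcols(rr)$ref, S4Vectors::mcols(rr)$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a location table of karyotype counts
#'
#' Expects a TSV with header columns \code{location}, \code{latitude},
#' \code{longitude}, \code{temperature}, \code{n_SS}, \code{n_SN},
#' \code{n_NN} (one row per sampling location; e.g. the packaged European
#' table, \code{system.file("extdata", "european_locations.tsv",
#' package = "KaryoCline")}).
#'
#' @param path path to the TSV file.
#' @return data.frame with validated types.
#' @export
readLocationTable <- function(path) {
  if (!file.exists(path)) stop("cannot read location table: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("location table is empty: ", path)
  needed <- c("location", "latitude", "longitude", "temperature",
              "n_SS", "n_SN", "n_NN")
  miss <- setdiff(needed, names(tab))
  if (length(miss))
    stop("location table misses column(s): ", paste(miss, collapse = ", "))
  for (col in c("latitude", "longitude", "temperature"))
    tab[[col]] <- as.numeric(tab[[col]])
  for (col in c("n_SS", "n_SN", "n_NN")) {
    tab[[col]] <- as.integer(tab[[col]])
    if (anyNA(tab[[col]]) || any(tab[[col]] < 0))
      stop("negative or non-integer counts in column ", col)
  }
  if (any(tab$n_SS + tab$n_SN + tab$n_NN < 1))
    stop("each location needs at least one genotyped individual")
  tab
}

#' Read sequences from a FASTA file
#'
#' Sequences are uppercased; names are truncated at the first whitespace.
#'
#' @param path path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
readFastaSequences <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence names in ", path)
  seqs
}

#' Read gene features from a GFF3 file
#'
#' Coordinates stay in the 1-based closed GRanges convention used throughout
#' the package; rtracklayer performs the format conversion at the boundary.
#'
#' @param path path to a GFF3 file.
#' @param types feature types to retain (default CDS and gene).
#' @return GRanges with metadata columns \code{type} and \code{ID}.
#' @export
readGff3Features <- function(path, types = c("CDS", "gene")) {
  if (!file.exists(path)) stop("cannot read GFF3: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% types]
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    type = as.character(gr$type),
    ID = if (!is.null(gr$ID)) as.character(gr$ID)
         else rep(NA_character_, length(gr)))
  names(out) <- NULL
  out
}

#' Write features as GFF3
#'
#' @param features GRanges with \code{type} and \code{ID} metadata columns.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeGff3Features <- function(features, path) {
  gr <- features
  gr$source <- "KaryoCline"
  if (!"phase" %in% names(S4Vectors::mcols(gr)))
    gr$phase <- ifelse(gr$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a restriction enzyme catalogue
#'
#' Expects a TSV with columns \code{name}, \code{site} (IUPAC recognition
#' sequence, length >= 4) and \code{cutOffset} (bases 5' of the cut on the
#' strand the site is written on; EcoRI G^AATTC has offset 1). A catalogue of
#' common 6-cutters ships as \code{system.file("extdata", "enzymes.tsv",
#' package = "KaryoCline")}.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns name, site, cutOffset.
#' @export
readEnzymeCatalogue <- function(path) {
  if (!file.exists(path)) stop("cannot read enzyme catalogue: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("name", "site", "cutOffset")
  miss <- setdiff(needed, names(tab))
  if (length(miss))
    stop("enzyme catalogue misses column(s): ", paste(miss, collapse = ", "))
  tab$site <- toupper(tab$site)
  if (any(nchar(tab$site) < 4))
    stop("recognition sites must be at least 4 bp")
  bad <- !vapply(tab$site, isIupac, logical(1))
  if (any(bad))
    stop("non-IUPAC recognition site(s): ",
         paste(tab$site[bad], collapse = ", "))
  tab$cutOffset <- as.integer(tab$cutOffset)
  if (any(tab$cutOffset < 0 | tab$cutOffset > nchar(tab$site)))
    stop("cutOffset must lie within the recognition site")
  tab
}
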