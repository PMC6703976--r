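# FASTA interchange for allele libraries and consensus sequences.
#
# Header dialects: "locus|allele" for library records, "dog|locus" for
# consensus records. Records are wrapped at 60 columns on output.

#' Read an allele library from FASTA
#'
#' Records must be named \code{"locus|allele"}; all records at one locus
#' must have the same length, unique names and unique sequences, and
#' contain only A/C/G/T.
#'
#' @param path FASTA file path.
#' @return an [AlleleLibrary-class].
#' @export
readAlleleLibrary <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(ids) != 2L))
    stop("library FASTA headers must be 'locus|allele'")
  locus <- vapply(ids, `[`, "", 1L)
  allele <- vapply(ids, `[`, "", 2L)
  if (anyDuplicated(paste(locus, allele, sep = "|")))
    stop("duplicate locus|allele headers in library FASTA")
  byLocus <- split(stats::setNames(as.character(seqs), allele), locus)
  # preserve first-appearance locus order
  alleleLibrary(byLocus[unique(locus)])
}

#' Write an allele library to FASTA
#'
#' Inverse of [readAlleleLibrary()]; headers are \code{"locus|allele"}.
#'
#' @param library an [AlleleLibrary-class].
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
writeAlleleLibrary <- function(library, path) {
  recs <- unlist(lapply(loci(library), function(locus) {
    a <- alleles(library, locus)
    stats::setNames(a, paste(locus, names(a), sep = "|"))
  }))
  x <- Biostrings::DNAStringSet(recs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read consensus sequences from FASTA
#'
#' Records named \code{"dog|locus"}, sequences over the 15 IUPAC
#' nucleotide symbols.
#'
#' @param path FASTA file path.
#' @return named character vector of upper-case consensus sequences.
#' @export
readConsensusFasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(ids) != 2L))
    stop("consensus FASTA headers must be 'dog|locus'")
  stats::setNames(toupper(as.character(seqs)), names(seqs))
}

#' Write consensus sequences to FASTA
#'
#' @param consensus named character vector (\code{"dog|locus"} names).
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
writeConsensusFasta <- function(consensus, path) {
  x <- Biostrings::DNAStringSet(consensus)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}
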