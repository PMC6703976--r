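#' @import methods
NULL

#' Reference allele library for DLA class II loci
#'
#' An \code{AlleleLibrary} holds, per locus, the named reference allele
#' sequences against which diploid sequencing consensus strings are typed.
#' All alleles at one locus must have identical length (the loci are
#' fixed-size amplicons: 290 bp for DRB1, 312 bp for DQA1, 372 bp for
#' DQB1 by default), contain only A/C/G/T, and be unique in both name
#' and sequence.
#'
#' @slot alleles named list; one element per locus, each a named
#'   character vector mapping allele name to an uppercase A/C/G/T
#'   sequence.
#'
#' @seealso [alleleLibrary()], [readAlleleLibrary()], [callGenotype()]
#' @export
setClass("AlleleLibrary", representation(alleles = "list"))

setValidity("AlleleLibrary", function(object) {
  al <- object@alleles
  if (length(al) == 0L) return("library has no loci")
  if (is.null(names(al)) || any(names(al) == "") || anyDuplicated(names(al)))
    return("loci must have unique non-empty names")
  for (locus in names(al)) {
    seqs <- al[[locus]]
    if (!is.character(seqs) || length(seqs) == 0L)
      return(sprintf("locus %s: must be a non-empty character vector", locus))
    if (is.null(names(seqs)) || any(names(seqs) == ""))
      return(sprintf("locus %s: alleles must be named", locus))
    if (anyDuplicated(names(seqs)))
      return(sprintf("locus %s: duplicate allele names", locus))
    if (anyDuplicated(seqs))
      return(sprintf("locus %s: duplicate allele sequences", locus))
    if (length(unique(nchar(seqs))) != 1L)
      return(sprintf("locus %s: alleles have mixed lengths", locus))
    if (any(grepl("[^ACGT]", seqs)))
      return(sprintf("locus %s: allele sequences must contain only A/C/G/T",
                     locus))
  }
  TRUE
})

#' Construct an allele library
#'
#' @param alleles named list of named character vectors: per locus, a map
#'   from allele name to reference sequence. Input is upper-cased.
#' @return an [AlleleLibrary-class] object.
#' @examples
#' lib <- alleleLibrary(list(DRB1 = c(X = "ACGT", Y = "AGGT")))
#' loci(lib)
#' @export
alleleLibrary <- function(alleles) {
  alleles <- lapply(alleles, function(x) {
    out <- toupper(x)
    names(out) <- names(x)
    out
  })
  new("AlleleLibrary", alleles = alleles)
}

#' @describeIn AlleleLibrary-class locus names in the library.
#' @param object,x an \code{AlleleLibrary}.
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))

#' @rdname AlleleLibrary-class
#' @export
setMethod("loci", "AlleleLibrary", function(x) names(x@alleles))

#' Alleles at one locus
#'
#' @param x an [AlleleLibrary-class].
#' @param locus locus name.
#' @return named character vector of allele sequences.
#' @export
setGeneric("alleles", function(x, locus) standardGeneric("alleles"))

#' @rdname alleles
#' @export
setMethod("alleles", "AlleleLibrary", function(x, locus) {
  if (!locus %in% names(x@alleles))
    stop("unknown locus: ", locus)
  x@alleles[[locus]]
})

#' Amplicon length of a locus
#'
#' @inheritParams alleles
#' @return integer sequence length shared by all alleles at the locus.
#' @export
locusLength <- function(x, locus) unname(nchar(alleles(x, locus)[1L]))

setMethod("show", "AlleleLibrary", function(object) {
  cat("AlleleLibrary with", length(object@alleles), "loci\n")
  for (locus in names(object@alleles)) {
    seqs <- object@alleles[[locus]]
    cat(sprintf("  %s: %d alleles, %d bp\n", locus, length(seqs),
                nchar(seqs[1L])))
  }
  invisible(object)
})

#' Case-control SNP genotype dataset
#'
#' Container for a sample-by-SNP dosage matrix (0/1/2 copies of the
#' minor allele, \code{NA} for missing) together with case-control
#' status and SNP map information, as used by the desk-scale GWAS stage.
#'
#' @slot genotypes integer matrix, samples in rows (rownames are sample
#'   IDs), SNPs in columns (colnames are SNP IDs); values 0, 1, 2 or NA.
#' @slot status integer vector aligned with rows: 1 = control,
#'   2 = affected.
#' @slot snpInfo data.frame with columns \code{snp_id},
#'   \code{chromosome}, \code{position_bp}, one row per SNP column.
#'
#' @seealso [snpDataset()], [qcFilter()], [gwasRun()]
#' @export
setClass("SnpDataset",
         representation(genotypes = "matrix", status = "integer",
                        snpInfo = "data.frame"))

setValidity("SnpDataset", function(object) {
  g <- object@genotypes
  if (nrow(g) != length(object@status))
    return("status length must equal number of samples")
  if (!all(object@status %in% c(1L, 2L)))
    return("status must be 1 (control) or 2 (affected)")
  if (is.null(rownames(g)) || anyDuplicated(rownames(g)))
    return("genotype matrix needs unique sample rownames")
  info <- object@snpInfo
  if (!all(c("snp_id", "chromosome", "position_bp") %in% names(info)))
    return("snpInfo needs columns snp_id, chromosome, position_bp")
  if (nrow(info) != ncol(g))
    return("snpInfo rows must equal number of SNP columns")
  cn <- colnames(g)
  if (is.null(cn)) cn <- character(0)
  if (!identical(as.character(info$snp_id), cn))
    return("snpInfo$snp_id must match genotype colnames in order")
  vals <- g[!is.na(g)]
  if (length(vals) && !all(vals %in% 0:2))
    return("genotype dosages must be 0, 1, 2 or NA")
  if (any(info$position_bp < 0))
    return("positions must be non-negative")
  TRUE
})

#' Construct a SNP dataset
#'
#' @param genotypes numeric/integer matrix of minor-allele dosages with
#'   sample rownames and SNP colnames.
#' @param status integer (or coercible) vector, 1 = control,
#'   2 = affected, one per sample row.
#' @param snpInfo data.frame with \code{snp_id}, \code{chromosome},
#'   \code{position_bp} matching the SNP columns.
#' @return a [SnpDataset-class] object.
#' @export
snpDataset <- function(genotypes, status, snpInfo) {
  mode(genotypes) <- "integer"
  snpInfo$snp_id <- as.character(snpInfo$snp_id)
  new("SnpDataset", genotypes = genotypes, status = as.integer(status),
      snpInfo = snpInfo)
}

#' @describeIn SnpDataset-class dosage matrix accessor.
#' @param x,object a \code{SnpDataset}.
#' @export
setGeneric("genoMatrix", function(x) standardGeneric("genoMatrix"))

#' @rdname SnpDataset-class
#' @export
setMethod("genoMatrix", "SnpDataset", function(x) x@genotypes)

#' @describeIn SnpDataset-class case-control status accessor
#'   (1 = control, 2 = affected), named by sample.
#' @export
setGeneric("sampleStatus", function(x) standardGeneric("sampleStatus"))

#' @rdname SnpDataset-class
#' @export
setMethod("sampleStatus", "SnpDataset", function(x) {
  stats::setNames(x@status, rownames(x@genotypes))
})

#' @describeIn SnpDataset-class SNP map accessor.
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname SnpDataset-class
#' @export
setMethod("snpInfo", "SnpDataset", function(x) x@snpInfo)

#' @describeIn SnpDataset-class number of SNPs.
#' @export
nSnps <- function(x) ncol(x@genotypes)

#' @describeIn SnpDataset-class number of samples.
#' @export
nSamples <- function(x) nrow(x@genotypes)

setMethod("show", "SnpDataset", function(object) {
  st <- object@status
  cat(sprintf("SnpDataset: %d samples (%d affected / %d control), %d SNPs\n",
              nrow(object@genotypes), sum(st == 2L), sum(st == 1L),
              ncol(object@genotypes)))
  invisible(object)
})
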