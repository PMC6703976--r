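# Desk-scale GWAS stage: QC filters, 1-df allelic chi-square, Bonferroni
# correction and the genomic inflation factor.

# median of the 1-df chi-square distribution, qchisq(0.5, 1)
.CHISQ1_MEDIAN <- 0.4549364

#' Quality-control filter for a SNP dataset
#'
#' Keeps SNPs with genotyping call rate >= \code{minCallRate} and minor
#' allele frequency >= \code{minMaf} (MAF computed over non-missing
#' calls, cohorts pooled, folded to the minor side). These are the
#' standard array QC thresholds; the originating study's phrasing of the
#' MAF rule is self-contradictory and the standard reading (drop
#' MAF < 0.05) is adopted.
#'
#' @param x a [SnpDataset-class].
#' @param minCallRate minimum per-SNP call rate.
#' @param minMaf minimum minor allele frequency (boundary kept).
#' @return the filtered [SnpDataset-class]; warns if nothing survives.
#' @export
qcFilter <- function(x, minCallRate = 0.90, minMaf = 0.05) {
  g <- genoMatrix(x)
  callRate <- colMeans(!is.na(g))
  af <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  keep <- callRate >= minCallRate & maf >= minMaf
  if (!any(keep)) warning("qcFilter: no SNPs pass quality control")
  snpDataset(g[, keep, drop = FALSE], sampleStatus(x),
             snpInfo(x)[keep, , drop = FALSE])
}

# vectorised allelic chi-square over the columns of a dosage matrix
.allelicChisq <- function(g, status) {
  case <- status == 2L; ctrl <- status == 1L
  a <- colSums(g[case, , drop = FALSE], na.rm = TRUE)              # case minor
  b <- 2 * colSums(!is.na(g[case, , drop = FALSE])) - a            # case major
  c_ <- colSums(g[ctrl, , drop = FALSE], na.rm = TRUE)             # ctrl minor
  d <- 2 * colSums(!is.na(g[ctrl, , drop = FALSE])) - c_           # ctrl major
  n <- a + b + c_ + d
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  chisq <- ifelse(denom > 0, n * (a * d - b * c_)^2 / denom, 0)
  chisq
}

#' 1-df allelic chi-square test for one SNP
#'
#' Builds the 2x2 allele-count table (minor/major x case/control) from
#' dosages and applies Pearson's chi-square without continuity
#' correction, 1 df. A degenerate margin (e.g. a monomorphic SNP) gives
#' \code{chisq = 0}, \code{p = 1}.
#'
#' @param genotypes dosage vector (0/1/2/NA), one entry per sample.
#' @param status integer vector, 1 = control, 2 = affected.
#' @return named numeric \code{c(chisq, p)}.
#' @examples
#' allelicTest(c(2,2,2,2,2, 0,0,0,0,0), c(2,2,2,2,2, 1,1,1,1,1))
#' # chisq 20, p 7.7e-6
#' @export
allelicTest <- function(genotypes, status) {
  status <- as.integer(status)
  if (!any(status == 2L & !is.na(genotypes)) ||
      !any(status == 1L & !is.na(genotypes)))
    stop("allelicTest: need non-missing calls in both cohorts")
  chisq <- .allelicChisq(matrix(genotypes, ncol = 1L), status)
  c(chisq = unname(chisq),
    p = stats::pchisq(unname(chisq), df = 1L, lower.tail = FALSE))
}

#' Genomic inflation factor
#'
#' \code{lambda = median(chisq) / 0.4549364}, the observed median of the
#' 1-df association statistics over the null chi-square(1) median. A
#' value near 1 indicates no population stratification.
#'
#' @param chisq numeric vector of 1-df chi-square statistics.
#' @return lambda (full precision; round to 3 decimals for reports).
#' @export
genomicInflation <- function(chisq) {
  if (length(chisq) == 0L) stop("genomicInflation: empty input")
  stats::median(chisq) / .CHISQ1_MEDIAN
}

#' Run the GWAS stage
#'
#' QC filter, per-SNP allelic chi-square, Bonferroni correction over the
#' number of SNPs tested, genomic inflation factor, and Manhattan / QQ
#' export tables. Lambda is reported descriptively and not used to
#' adjust P-values.
#'
#' @param x a [SnpDataset-class].
#' @inheritParams qcFilter
#' @return list:
#'   \describe{
#'     \item{results}{data.frame sorted by \code{p_raw}: \code{snp_id},
#'       \code{chromosome}, \code{position_bp}, \code{chisq},
#'       \code{p_raw}, \code{p_bonferroni}.}
#'     \item{summary}{list \code{n_snps_input}, \code{n_snps_after_qc},
#'       \code{lambda_gc}.}
#'     \item{manhattan}{data.frame \code{snp_id}, \code{chromosome},
#'       \code{position_bp}, \code{neg_log10_p} in map order.}
#'     \item{qq}{data.frame \code{expected}, \code{observed} -log10 P,
#'       ascending.}
#'   }
#' @export
gwasRun <- function(x, minCallRate = 0.90, minMaf = 0.05) {
  nIn <- nSnps(x)
  xf <- qcFilter(x, minCallRate = minCallRate, minMaf = minMaf)
  m <- nSnps(xf)
  info <- snpInfo(xf)
  chisq <- .allelicChisq(genoMatrix(xf), sampleStatus(xf))
  p <- stats::pchisq(chisq, df = 1L, lower.tail = FALSE)
  results <- data.frame(snp_id = info$snp_id,
                        chromosome = info$chromosome,
                        position_bp = info$position_bp,
                        chisq = chisq, p_raw = p,
                        p_bonferroni = pmin(1, p * m),
                        stringsAsFactors = FALSE)
  manhattan <- data.frame(snp_id = info$snp_id,
                          chromosome = info$chromosome,
                          position_bp = info$position_bp,
                          neg_log10_p = -log10(p),
                          stringsAsFactors = FALSE)
  qq <- data.frame(expected = sort(-log10(stats::ppoints(m))),
                   observed = sort(-log10(p)))
  list(results = results[order(results$p_raw, results$snp_id), ],
       summary = list(n_snps_input = nIn, n_snps_after_qc = m,
                      lambda_gc = if (m) genomicInflation(chisq) else NA_real_),
       manhattan = manhattan, qq = qq)
}

#' Read a SNP dataset from dosage TSV + map TSV
#'
#' Genotype dialect: tab-separated, first column \code{sample_id},
#' second \code{status} (1 = control, 2 = affected), remaining columns
#' dosages 0/1/2 or NA, one column per SNP. Map: tab-separated
#' \code{snp_id}, \code{chromosome}, \code{position_bp} in SNP column
#' order.
#'
#' @param genoPath path to the genotype TSV.
#' @param mapPath path to the map TSV.
#' @return a [SnpDataset-class].
#' @export
readSnpDataset <- function(genoPath, mapPath) {
  geno <- utils::read.delim(genoPath, check.names = FALSE,
                            stringsAsFactors = FALSE)
  map <- utils::read.delim(mapPath, stringsAsFactors = FALSE)
  g <- as.matrix(geno[, -(1:2), drop = FALSE])
  rownames(g) <- geno[[1L]]
  snpDataset(g, geno[[2L]], map)
}

#' Write a SNP dataset to the dosage TSV + map TSV dialect
#'
#' @param x a [SnpDataset-class].
#' @inheritParams readSnpDataset
#' @return invisibly, \code{c(genoPath, mapPath)}.
#' @export
writeSnpDataset <- function(x, genoPath, mapPath) {
  g <- genoMatrix(x)
  df <- data.frame(sample_id = rownames(g), status = sampleStatus(x),
                   g, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, genoPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(snpInfo(x), mapPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(genoPath, mapPath))
}

#' Read PLINK-style PED/MAP text files
#'
#' White-space separated PED (family, individual, paternal, maternal,
#' sex, phenotype, then two allele columns per SNP; \code{0} = missing
#' allele) and MAP (chromosome, snp_id, genetic distance, position).
#' The two allele columns are collapsed to a dosage against the minor
#' allele, determined per SNP from the data (ties broken
#' alphabetically). Phenotype 1/2 is taken as control/affected.
#'
#' @param pedPath PED file path.
#' @param mapPath MAP file path.
#' @return a [SnpDataset-class].
#' @export
readPedMap <- function(pedPath, mapPath) {
  ped <- utils::read.table(pedPath, stringsAsFactors = FALSE)
  map <- utils::read.table(mapPath, stringsAsFactors = FALSE)
  names(map) <- c("chromosome", "snp_id", "cm", "position_bp")[
    seq_len(ncol(map))]
  nSnp <- nrow(map)
  if (ncol(ped) != 6L + 2L * nSnp)
    stop("PED column count does not match MAP SNP count")
  g <- matrix(NA_integer_, nrow(ped), nSnp,
              dimnames = list(ped[[2L]], map$snp_id))
  for (s in seq_len(nSnp)) {
    a1 <- as.character(ped[[6L + 2L * s - 1L]])
    a2 <- as.character(ped[[6L + 2L * s]])
    miss <- a1 == "0" | a2 == "0"
    obs <- c(a1[!miss], a2[!miss])
    if (length(obs)) {
      tab <- sort(table(obs))
      minor <- names(tab)[1L]  # sort() breaks count ties alphabetically
      g[, s] <- ifelse(miss, NA_integer_,
                       (a1 == minor) + (a2 == minor))
    }
  }
  snpDataset(g, ped[[6L]],
             data.frame(snp_id = map$snp_id, chromosome = map$chromosome,
                        position_bp = map$position_bp,
                        stringsAsFactors = FALSE))
}
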