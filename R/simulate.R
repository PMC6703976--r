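# Seeded synthetic-data generator. Emulates a two-cohort DLA typing
# study (34 affected / 66 control dogs by default, three loci of 290,
# 312 and 372 bp) plus an independent SNP panel for the GWAS stage.
# Every generator is a pure function of (config, seed).

#' Simulation configuration
#'
#' Defaults mirror the study design the package targets: cohorts of 34
#' affected and 66 control dogs; loci DRB1 (290 bp), DQA1 (312 bp),
#' DQB1 (372 bp); a pool of six three-locus haplotypes with one risk
#' haplotype at frequency 0.10 and a per-copy odds ratio of 4 on a
#' baseline odds of disease of 0.05; a null SNP panel of 1,000 markers
#' with MAF uniform on (0.05, 0.5) over 15 cases and 16 controls.
#'
#' @param seed integer seed; every generator derives its randomness from
#'   its \code{seed} argument, defaulting to this.
#' @param loci named integer vector of amplicon lengths.
#' @param nAllelesPerLocus alleles simulated per locus (>= pool size).
#' @param haplotypePool data.frame with one column per locus (allele
#'   names) plus \code{freq} summing to 1; \code{NULL} builds the
#'   default pool hap_i = (locus*00i across loci), frequencies
#'   \code{c(0.10, 0.30, 0.22, 0.18, 0.12, 0.08)}.
#' @param riskHaplotype label (\code{"drb1/dqa1/dqb1"}) of the risk
#'   haplotype; default the pool's first (frequency 0.10).
#' @param riskOR per-copy odds ratio of disease.
#' @param baselineOdds odds of disease with zero risk copies.
#' @param nAffected,nControl cohort sizes.
#' @param snp list: \code{nCases}, \code{nControls}, \code{nSnps},
#'   \code{mafRange} in (0, 0.5], \code{orAssoc} (allelic OR of one
#'   associated SNP, \code{NULL} = fully null panel),
#'   \code{missingRate}.
#' @return validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L,
                             loci = c(DRB1 = 290L, DQA1 = 312L, DQB1 = 372L),
                             nAllelesPerLocus = 6L,
                             haplotypePool = NULL,
                             riskHaplotype = NULL,
                             riskOR = 4,
                             baselineOdds = 0.05,
                             nAffected = 34L,
                             nControl = 66L,
                             snp = list(nCases = 15L, nControls = 16L,
                                        nSnps = 1000L,
                                        mafRange = c(0.05, 0.5),
                                        orAssoc = NULL, missingRate = 0)) {
  if (nAffected <= 0L || nControl <= 0L)
    stop("cohort sizes must be positive")
  if (riskOR <= 0 || baselineOdds <= 0)
    stop("riskOR and baselineOdds must be positive")
  if (is.null(haplotypePool)) {
    if (nAllelesPerLocus < 6L)
      stop("default haplotype pool needs >= 6 alleles per locus")
    haplotypePool <- data.frame(
      lapply(names(loci), function(l)
        sprintf("%s*%03d", l, 1:6)),
      freq = c(0.10, 0.30, 0.22, 0.18, 0.12, 0.08))
    names(haplotypePool)[seq_along(loci)] <- names(loci)
  }
  if (abs(sum(haplotypePool$freq) - 1) > 1e-9)
    stop("haplotype pool frequencies must sum to 1")
  labels <- apply(haplotypePool[, names(loci), drop = FALSE], 1L, paste,
                  collapse = "/")
  if (is.null(riskHaplotype)) riskHaplotype <- labels[1L]
  if (!riskHaplotype %in% labels)
    stop("risk haplotype not in the pool")
  if (min(snp$mafRange) <= 0 || max(snp$mafRange) > 0.5)
    stop("mafRange must lie in (0, 0.5]")
  structure(list(seed = as.integer(seed), loci = loci,
                 nAllelesPerLocus = as.integer(nAllelesPerLocus),
                 haplotypePool = haplotypePool, poolLabels = labels,
                 riskHaplotype = riskHaplotype, riskOR = riskOR,
                 baselineOdds = baselineOdds,
                 nAffected = as.integer(nAffected),
                 nControl = as.integer(nControl), snp = snp),
            class = "SimulationConfig")
}

.randSeq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                       replace = TRUE), collapse = "")

.hamming <- function(x, y) sum(.charSplit(x) != .charSplit(y))

#' Simulate a reference allele library
#'
#' Random equal-length A/C/G/T alleles per locus, pairwise distinct with
#' pairwise Hamming distance >= 2, so a single-site error can never
#' convert one allele into another. Deterministic given the seed.
#'
#' @param config a [simulationConfig()].
#' @param seed integer seed (default \code{config$seed}).
#' @return an [AlleleLibrary-class] with allele names
#'   \code{"LOCUS*001"} ...
#' @export
simulateLibrary <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$nAllelesPerLocus
  out <- lapply(names(config$loci), function(locus) {
    len <- config$loci[[locus]]
    if (4^min(len, 30) < n)  # cap to dodge overflow on long loci
      stop("requested alleles exceed the sequence space at ", locus)
    seqs <- character(0)
    tries <- 0L
    while (length(seqs) < n) {
      cand <- .randSeq(len)
      if (all(vapply(seqs, .hamming, 0L, y = cand) >= 2L))
        seqs <- c(seqs, cand)
      tries <- tries + 1L
      if (tries > 1000L * n)
        stop("could not place ", n, " alleles with Hamming >= 2 at ",
             locus)
    }
    stats::setNames(seqs, sprintf("%s*%03d", locus, seq_len(n)))
  })
  names(out) <- names(config$loci)
  alleleLibrary(out)
}

#' Exact allelic odds ratio induced by the disease model
#'
#' Under Hardy-Weinberg sampling of haplotypes and odds of disease
#' \code{baselineOdds * riskOR^copies}, the allele-copy 2x2 table
#' contrasting risk-haplotype copies in cases versus controls has a
#' population odds ratio that is close to, but not exactly, the per-copy
#' parameter (the logistic link is not exactly log-linear in copies).
#' This computes it exactly by enumerating the three genotype classes --
#' the estimand the Woolf interval is expected to cover.
#'
#' @param config a [simulationConfig()].
#' @return the induced allele-copy odds ratio.
#' @export
trueAllelicOR <- function(config) {
  f <- config$haplotypePool$freq[config$poolLabels == config$riskHaplotype]
  pG <- c((1 - f)^2, 2 * f * (1 - f), f^2)     # copies 0,1,2
  odds <- config$baselineOdds * config$riskOR^(0:2)
  pD <- odds / (1 + odds)
  pCase <- sum((0:2) * pG * pD) / (2 * sum(pG * pD))
  pCtrl <- sum((0:2) * pG * (1 - pD)) / (2 * sum(pG * (1 - pD)))
  (pCase / (1 - pCase)) / (pCtrl / (1 - pCtrl))
}

#' Simulate a case-control cohort of diplotypes
#'
#' Each dog draws two haplotypes i.i.d. from the pool (Hardy-Weinberg);
#' disease status is Bernoulli with odds \code{baselineOdds *
#' riskOR^copies} of the risk haplotype; draws are rejected until
#' exactly \code{nAffected} affected and \code{nControl} control dogs
#' are collected (case-control ascertainment to fixed cohort sizes).
#'
#' @param config a [simulationConfig()].
#' @param seed integer seed (default \code{config$seed}).
#' @param ensureAnchors append one fully homozygous dog per pool
#'   haplotype lacking one, so Clark phasing has an anchor for every
#'   haplotype (used when exercising the end-to-end recovery property;
#'   appended dogs get status from the same disease model, enlarging
#'   the cohorts).
#' @param maxDraws rejection-sampling guard.
#' @return data.frame (the true cohort): \code{dog_id}, \code{status},
#'   \code{hap1}, \code{hap2} (pool labels, hap1 <= hap2),
#'   \code{risk_copies}.
#' @export
simulateCohort <- function(config, seed = config$seed,
                           ensureAnchors = FALSE, maxDraws = 1e6) {
  set.seed(seed)
  pool <- config$poolLabels
  freq <- config$haplotypePool$freq
  aff <- list(); ctl <- list(); drawn <- 0L
  drawDog <- function(h) {
    copies <- sum(h == config$riskHaplotype)
    odds <- config$baselineOdds * config$riskOR^copies
    affected <- stats::runif(1L) < odds / (1 + odds)
    list(hap = sort(h), affected = affected, copies = copies)
  }
  while (length(aff) < config$nAffected || length(ctl) < config$nControl) {
    drawn <- drawn + 1L
    if (drawn > maxDraws)
      stop("cohort sizes unreachable within maxDraws")
    d <- drawDog(sample(pool, 2L, replace = TRUE, prob = freq))
    if (d$affected && length(aff) < config$nAffected)
      aff[[length(aff) + 1L]] <- d
    else if (!d$affected && length(ctl) < config$nControl)
      ctl[[length(ctl) + 1L]] <- d
  }
  dogs <- c(aff, ctl)
  status <- rep(c("affected", "control"),
                c(length(aff), length(ctl)))
  if (ensureAnchors) {
    anchored <- unique(unlist(lapply(dogs, function(d)
      if (d$hap[1L] == d$hap[2L]) d$hap[1L])))
    for (h in setdiff(pool, anchored)) {
      d <- drawDog(c(h, h))
      dogs[[length(dogs) + 1L]] <- d
      status <- c(status, if (d$affected) "affected" else "control")
    }
  }
  data.frame(
    dog_id = sprintf("dog%03d", seq_along(dogs)),
    status = status,
    hap1 = vapply(dogs, function(d) d$hap[1L], ""),
    hap2 = vapply(dogs, function(d) d$hap[2L], ""),
    risk_copies = vapply(dogs, function(d) d$copies, 0L),
    stringsAsFactors = FALSE)
}

# per-locus allele pairs of a cohort row
.cohortAlleles <- function(cohort, lociNames) {
  h1 <- strsplit(cohort$hap1, "/", fixed = TRUE)
  h2 <- strsplit(cohort$hap2, "/", fixed = TRUE)
  out <- list()
  for (l in seq_along(lociNames))
    out[[lociNames[l]]] <- cbind(vapply(h1, `[`, "", l),
                                 vapply(h2, `[`, "", l))
  out
}

#' Render diploid consensus sequences for a cohort
#'
#' The inverse of typing: per dog and locus, the position-wise IUPAC
#' union of the two allele sequences. With \code{errorRate > 0} each
#' position is independently corrupted, with that probability, to a
#' uniformly chosen different IUPAC symbol (substitution-only error
#' model).
#'
#' @param cohort data.frame from [simulateCohort()].
#' @param library the [AlleleLibrary-class] containing every pool
#'   allele.
#' @param errorRate per-position corruption probability (default 0).
#' @param seed integer seed for the error process.
#' @return named character vector of consensus strings, names
#'   \code{"dog|locus"}.
#' @export
renderConsensus <- function(cohort, library, errorRate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lociNames <- loci(library)
  pairs <- .cohortAlleles(cohort, lociNames)
  out <- character(0)
  for (locus in lociNames) {
    refs <- alleles(library, locus)
    p <- pairs[[locus]]
    for (i in seq_len(nrow(cohort))) {
      u <- iupacUnion(.charSplit(refs[[p[i, 1L]]]),
                      .charSplit(refs[[p[i, 2L]]]))
      if (errorRate > 0) {
        hit <- stats::runif(length(u)) < errorRate
        for (k in which(hit))
          u[k] <- sample(setdiff(.IUPAC_SYMBOLS, u[k]), 1L)
      }
      out[paste(cohort$dog_id[i], locus, sep = "|")] <-
        paste(u, collapse = "")
    }
  }
  out[order(names(out))]
}

#' Simulate a case-control SNP dataset
#'
#' Independent SNPs: per-SNP MAF uniform on \code{mafRange}, genotypes
#' Binomial(2, MAF) per sample (no structure, no linkage). With
#' \code{orAssoc} set, the first SNP is associated: its control allele
#' frequency is drawn from \code{mafRange} and the case frequency solves
#' the target allelic odds ratio. Missing calls are sprinkled uniformly
#' at \code{missingRate}.
#'
#' @param config a [simulationConfig()] (uses \code{config$snp}).
#' @param seed integer seed (default \code{config$seed}).
#' @return a [SnpDataset-class]; SNPs are placed on chromosomes 1-38
#'   round-robin at 1 kb spacing.
#' @export
simulateSnpDataset <- function(config, seed = config$seed) {
  set.seed(seed)
  sc <- config$snp
  nCase <- sc$nCases; nCtrl <- sc$nControls; m <- sc$nSnps
  status <- c(rep(2L, nCase), rep(1L, nCtrl))
  maf <- stats::runif(m, sc$mafRange[1L], sc$mafRange[2L])
  g <- vapply(seq_len(m), function(s)
    stats::rbinom(nCase + nCtrl, 2L, maf[s]), integer(nCase + nCtrl))
  if (!is.null(sc$orAssoc)) {
    p0 <- maf[1L]
    o1 <- sc$orAssoc * p0 / (1 - p0)
    p1 <- o1 / (1 + o1)
    g[, 1L] <- c(stats::rbinom(nCase, 2L, p1),
                 stats::rbinom(nCtrl, 2L, p0))
  }
  if (!is.null(sc$missingRate) && sc$missingRate > 0) {
    drop <- stats::runif(length(g)) < sc$missingRate
    g[drop] <- NA_integer_
  }
  rownames(g) <- sprintf("s%03d", seq_len(nCase + nCtrl))
  colnames(g) <- sprintf("SNP%05d", seq_len(m))
  info <- data.frame(snp_id = colnames(g),
                     chromosome = rep_len(1:38, m),
                     position_bp = 1000L * (seq_len(m) %/% 38L + 1L),
                     stringsAsFactors = FALSE)
  snpDataset(g, status, info)
}
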