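# QC filters, allelic chi-square, Bonferroni, genomic inflation factor.

smallDataset <- function(g, status, chrom = 1L) {
  colnames(g) <- sprintf("S%02d", seq_len(ncol(g)))
  rownames(g) <- sprintf("d%02d", seq_len(nrow(g)))
  snpDataset(g, status,
             data.frame(snp_id = colnames(g), chromosome = chrom,
                        position_bp = seq_len(ncol(g)) * 1000L))
}

test_that("qcFilter removes low call rate and low MAF, keeps the boundary", {
  set.seed(21)
  n <- 20L
  g <- cbind(
    rbinom(n, 2, 0.3),                       # clean
    c(rep(NA, 3), rbinom(n - 3, 2, 0.3)),    # call rate 85% -> drop
    rep(0L, n),                              # monomorphic -> drop
    c(rep(1L, 2), rep(0L, n - 2)),           # MAF 2/40 = 0.05 -> keep
    rbinom(n, 2, 0.4))                       # clean
  d <- smallDataset(g, rep(c(1L, 2L), each = 10))
  f <- qcFilter(d, minCallRate = 0.90, minMaf = 0.05)
  expect_identical(snpInfo(f)$snp_id, c("S01", "S04", "S05"))
  expect_warning(qcFilter(smallDataset(matrix(0L, n, 1), rep(1:2, 10))),
                 "no SNPs")
})

test_that("allelic chi-square matches hand computation and handles degeneracy", {
  res <- allelicTest(c(rep(2L, 5), rep(0L, 5)), c(rep(2L, 5), rep(1L, 5)))
  expect_equal(res[["chisq"]], 20)          # table (10,0,0,10)
  expect_equal(res[["p"]], pchisq(20, 1, lower.tail = FALSE))
  # identical allele counts in both cohorts
  res0 <- allelicTest(c(1L, 1L, 1L, 1L), c(2L, 2L, 1L, 1L))
  expect_equal(res0[["chisq"]], 0)
  expect_equal(res0[["p"]], 1)
  # degenerate margin: monomorphic
  resm <- allelicTest(c(0L, 0L, 0L, 0L), c(2L, 2L, 1L, 1L))
  expect_equal(resm[["chisq"]], 0)
  expect_equal(resm[["p"]], 1)
  expect_error(allelicTest(c(NA, NA, 0L, 1L), c(2L, 2L, 1L, 1L)),
               "both cohorts")
})

test_that("allelic chi-square equals Pearson chisq.test on random draws", {
  set.seed(22)
  status <- c(rep(2L, 15), rep(1L, 16))
  for (i in 1:50) {
    g <- rbinom(31, 2, runif(1, 0.1, 0.5))
    a <- sum(g[status == 2]); c_ <- sum(g[status == 1])
    tab <- matrix(c(a, c_, 30 - a, 32 - c_), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(allelicTest(g, status)[["chisq"]],
                 unname(suppressWarnings(
                   chisq.test(tab, correct = FALSE)$statistic)))
  }
})

test_that("genomic inflation factor is median-based and homogeneous", {
  expect_equal(genomicInflation(rep(0.4549364, 7)), 1)
  x <- rchisq(101, 3)
  expect_equal(genomicInflation(2 * x), 2 * genomicInflation(x))
  set.seed(23)
  lam <- genomicInflation(rchisq(1e5, 1))
  expect_gt(lam, 0.98); expect_lt(lam, 1.02)
  expect_error(genomicInflation(numeric(0)), "empty")
})

test_that("gwasRun wires QC, tests, Bonferroni and exports coherently", {
  cfg <- simulationConfig(seed = 3,
                          snp = list(nCases = 15L, nControls = 16L,
                                     nSnps = 200L, mafRange = c(0.1, 0.5),
                                     orAssoc = NULL, missingRate = 0.02))
  gw <- gwasRun(simulateSnpDataset(cfg))
  r <- gw$results
  expect_lte(gw$summary$n_snps_after_qc, gw$summary$n_snps_input)
  expect_equal(r$p_bonferroni,
               pmin(1, r$p_raw * gw$summary$n_snps_after_qc))
  # Bonferroni is monotone: same ranking as raw P
  expect_identical(order(r$p_raw), order(r$p_bonferroni,
                                         r$p_raw))
  expect_false(is.unsorted(r$p_raw))
  expect_identical(names(gw$manhattan),
                   c("snp_id", "chromosome", "position_bp",
                     "neg_log10_p"))
  expect_identical(names(gw$qq), c("expected", "observed"))
  expect_false(is.unsorted(gw$qq$observed))
  # single-SNP dataset: corrected P equals raw P
  one <- smallDataset(matrix(rbinom(31, 2, 0.4), ncol = 1),
                      c(rep(2L, 15), rep(1L, 16)))
  gw1 <- gwasRun(one)
  expect_equal(gw1$results$p_bonferroni, gw1$results$p_raw)
})

test_that("an associated SNP dominates the scan at large effect and n", {
  cfg <- simulationConfig(seed = 4,
                          snp = list(nCases = 200L, nControls = 200L,
                                     nSnps = 300L, mafRange = c(0.1, 0.4),
                                     orAssoc = 10, missingRate = 0))
  hits <- vapply(1:20, function(i) {
    gw <- gwasRun(simulateSnpDataset(cfg, seed = 400 + i))
    gw$results$snp_id[1L] == "SNP00001"
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("dosage TSV and PED/MAP readers agree with the in-memory dataset", {
  cfg <- simulationConfig(seed = 5,
                          snp = list(nCases = 5L, nControls = 6L,
                                     nSnps = 8L, mafRange = c(0.2, 0.5),
                                     orAssoc = NULL, missingRate = 0.05))
  d <- simulateSnpDataset(cfg)
  gp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  writeSnpDataset(d, gp, mp)
  back <- readSnpDataset(gp, mp)
  expect_identical(genoMatrix(back), genoMatrix(d))
  expect_identical(sampleStatus(back), sampleStatus(d))
  expect_identical(snpInfo(back)$snp_id, snpInfo(d)$snp_id)

  # PED/MAP: encode dosage 0 -> A/A, 1 -> A/B, 2 -> B/B with B minor
  g <- genoMatrix(d)
  ped <- data.frame(fam = rownames(g), id = rownames(g), pat = 0, mat = 0,
                    sex = 0, pheno = sampleStatus(d))
  for (s in seq_len(ncol(g))) {
    a1 <- ifelse(is.na(g[, s]), "0", ifelse(g[, s] >= 1, "B", "A"))
    a2 <- ifelse(is.na(g[, s]), "0", ifelse(g[, s] == 2, "B", "A"))
    ped[[paste0("s", s, "a")]] <- a1
    ped[[paste0("s", s, "b")]] <- a2
  }
  pedPath <- withr::local_tempfile(fileext = ".ped")
  mapPath <- withr::local_tempfile(fileext = ".map")
  write.table(ped, pedPath, col.names = FALSE, row.names = FALSE,
              quote = FALSE)
  write.table(data.frame(snpInfo(d)$chromosome, snpInfo(d)$snp_id, 0,
                         snpInfo(d)$position_bp),
              mapPath, col.names = FALSE, row.names = FALSE, quote = FALSE)
  fromPed <- readPedMap(pedPath, mapPath)
  # dosages agree wherever B is the true minor allele in the encoded data
  gb <- genoMatrix(fromPed)
  for (s in seq_len(ncol(g))) {
    obs <- g[!is.na(g[, s]), s]
    minorIsB <- sum(obs) < length(obs)  # B strictly minor (ties pick A)
    if (minorIsB) expect_identical(gb[, s], g[, s])
    else expect_identical(gb[, s], 2L - g[, s])
  }
})
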