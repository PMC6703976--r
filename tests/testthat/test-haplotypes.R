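# Clark-style three-locus haplotype inference.

callsRow <- function(dog, locus, a1, a2) {
  data.frame(dog_id = dog, locus = locus,
             status = if (a1 == a2) "homozygous" else "heterozygous",
             allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
}
makeCalls <- function(dogGenos) {
  lociNames <- c("DRB1", "DQA1", "DQB1")
  do.call(rbind, unlist(lapply(names(dogGenos), function(dog) {
    lapply(1:3, function(l)
      callsRow(dog, lociNames[l], dogGenos[[dog]][[l]][1],
               dogGenos[[dog]][[l]][2]))
  }), recursive = FALSE))
}

test_that("enumeratePhasings yields 2^(h-1) unordered decompositions", {
  hom <- list(c("a", "a"), c("b", "b"), c("c", "c"))
  expect_identical(enumeratePhasings(hom),
                   list(list(c("a", "b", "c"), c("a", "b", "c"))))
  h1 <- list(c("a1", "a2"), c("b", "b"), c("c", "c"))
  expect_length(enumeratePhasings(h1), 1L)
  h2 <- list(c("a1", "a2"), c("b1", "b2"), c("c", "c"))
  expect_length(enumeratePhasings(h2), 2L)
  h3 <- list(c("a1", "a2"), c("b1", "b2"), c("c1", "c2"))
  ph <- enumeratePhasings(h3)
  expect_length(ph, 4L)
  # matches the independent brute-force enumeration
  keys <- vapply(ph, function(p)
    paste(sort(c(paste(p[[1]], collapse = "/"),
                 paste(p[[2]], collapse = "/"))), collapse = "+"), "")
  expect_identical(sort(keys), oracleDecomps(h3))
  expect_error(enumeratePhasings(h3[1:2]), "incomplete")
})

test_that("a homozygous anchor resolves a triple heterozygote (Clark extension)", {
  calls <- makeCalls(list(
    dog1 = list(c("a1", "a1"), c("b1", "b1"), c("c1", "c1")),
    dog2 = list(c("a1", "a2"), c("b1", "b2"), c("c1", "c2"))))
  res <- inferHaplotypes(calls)
  d <- res$diplotypes
  expect_identical(d$status, c("resolved", "resolved"))
  expect_identical(d$hap1[1], "a1/b1/c1")
  expect_setequal(c(d$hap1[2], d$hap2[2]), c("a1/b1/c1", "a2/b2/c2"))
  expect_identical(d$provenance, c("unique", "one-known-extension"))
  expect_true(all(c("a1/b1/c1", "a2/b2/c2") %in% res$haplotypes))
})

test_that("a single-locus heterozygote resolves without anchors; triple heterozygotes without anchors stay unidentified", {
  calls <- makeCalls(list(
    dogA = list(c("a1", "a2"), c("b1", "b1"), c("c1", "c1"))))
  res <- inferHaplotypes(calls)
  expect_identical(res$diplotypes$status, "resolved")
  expect_identical(res$diplotypes$iteration, 0L)

  calls2 <- makeCalls(list(
    dogX = list(c("a1", "a2"), c("b1", "b2"), c("c1", "c2")),
    dogY = list(c("a1", "a3"), c("b1", "b3"), c("c1", "c3"))))
  res2 <- inferHaplotypes(calls2)
  expect_identical(res2$diplotypes$status,
                   c("unidentified", "unidentified"))
  expect_length(res2$haplotypes, 0L)
})

test_that("ambiguous/novel/missing locus calls exclude a dog from phasing", {
  calls <- makeCalls(list(
    dog1 = list(c("a1", "a1"), c("b1", "b1"), c("c1", "c1"))))
  bad <- data.frame(dog_id = "dog2", locus = c("DRB1", "DQA1", "DQB1"),
                    status = c("ambiguous", "homozygous", "homozygous"),
                    allele1 = c(NA, "b1", "c1"),
                    allele2 = c(NA, "b1", "c1"), stringsAsFactors = FALSE)
  res <- inferHaplotypes(rbind(calls, bad))
  d <- res$diplotypes
  expect_identical(d$status[d$dog_id == "dog2"], "unidentified")
  expect_match(d$provenance[d$dog_id == "dog2"], "ambiguous")
})

test_that("copy counts are conserved and unidentified dogs contribute two copies", {
  calls <- makeCalls(list(
    dog1 = list(c("a1", "a1"), c("b1", "b1"), c("c1", "c1")),
    dog2 = list(c("a1", "a2"), c("b1", "b2"), c("c1", "c2")),
    # triple heterozygote sharing no haplotype with the anchored set
    dog3 = list(c("a3", "a4"), c("b3", "b4"), c("c3", "c4"))))
  samples <- data.frame(dog_id = paste0("dog", 1:3),
                        status = c("affected", "affected", "control"),
                        stringsAsFactors = FALSE)
  res <- inferHaplotypes(calls)
  hc <- countHaplotypes(res$diplotypes, samples)
  expect_identical(sum(hc$n_affected), 4L)   # 2 dogs x 2 copies
  expect_identical(sum(hc$n_control), 2L)
  expect_identical(hc$n_control[hc$haplotype == "Unidentified"], 2L)
  expect_identical(hc$haplotype[nrow(hc)], "Unidentified")
  expect_equal(hc$freq_affected, hc$n_affected / 4)
})

test_that("resolution is monotone in H and independent of input row order", {
  calls <- makeCalls(list(
    dog1 = list(c("a1", "a1"), c("b1", "b1"), c("c1", "c1")),
    dog2 = list(c("a1", "a2"), c("b1", "b2"), c("c1", "c2")),
    dog3 = list(c("a2", "a3"), c("b2", "b3"), c("c2", "c3"))))
  res <- inferHaplotypes(calls)
  # re-running with the final H reproduces the same assignments
  res2 <- inferHaplotypes(calls, knownHaplotypes = res$haplotypes)
  expect_identical(
    res2$diplotypes[, c("dog_id", "status", "hap1", "hap2")],
    res$diplotypes[, c("dog_id", "status", "hap1", "hap2")])
  # shuffled input rows give identical results
  set.seed(5)
  res3 <- inferHaplotypes(calls[sample(nrow(calls)), ])
  expect_identical(res3$diplotypes, res$diplotypes)
})

test_that("phasing agrees with brute-force decomposition on small cohorts", {
  set.seed(99)
  lociNames <- c("DRB1", "DQA1", "DQB1")
  for (trial in 1:60) {
    nHap <- sample(2:4, 1)
    pool <- lapply(seq_len(nHap), function(i)
      c(paste0("a", sample(3, 1)), paste0("b", sample(3, 1)),
        paste0("c", sample(3, 1))))
    nDogs <- sample(2:6, 1)
    genos <- lapply(seq_len(nDogs), function(d) {
      h <- pool[sample(nHap, 2, replace = TRUE)]
      lapply(1:3, function(l) sort(c(h[[1]][l], h[[2]][l])))
    })
    names(genos) <- sprintf("dog%02d", seq_len(nDogs))
    res <- inferHaplotypes(makeCalls(genos))
    d <- res$diplotypes
    for (i in seq_len(nrow(d))) {
      g <- genos[[d$dog_id[i]]]
      if (d$status[i] == "resolved") {
        key <- paste(sort(c(d$hap1[i], d$hap2[i])), collapse = "+")
        expect_true(key %in% oracleDecomps(g))
      }
      # every all-homozygous dog must resolve at iteration 0
      if (all(vapply(g, function(p) p[1] == p[2], NA))) {
        expect_identical(d$status[i], "resolved")
        expect_identical(d$iteration[i], 0L)
      }
    }
    # conservation of copies
    samples <- data.frame(dog_id = names(genos), status = "control",
                          stringsAsFactors = FALSE)
    hc <- countHaplotypes(d, samples)
    expect_identical(sum(hc$n_control), 2L * nDogs)
  }
})
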