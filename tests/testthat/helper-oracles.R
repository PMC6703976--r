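# Independent oracles for property-style tests. These share no code
# with the implementation: the IUPAC map comes from Biostrings, pair
# enumeration and phase decomposition are written from scratch here.

# union symbol of two bases via Biostrings' published code map
oracleUnion <- function(b1, b2) {
  key <- paste(sort(unique(c(b1, b2))), collapse = "")
  names(Biostrings::IUPAC_CODE_MAP)[Biostrings::IUPAC_CODE_MAP == key]
}

oracleRender <- function(a1, a2) {
  x <- strsplit(a1, "")[[1]]; y <- strsplit(a2, "")[[1]]
  paste(mapply(oracleUnion, x, y), collapse = "")
}

# exhaustive classification of a consensus against a reference set
# (no N handling: oracle trials use clean consensus strings)
oracleCall <- function(cons, refs) {
  nm <- sort(names(refs))
  hits <- list()
  for (i in seq_along(nm)) for (j in i:length(nm)) {
    if (oracleRender(refs[[nm[i]]], refs[[nm[j]]]) == cons)
      hits[[length(hits) + 1L]] <- c(nm[i], nm[j])
  }
  if (length(hits) == 0L) return(list(status = "novel", pairs = list()))
  if (length(hits) == 1L) {
    st <- if (hits[[1]][1] == hits[[1]][2]) "homozygous" else "heterozygous"
    return(list(status = st, pairs = hits))
  }
  list(status = "ambiguous", pairs = hits)
}

# independent brute-force enumeration of unordered phase decompositions
oracleDecomps <- function(g) {
  labs <- character(0)
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    h1 <- paste(g[[1]][i], g[[2]][j], g[[3]][k], sep = "/")
    h2 <- paste(g[[1]][3 - i], g[[2]][3 - j], g[[3]][3 - k], sep = "/")
    labs <- c(labs, paste(sort(c(h1, h2)), collapse = "+"))
  }
  sort(unique(labs))
}

# small random allele library with pairwise Hamming >= 2, independent of
# the package's simulator
randomRefs <- function(nAlleles, len) {
  ham <- function(x, y)
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  seqs <- character(0)
  while (length(seqs) < nAlleles) {
    cand <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = "")
    if (all(vapply(seqs, ham, 0L, y = cand) >= 2L))
      seqs <- c(seqs, cand)
  }
  stats::setNames(seqs, paste0("al", seq_len(nAlleles)))
}

fixturePath <- function(name) {
  system.file("extdata", name, package = "dlatyper", mustWork = TRUE)
}
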