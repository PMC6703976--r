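# Genotype calling from diploid consensus sequences.

#' Call a per-locus genotype from a consensus sequence
#'
#' Types one dog at one locus against the reference allele library,
#' inverting the diploid consensus: an unambiguous consensus must match
#' a single reference allele (homozygote); a consensus with ambiguity
#' codes is explained by the unordered allele pair whose position-wise
#' IUPAC union reproduces it.
#'
#' Statuses:
#' \describe{
#'   \item{homozygous}{no ambiguity codes and exactly one matching
#'     reference allele (reported as that allele twice).}
#'   \item{heterozygous}{exactly one explaining known-allele pair.}
#'   \item{ambiguous}{two or more explaining pairs; all candidates are
#'     reported, sorted lexicographically, and no tie is broken.}
#'   \item{novel}{no explaining pair. For an unambiguous consensus the
#'     closest reference alleles (minimum Hamming distance, ties all
#'     reported) and the mismatching positions are returned. For an
#'     ambiguous consensus with exactly one compatible reference allele
#'     (its base lies in the consensus base set at every position), the
#'     second, unobserved allele is forced base-by-base and returned in
#'     \code{novel_complement} -- the situation in which a previously
#'     undescribed allele is detected in a heterozygote.}
#' }
#'
#' \code{N} in the consensus is a wildcard compatible with any base
#' (reject with \code{strictN = TRUE}). \code{mismatch_positions} are
#' 0-based, matching the tabular interchange format.
#'
#' @param consensus consensus sequence string (15 IUPAC symbols,
#'   case-insensitive).
#' @param library an [AlleleLibrary-class].
#' @param locus locus name present in the library.
#' @param dogId sample identifier carried into the result.
#' @param strictN logical; error on \code{N} in the consensus.
#' @return a list of class \code{GenotypeCall} with elements
#'   \code{dog_id}, \code{locus}, \code{status}, \code{alleles}
#'   (character pair or \code{NULL}), \code{candidates} (list of
#'   character pairs or \code{NULL}), \code{mismatch_positions}
#'   (0-based integer vector or \code{NULL}), \code{novel_complement}
#'   (string or \code{NA}).
#' @examples
#' lib <- alleleLibrary(list(DRB1 = c(X = "ACGT", Y = "AGGT")))
#' callGenotype("ACGT", lib, "DRB1")$status      # homozygous
#' callGenotype("ASGT", lib, "DRB1")$alleles     # X Y
#' @export
callGenotype <- function(consensus, library, locus, dogId = NA_character_,
                         strictN = FALSE) {
  stopifnot(is(library, "AlleleLibrary"))
  refs <- alleles(library, locus)
  chars <- .consensusChars(consensus, strictN = strictN)
  if (length(chars) != locusLength(library, locus))
    stop(sprintf("length mismatch at %s: consensus %d bp, library %d bp",
                 locus, length(chars), locusLength(library, locus)))

  refChars <- lapply(refs, .charSplit)
  nonN <- chars != "N"
  res <- list(dog_id = dogId, locus = locus, status = NA_character_,
              alleles = NULL, candidates = NULL,
              mismatch_positions = NULL, novel_complement = NA_character_)
  class(res) <- "GenotypeCall"

  if (all(chars %in% c("A", "C", "G", "T", "N"))) {
    # unambiguous path (N positions are wildcards)
    hits <- names(refs)[vapply(refChars, function(r)
      all(r[nonN] == chars[nonN]), NA)]
    if (length(hits) == 1L) {
      res$status <- "homozygous"
      res$alleles <- c(hits, hits)
    } else if (length(hits) >= 2L) {
      res$status <- "ambiguous"
      res$candidates <- lapply(sort(hits), function(h) c(h, h))
    } else {
      dists <- vapply(refChars, function(r) sum(r[nonN] != chars[nonN]), 0L)
      closest <- sort(names(refs)[dists == min(dists)])
      mism <- which(refChars[[closest[1L]]] != chars & nonN) - 1L
      res$status <- "novel"
      res$candidates <- lapply(closest, function(h) c(h, h))
      res$mismatch_positions <- mism
    }
    return(res)
  }

  # ambiguous path: enumerate unordered pairs of known alleles
  nm <- sort(names(refs))
  pairs <- list(); unexplained <- list()
  for (i in seq_along(nm)) for (j in i:length(nm)) {
    u <- iupacUnion(refChars[[nm[i]]], refChars[[nm[j]]])
    bad <- which(u != chars & nonN)
    if (length(bad) == 0L) pairs[[length(pairs) + 1L]] <- c(nm[i], nm[j])
    unexplained[[paste(nm[i], nm[j])]] <- bad
  }
  if (length(pairs) == 1L) {
    p <- pairs[[1L]]
    res$status <- if (p[1L] == p[2L]) "homozygous" else "heterozygous"
    res$alleles <- p
  } else if (length(pairs) >= 2L) {
    res$status <- "ambiguous"
    res$candidates <- pairs  # already lexicographic: i outer, j inner sorted
  } else {
    res$status <- "novel"
    compat <- nm[vapply(nm, function(a) {
      all(mapply(function(b, s) b %in% .IUPAC_SETS[[s]],
                 refChars[[a]], chars))
    }, NA)]
    if (length(compat) == 1L) {
      comp <- .forceComplement(chars, refChars[[compat]])
      if (!is.null(comp)) {
        res$novel_complement <- paste(comp, collapse = "")
        res$alleles <- c(compat, NA_character_)
        # positions where the inferred complement departs from its anchor
        res$mismatch_positions <- which(comp != refChars[[compat]] &
                                          comp != "N") - 1L
      }
    }
    if (is.null(res$mismatch_positions)) {
      # no unique anchor: report the failure set of the best known pair
      best <- which.min(lengths(unexplained))
      res$mismatch_positions <- unexplained[[best]] - 1L
    }
  }
  res
}

# force the unobserved second allele given one compatible known allele;
# NULL when a position carries a 3/4-base symbol other than N (no
# two-allele union can produce it). N positions stay N (unresolvable).
.forceComplement <- function(chars, anchor) {
  out <- character(length(chars))
  for (i in seq_along(chars)) {
    s <- .IUPAC_SETS[[chars[i]]]
    if (chars[i] == "N") { out[i] <- "N"; next }
    if (length(s) > 2L) return(NULL)
    if (length(s) == 1L) out[i] <- s
    else out[i] <- setdiff(s, anchor[i])
  }
  out
}

#' @export
print.GenotypeCall <- function(x, ...) {
  cat(sprintf("GenotypeCall %s @ %s: %s", x$dog_id, x$locus, x$status))
  if (!is.null(x$alleles))
    cat(" [", paste(x$alleles, collapse = "/"), "]", sep = "")
  if (!is.null(x$candidates))
    cat(" candidates:",
        paste(vapply(x$candidates, paste, "", collapse = "/"),
              collapse = "; "))
  cat("\n")
  invisible(x)
}

#' Call genotypes for a whole cohort
#'
#' Applies [callGenotype()] to every consensus record. Record names must
#' follow the \code{"dog|locus"} header dialect. Records whose locus is
#' absent from the library, or whose length mismatches it, are reported
#' with status \code{missing} rather than failing the run.
#'
#' @param consensus named character vector or
#'   \code{Biostrings::DNAStringSet} of consensus sequences, names
#'   \code{"dog|locus"}.
#' @inheritParams callGenotype
#' @return data.frame with columns \code{dog_id}, \code{locus},
#'   \code{status}, \code{allele1}, \code{allele2}, \code{candidates}
#'   (pairs \code{"a/b"} joined by \code{";"}), \code{mismatch_positions}
#'   (0-based, \code{";"}-joined), \code{novel_complement}.
#' @export
callGenotypes <- function(consensus, library, strictN = FALSE) {
  seqs <- stats::setNames(as.character(consensus), names(consensus))
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("consensus records must be named 'dog|locus'")
  ids <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(ids) != 2L))
    stop("consensus record names must be 'dog|locus'")
  rows <- lapply(seq_along(seqs), function(k) {
    dog <- ids[[k]][1L]; locus <- ids[[k]][2L]
    call <- tryCatch(
      callGenotype(seqs[[k]], library, locus, dogId = dog,
                   strictN = strictN),
      error = function(e) {
        warning(sprintf("%s|%s: %s (reported as missing)", dog, locus,
                        conditionMessage(e)), call. = FALSE)
        list(dog_id = dog, locus = locus, status = "missing",
             alleles = NULL, candidates = NULL, mismatch_positions = NULL,
             novel_complement = NA_character_)
      })
    data.frame(
      dog_id = dog, locus = locus, status = call$status,
      allele1 = if (is.null(call$alleles)) NA_character_ else call$alleles[1L],
      allele2 = if (is.null(call$alleles)) NA_character_ else call$alleles[2L],
      candidates = if (is.null(call$candidates)) NA_character_ else
        paste(vapply(call$candidates, paste, "", collapse = "/"),
              collapse = ";"),
      mismatch_positions = if (is.null(call$mismatch_positions))
        NA_character_ else paste(call$mismatch_positions, collapse = ";"),
      novel_complement = call$novel_complement,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$dog_id, out$locus), , drop = FALSE]
}
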