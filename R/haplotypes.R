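# Three-locus haplotype inference by Clark-style parsimony phasing.
#
# The known-haplotype set H is seeded from individuals whose phase is
# certain (homozygous at all loci, or heterozygous at at most one), then
# heterozygotes are resolved iteratively: a dog is assigned the unique
# phasing whose two haplotypes are both already known; failing that, the
# unique phasing with exactly one known haplotype, whose complement then
# joins H. Dogs that never resolve are reported as "unidentified" --
# ambiguity is surfaced, never broken.

.hapLabel <- function(triple) paste(triple, collapse = "/")

#' Enumerate phase decompositions of a three-locus genotype
#'
#' All distinct unordered pairs of haplotypes consistent with the
#' per-locus allele pairs: \code{2^(h-1)} decompositions for \code{h}
#' heterozygous loci (one when \code{h} is 0 or 1). Deterministic order
#' (lexicographic by haplotype label pair).
#'
#' @param genotype list of three character pairs (allele names), in
#'   locus order, e.g. \code{list(c("a1","a2"), c("b1","b1"),
#'   c("c1","c2"))}.
#' @return list of decompositions; each is a list of two character
#'   triples (hap1 <= hap2 by label).
#' @examples
#' g <- list(c("a1","a2"), c("b1","b2"), c("c1","c2"))
#' length(enumeratePhasings(g))  # 4
#' @export
enumeratePhasings <- function(genotype) {
  if (length(genotype) != 3L ||
      any(vapply(genotype, length, 0L) != 2L) ||
      any(vapply(genotype, anyNA, NA)))
    stop("incomplete genotype: three per-locus allele pairs required")
  grid <- expand.grid(i = 1:2, j = 1:2, k = 1:2)
  seen <- character(0); out <- list()
  for (r in seq_len(nrow(grid))) {
    idx <- as.integer(grid[r, ])
    h1 <- vapply(1:3, function(l) genotype[[l]][idx[l]], "")
    h2 <- vapply(1:3, function(l) genotype[[l]][3L - idx[l]], "")
    pair <- list(h1, h2)
    labs <- c(.hapLabel(h1), .hapLabel(h2))
    if (labs[1L] > labs[2L]) { pair <- pair[2:1]; labs <- labs[2:1] }
    key <- paste(labs, collapse = "+")
    if (!key %in% seen) { seen <- c(seen, key); out[[length(out) + 1L]] <- pair }
  }
  out[order(seen)]
}

# collect per-dog genotypes from a calls data.frame; dogs with any
# non-hom/het locus call (or a missing locus) are phase-ineligible
.collectGenotypes <- function(calls, lociNames) {
  dogs <- sort(unique(calls$dog_id))
  out <- list()
  for (dog in dogs) {
    sub <- calls[calls$dog_id == dog, , drop = FALSE]
    g <- vector("list", length(lociNames))
    reason <- NULL
    for (l in seq_along(lociNames)) {
      row <- sub[sub$locus == lociNames[l], , drop = FALSE]
      if (nrow(row) == 0L) { reason <- paste0("no call at ", lociNames[l]); break }
      if (!row$status[1L] %in% c("homozygous", "heterozygous")) {
        reason <- paste0(row$status[1L], " at ", lociNames[l]); break
      }
      g[[l]] <- sort(c(row$allele1[1L], row$allele2[1L]))
    }
    out[[dog]] <- if (is.null(reason)) list(genotype = g) else
      list(genotype = NULL, reason = reason)
  }
  out
}

#' Infer three-locus haplotypes for a cohort
#'
#' Clark-style parsimony phasing over the three DLA class II loci (see
#' the file-level description above). Dogs with an ambiguous, novel or
#' missing call at any locus are excluded from phasing and reported as
#' unidentified. Iteration over dogs is in sorted \code{dog_id} order,
#' so results are independent of input row order.
#'
#' @param calls data.frame as returned by [callGenotypes()] (columns
#'   \code{dog_id}, \code{locus}, \code{status}, \code{allele1},
#'   \code{allele2}).
#' @param lociNames locus order defining the haplotype label, default
#'   \code{c("DRB1", "DQA1", "DQB1")}.
#' @param maxIter maximum resolution sweeps after seeding (fixpoint is
#'   typically reached in at most 3).
#' @param knownHaplotypes optional character vector of haplotype labels
#'   used to pre-seed the known set H.
#' @return list with elements
#'   \describe{
#'     \item{diplotypes}{data.frame: \code{dog_id}, \code{status}
#'       (\code{resolved}/\code{unidentified}), \code{hap1}, \code{hap2}
#'       (labels, hap1 <= hap2; NA when unidentified), \code{iteration},
#'       \code{provenance} (\code{unique}, \code{both-known},
#'       \code{one-known-extension}, or the exclusion reason).}
#'     \item{haplotypes}{sorted character vector: the discovered set H.}
#'   }
#' @export
inferHaplotypes <- function(calls, lociNames = c("DRB1", "DQA1", "DQB1"),
                            maxIter = 10L, knownHaplotypes = character(0)) {
  gens <- .collectGenotypes(calls, lociNames)
  dogs <- names(gens)
  H <- unique(knownHaplotypes)
  res <- data.frame(dog_id = dogs, status = "unidentified",
                    hap1 = NA_character_, hap2 = NA_character_,
                    iteration = NA_integer_, provenance = NA_character_,
                    stringsAsFactors = FALSE)
  rownames(res) <- dogs
  phasings <- list()

  # iteration 0: certain phases (h <= 1) seed H
  for (dog in dogs) {
    g <- gens[[dog]]
    if (is.null(g$genotype)) { res[dog, "provenance"] <- g$reason; next }
    ph <- enumeratePhasings(g$genotype)
    phasings[[dog]] <- ph
    if (length(ph) == 1L) {
      labs <- vapply(ph[[1L]], .hapLabel, "")
      res[dog, c("status", "hap1", "hap2")] <- c("resolved", labs)
      res[dog, "iteration"] <- 0L
      res[dog, "provenance"] <- "unique"
      H <- union(H, labs)
    }
  }

  for (iter in seq_len(maxIter)) {
    progressed <- FALSE
    pending <- dogs[res$status == "unidentified" &
                      dogs %in% names(phasings)]
    for (dog in pending) {
      ph <- phasings[[dog]]
      labs <- lapply(ph, function(p) vapply(p, .hapLabel, ""))
      nKnown <- vapply(labs, function(l) sum(l %in% H), 0L)
      pick <- NULL; prov <- NULL
      if (sum(nKnown == 2L) == 1L) {
        pick <- labs[[which(nKnown == 2L)]]; prov <- "both-known"
      } else if (sum(nKnown == 2L) == 0L && sum(nKnown == 1L) == 1L) {
        pick <- labs[[which(nKnown == 1L)]]; prov <- "one-known-extension"
      }
      if (!is.null(pick)) {
        res[dog, c("status", "hap1", "hap2")] <- c("resolved", pick)
        res[dog, "iteration"] <- iter
        res[dog, "provenance"] <- prov
        H <- union(H, pick)
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  res$iteration <- as.integer(res$iteration)
  unres <- res$status == "unidentified" & is.na(res$provenance)
  res$provenance[unres] <- "no-resolving-rule"
  rownames(res) <- NULL
  list(diplotypes = res, haplotypes = sort(H))
}

#' Per-cohort haplotype copy counts
#'
#' Each resolved dog contributes two haplotype copies; each unidentified
#' dog contributes two copies to the \code{Unidentified} row, so copy
#' counts sum to twice the cohort size. Frequencies are counts over
#' 2 x (cohort size).
#'
#' @param diplotypes data.frame from [inferHaplotypes()].
#' @param samples data.frame with columns \code{dog_id}, \code{status}
#'   (\code{affected}/\code{control}).
#' @return data.frame: \code{haplotype}, \code{n_affected},
#'   \code{freq_affected}, \code{n_control}, \code{freq_control}, sorted
#'   by descending total count then label, \code{Unidentified} last.
#' @export
countHaplotypes <- function(diplotypes, samples) {
  m <- merge(diplotypes, samples[, c("dog_id", "status")],
             by = "dog_id", suffixes = c("", ".cohort"))
  if (nrow(m) != nrow(diplotypes))
    stop("sample sheet is missing dogs present in the diplotype table")
  cohorts <- c(affected = "affected", control = "control")
  tallies <- lapply(cohorts, function(co) {
    sub <- m[m$status.cohort == co, , drop = FALSE]
    copies <- c(sub$hap1[sub$status == "resolved"],
                sub$hap2[sub$status == "resolved"],
                rep("Unidentified", 2L * sum(sub$status != "resolved")))
    table(copies)
  })
  haps <- sort(unique(c(names(tallies$affected), names(tallies$control))))
  get <- function(t, h) ifelse(h %in% names(t), as.integer(t[h]), 0L)
  nAff <- 2L * sum(m$status.cohort == "affected")
  nCtl <- 2L * sum(m$status.cohort == "control")
  out <- data.frame(
    haplotype = haps,
    n_affected = vapply(haps, function(h) get(tallies$affected, h), 0L),
    n_control = vapply(haps, function(h) get(tallies$control, h), 0L),
    stringsAsFactors = FALSE)
  out$freq_affected <- if (nAff) out$n_affected / nAff else NA_real_
  out$freq_control <- if (nCtl) out$n_control / nCtl else NA_real_
  unid <- out$haplotype == "Unidentified"
  tot <- out$n_affected + out$n_control
  out <- rbind(out[!unid, ][order(-tot[!unid], out$haplotype[!unid]), ],
               out[unid, ])
  rownames(out) <- NULL
  out[, c("haplotype", "n_affected", "freq_affected",
          "n_control", "freq_control")]
}
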