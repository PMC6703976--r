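# Case-control 2x2 association statistics.
#
# Convention (verified to reproduce the published allele, haplotype and
# homozygosity tables from their count columns): OR = ad/bc; when any
# cell is zero, 0.5 is added to every cell (Haldane-Anscombe) before OR,
# CI and P; 95% CI is the Woolf logit interval ln(OR) +/- z*SE with
# SE = sqrt(1/a + 1/b + 1/c + 1/d) and the conventional critical value
# z = 1.96; the two-sided P is the Wald normal test of ln(OR) = 0.
# Pearson chi-square and Fisher's exact test do NOT reproduce the
# published P-values; this convention does, row for row.

.corrected2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("negative cell count")
  if (a + b == 0 || c + d == 0)
    stop("undefined table: a cohort has zero total")
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  list(a = a, b = b, c = c, d = d, corrected = corrected)
}

#' Odds ratio of a 2x2 case-control table
#'
#' \code{(a*d)/(b*c)} on the table (a = affected units carrying the
#' feature, b = affected not carrying it, c / d likewise for controls).
#' If any cell is zero, 0.5 is first added to every cell
#' (Haldane-Anscombe) and \code{corrected} is flagged.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return list with \code{or} and logical \code{corrected}.
#' @examples
#' oddsRatio(14, 54, 8, 124)$or   # 4.0185
#' oddsRatio(1, 67, 0, 132)       # 5.889, corrected
#' @export
oddsRatio <- function(a, b, c, d) {
  t <- .corrected2x2(a, b, c, d)
  list(or = (t$a * t$d) / (t$b * t$c), corrected = t$corrected)
}

#' Woolf (logit) confidence interval for an odds ratio
#'
#' \code{exp(ln(OR) +/- z * SE)} with \code{SE = sqrt(1/a + 1/b + 1/c +
#' 1/d)} on the (zero-cell corrected) table. The default critical value
#' is the conventional reporting value 1.96; pass
#' \code{zCrit = qnorm(0.975)} for the exact quantile, or another
#' quantile for a different level.
#'
#' @inheritParams oddsRatio
#' @param zCrit normal critical value.
#' @return numeric \code{c(ci_low, ci_high)}.
#' @examples
#' woolfCI(14, 54, 8, 124)  # 1.59 10.14
#' @export
woolfCI <- function(a, b, c, d, zCrit = 1.96) {
  t <- .corrected2x2(a, b, c, d)
  lor <- log((t$a * t$d) / (t$b * t$c))
  se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  stats::setNames(exp(lor + c(-1, 1) * zCrit * se), c("ci_low", "ci_high"))
}

#' Two-sided Wald test of ln(OR) = 0
#'
#' \code{z = |ln(OR)| / SE} on the (zero-cell corrected) table;
#' \code{p = 2 * (1 - Phi(z))}.
#'
#' @inheritParams oddsRatio
#' @return two-sided p-value.
#' @examples
#' waldP(14, 54, 8, 124)  # 0.0032
#' waldP(5, 5, 5, 5)      # 1
#' @export
waldP <- function(a, b, c, d) {
  t <- .corrected2x2(a, b, c, d)
  lor <- log((t$a * t$d) / (t$b * t$c))
  se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  2 * stats::pnorm(abs(lor) / se, lower.tail = FALSE)
}

#' Full association statistics for one 2x2 table
#'
#' @inheritParams woolfCI
#' @return one-row data.frame: \code{a}, \code{b}, \code{c}, \code{d},
#'   \code{freq_affected}, \code{freq_control}, \code{or_value},
#'   \code{ci_low}, \code{ci_high}, \code{p_value}, \code{corrected}.
#' @examples
#' associationTest(10, 24, 8, 58)  # three-locus homozygosity test
#' @export
associationTest <- function(a, b, c, d, zCrit = 1.96) {
  or <- oddsRatio(a, b, c, d)
  ci <- woolfCI(a, b, c, d, zCrit = zCrit)
  data.frame(a = a, b = b, c = c, d = d,
             freq_affected = a / (a + b), freq_control = c / (c + d),
             or_value = or$or, ci_low = unname(ci[1L]),
             ci_high = unname(ci[2L]), p_value = waldP(a, b, c, d),
             corrected = or$corrected)
}

.splitCohorts <- function(samples) {
  if (!all(c("dog_id", "status") %in% names(samples)))
    stop("sample sheet needs columns dog_id, status")
  bad <- setdiff(unique(samples$status), c("affected", "control"))
  if (length(bad))
    stop("unknown status label(s): ", paste(bad, collapse = ", "))
  split(samples$dog_id, samples$status)
}

#' Tabulate allele-copy 2x2 tables per locus
#'
#' Each dog with a resolved (homozygous or heterozygous) call at a locus
#' contributes two allele copies there; dogs with ambiguous, novel or
#' missing calls are excluded from that locus's denominators (the
#' published denominators imply complete typing).
#'
#' @param calls data.frame from [callGenotypes()].
#' @param samples sample sheet: \code{dog_id}, \code{status}
#'   (\code{affected}/\code{control}).
#' @return data.frame with one row per locus x allele: \code{locus},
#'   \code{feature}, \code{a}, \code{b}, \code{c}, \code{d}.
#' @export
tabulateAlleleCounts <- function(calls, samples) {
  co <- .splitCohorts(samples)
  ok <- calls[calls$status %in% c("homozygous", "heterozygous"), ,
              drop = FALSE]
  out <- list()
  for (locus in unique(calls$locus)) {
    sub <- ok[ok$locus == locus, , drop = FALSE]
    copies <- data.frame(
      dog = rep(sub$dog_id, 2L),
      allele = c(sub$allele1, sub$allele2), stringsAsFactors = FALSE)
    isAff <- copies$dog %in% co$affected
    totA <- sum(isAff); totC <- sum(!isAff)
    for (al in sort(unique(copies$allele))) {
      a <- sum(isAff & copies$allele == al)
      c_ <- sum(!isAff & copies$allele == al)
      out[[length(out) + 1L]] <- data.frame(
        locus = locus, feature = al, a = a, b = totA - a,
        c = c_, d = totC - c_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Tabulate haplotype-copy 2x2 tables
#'
#' Denominators are twice the cohort sizes; unidentified dogs'
#' copies count against every haplotype's "not carrying" cell and are
#' reported as an \code{Unidentified} row (no statistics are computed
#' for it downstream).
#'
#' @param hapCounts data.frame from [countHaplotypes()].
#' @return data.frame: \code{feature}, \code{a}, \code{b}, \code{c},
#'   \code{d}.
#' @export
tabulateHaplotypeCounts <- function(hapCounts) {
  totA <- sum(hapCounts$n_affected)
  totC <- sum(hapCounts$n_control)
  data.frame(feature = hapCounts$haplotype,
             a = hapCounts$n_affected, b = totA - hapCounts$n_affected,
             c = hapCounts$n_control, d = totC - hapCounts$n_control,
             stringsAsFactors = FALSE)
}

#' Tabulate the three-locus homozygosity 2x2 table
#'
#' The unit is the dog: a carrier is homozygous at all three loci.
#' Dogs not fully typed at every locus are excluded.
#'
#' @inheritParams tabulateAlleleCounts
#' @param lociNames the loci that must all be homozygous.
#' @return one-row data.frame: \code{feature}, \code{a}, \code{b},
#'   \code{c}, \code{d}.
#' @export
tabulateHomozygosity <- function(calls, samples,
                                 lociNames = c("DRB1", "DQA1", "DQB1")) {
  co <- .splitCohorts(samples)
  dogs <- sort(unique(calls$dog_id))
  typed <- vapply(dogs, function(dog) {
    sub <- calls[calls$dog_id == dog & calls$locus %in% lociNames, ]
    nrow(sub) == length(lociNames) &&
      all(sub$status %in% c("homozygous", "heterozygous"))
  }, NA)
  homo <- vapply(dogs, function(dog) {
    sub <- calls[calls$dog_id == dog & calls$locus %in% lociNames, ]
    nrow(sub) == length(lociNames) && all(sub$status == "homozygous")
  }, NA)
  aff <- dogs %in% co$affected
  data.frame(feature = "three_locus_homozygous",
             a = sum(typed & homo & aff), b = sum(typed & !homo & aff),
             c = sum(typed & homo & !aff), d = sum(typed & !homo & !aff),
             stringsAsFactors = FALSE)
}

#' Association report over a table of 2x2 counts
#'
#' Runs [associationTest()] on every feature row and returns the
#' publication-style table: counts, frequencies, OR, 95% CI, two-sided
#' P. Rows are sorted by descending total count, then feature label; an
#' \code{Unidentified} row (unresolved haplotype copies) is kept, last,
#' with NA statistics. No multiple-testing adjustment is applied, by
#' design: the typing stage tests a handful of pre-specified features.
#'
#' @param counts data.frame with columns \code{feature}, \code{a},
#'   \code{b}, \code{c}, \code{d} (any extra columns are carried
#'   through).
#' @param zCrit normal critical value for the CI.
#' @return data.frame: carried columns plus \code{n_affected},
#'   \code{freq_affected}, \code{n_control}, \code{freq_control},
#'   \code{p_value}, \code{or_value}, \code{ci_low}, \code{ci_high},
#'   \code{corrected}.
#' @export
associationReport <- function(counts, zCrit = 1.96) {
  stat <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    if (r$feature == "Unidentified")
      return(data.frame(freq_affected = r$a / (r$a + r$b),
                        freq_control = r$c / (r$c + r$d),
                        or_value = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_,
                        corrected = NA))
    associationTest(r$a, r$b, r$c, r$d, zCrit = zCrit)[
      , c("freq_affected", "freq_control", "or_value", "ci_low",
          "ci_high", "p_value", "corrected")]
  })
  out <- cbind(counts, do.call(rbind, stat))
  out$n_affected <- out$a; out$n_control <- out$c
  unid <- out$feature == "Unidentified"
  tot <- out$a + out$c
  out <- rbind(out[!unid, ][order(-tot[!unid], out$feature[!unid]), ],
               out[unid, ])
  rownames(out) <- NULL
  keep <- c(setdiff(names(counts), c("a", "b", "c", "d")),
            "n_affected", "freq_affected", "n_control", "freq_control",
            "p_value", "or_value", "ci_low", "ci_high", "corrected")
  out[, keep]
}
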