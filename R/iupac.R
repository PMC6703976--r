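# IUPAC nucleotide ambiguity logic used by the typing stage.
#
# A direct-sequencing consensus of a diploid sample encodes a
# heterozygous position as the IUPAC symbol whose base set is the union
# of the two allele bases (R = A/G, S = C/G, ...). Typing inverts this:
# a pair of reference alleles "explains" a consensus when the
# position-wise union of the pair reproduces it exactly.

# symbol -> base set, the 15 standard nucleotide codes
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.IUPAC_SYMBOLS <- names(.IUPAC_SETS)

# 4x4 lookup: union symbol of two unambiguous bases
.UNION_MATRIX <- local({
  b <- c("A", "C", "G", "T")
  m <- matrix("", 4, 4, dimnames = list(b, b))
  key <- vapply(.IUPAC_SETS, function(s) paste(sort(s), collapse = ""), "")
  rev <- stats::setNames(names(key), key)
  for (x in b) for (y in b)
    m[x, y] <- rev[[paste(sort(unique(c(x, y))), collapse = "")]]
  m
})

.charSplit <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

#' Union of two unambiguous bases as an IUPAC symbol
#'
#' Returns the IUPAC nucleotide code whose base set is \{b1\} U \{b2\};
#' this is the symbol a diploid consensus shows at a position where the
#' two chromosome copies carry \code{b1} and \code{b2}. Commutative, and
#' the identity on equal inputs. Vectorised over positions.
#'
#' @param b1,b2 character vectors of single bases in A/C/G/T
#'   (case-insensitive).
#' @return character vector of IUPAC symbols.
#' @examples
#' iupacUnion("A", "G")  # "R"
#' iupacUnion(c("A", "C"), c("A", "G"))  # "A" "S"
#' @export
iupacUnion <- function(b1, b2) {
  b1 <- toupper(b1); b2 <- toupper(b2)
  ok <- b1 %in% c("A", "C", "G", "T") & b2 %in% c("A", "C", "G", "T")
  if (!all(ok))
    stop("iupacUnion: inputs must be unambiguous bases A/C/G/T, got: ",
         paste(unique(c(b1[!ok], b2[!ok])), collapse = ", "))
  .UNION_MATRIX[cbind(b1, b2)]
}

#' Does an allele pair explain a consensus sequence?
#'
#' TRUE when, at every position, the IUPAC union of the two allele bases
#' equals the consensus symbol. In particular every unambiguous
#' consensus position requires both alleles to match it. An \code{N} in
#' the consensus is treated as a wildcard compatible with any pair
#' (disable with \code{allowN = FALSE}).
#'
#' @param consensus consensus string over the 15 IUPAC symbols.
#' @param a1,a2 reference allele sequences (A/C/G/T), same length as
#'   \code{consensus}.
#' @param allowN logical; treat consensus \code{N} as a wildcard.
#' @return logical scalar.
#' @examples
#' pairExplains("ARG", "AAG", "AGG")  # TRUE
#' pairExplains("AAG", "AAG", "AGG")  # FALSE
#' @export
pairExplains <- function(consensus, a1, a2, allowN = TRUE) {
  if (nchar(consensus) != nchar(a1) || nchar(consensus) != nchar(a2))
    stop("pairExplains: sequence length mismatch")
  cons <- .charSplit(toupper(consensus))
  u <- iupacUnion(.charSplit(toupper(a1)), .charSplit(toupper(a2)))
  if (allowN) all(u == cons | cons == "N") else all(u == cons)
}

# validate a consensus string; returns the character vector of symbols
.consensusChars <- function(seq, strictN = FALSE) {
  chars <- .charSplit(toupper(seq))
  bad <- setdiff(unique(chars), .IUPAC_SYMBOLS)
  if (length(bad))
    stop("invalid consensus symbol(s): ", paste(bad, collapse = ", "))
  if (strictN && any(chars == "N"))
    stop("consensus contains N and strict N handling is enabled")
  chars
}
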