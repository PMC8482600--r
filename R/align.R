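# Global-alignment primitives shared by the array-hit test, repeat
# clustering and subtype assignment. Scoring follows the published scheme:
# match +1, mismatch 0, and a linear gap cost of 3 per gapped position
# (equivalent to gap open -3 / gap extend -3 in the affine parameterisation
# where the opening position already pays the extension).

align_submat <- local({
  m <- matrix(0, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                       c("A", "C", "G", "T", "N")))
  diag(m)[1:4] <- 1
  m
})

# count identical, non-N aligned positions given two aligned strings
count_identities <- function(aln_a, aln_b) {
  a <- strsplit(aln_a, "")
  b <- strsplit(aln_b, "")
  vapply(seq_along(a), function(i) {
    ai <- a[[i]]; bi <- b[[i]]
    sum(ai == bi & ai %in% c("A", "C", "G", "T"))
  }, integer(1))
}

# Global alignment of each pattern against one subject; returns identities
# and alignment lengths. Vectorised over patterns.
global_align_stats <- function(patterns, subject) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(patterns),
    subject = Biostrings::DNAString(subject),
    type = "global", substitutionMatrix = align_submat,
    gapOpening = 0, gapExtension = 3)
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  list(n_ident = count_identities(ap, as_), align_len = nchar(ap))
}

#' Global alignment identity between two sequences
#'
#' Identities in a global alignment (match +1, mismatch 0, linear gap cost 3
#' per position) divided by the alignment length. Orientation-aware callers
#' pass the reverse complement explicitly; this function never flips strands.
#'
#' @param a,b non-empty DNA strings (vectorised, recycled to a common
#'   length).
#' @return identity fraction(s) in `[0, 1]`.
#' @examples
#' global_identity("ACGTACGT", "ACGTACGT") # 1
#' @export
global_identity <- function(a, b) {
  stopifnot(all(nchar(a) > 0), all(nchar(b) > 0))
  st <- global_identities(a, b)
  st$n_ident / st$align_len
}
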