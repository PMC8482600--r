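# Small sequence helpers shared across modules.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# base set (sorted) -> IUPAC code
SET_TO_IUPAC <- local({
  codes <- vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = ""), "")
  stats::setNames(names(codes), codes)
})

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement; `N` maps to `N`.
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- character(length(x))
  nz <- nchar(x) > 0L
  out[!nz] <- ""
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out
}

#' Fraction of G+C bases in a DNA string
#'
#' `N` bases are excluded from both numerator and denominator.
#'
#' @param x character vector of DNA sequences.
#' @return numeric vector of GC fractions in `[0, 1]` (`NaN` for all-N input).
#' @export
gc_content <- function(x) {
  vapply(strsplit(toupper(x), ""), function(ch) {
    ch <- ch[ch %in% c("A", "C", "G", "T")]
    if (length(ch) == 0L) return(NaN)
    mean(ch %in% c("C", "G"))
  }, numeric(1))
}

# Normalise a sequence: upcase, U->T, any non-ACGT ambiguity code -> N.
# Returns the sequence; warns (once per call) when codes were replaced.
normalize_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    warning(sprintf("%d %s(s) contained non-ACGTN ambiguity codes; mapped to N",
                    sum(bad), what), call. = FALSE)
    x[bad] <- gsub("[^ACGTN]", "N", x[bad])
  }
  x
}

# random DNA with i.i.d. bases at a given GC content
random_dna <- function(n, len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, "")
}

# substring that pads out-of-range positions with N (1-based inclusive)
substr_padded <- function(seq, start, end) {
  n <- nchar(seq)
  left_pad <- max(0L, 1L - start)
  right_pad <- max(0L, end - n)
  core <- substr(seq, max(1L, start), min(n, end))
  paste0(strrep("N", left_pad), core, strrep("N", right_pad))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
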