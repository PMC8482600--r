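# Independent oracles used across the suite. These deliberately avoid the
# package's own alignment/statistics code paths.

# Brute-force global alignment by exhaustive enumeration (tiny inputs only):
# maximise score (match +1, mismatch 0, 3 per gapped position), break ties
# towards more identities, then more aligned pairs. Returns score, n_ident,
# align_len of the selected optimum.
brute_force_global <- function(a, b, gap = 3) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  best <- c(score = -Inf, ident = -Inf, diag = -Inf)
  rec <- function(i, j, score, ident, diag, len) {
    if (i > length(ac) && j > length(bc)) {
      cand <- c(score, ident, diag)
      if (cand[1] > best[1] ||
          (cand[1] == best[1] && cand[2] > best[2]) ||
          (cand[1] == best[1] && cand[2] == best[2] && cand[3] > best[3])) {
        best <<- c(score = score, ident = ident, diag = diag)
        best_len <<- len
      }
      return(invisible())
    }
    if (i <= length(ac) && j <= length(bc)) {
      m <- ac[i] == bc[j] && ac[i] %in% c("A", "C", "G", "T")
      rec(i + 1, j + 1, score + as.numeric(m), ident + as.integer(m),
          diag + 1, len + 1)
    }
    if (i <= length(ac)) rec(i + 1, j, score - gap, ident, diag, len + 1)
    if (j <= length(bc)) rec(i, j + 1, score - gap, ident, diag, len + 1)
  }
  best_len <- NA_integer_
  rec(1, 1, 0, 0L, 0L, 0L)
  list(score = unname(best[1]), n_ident = unname(best[2]),
       align_len = length(ac) + length(bc) - unname(best[3]))
}

# Biostrings score of the same global / overlap alignment problem: the
# independent implementation the DP is checked against.
bs_align_score <- function(a, b, type = "global") {
  submat <- matrix(0, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                            c("A", "C", "G", "T", "N")))
  diag(submat)[1:4] <- 1
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(a),
    subject = Biostrings::DNAString(b),
    type = type, substitutionMatrix = submat,
    gapOpening = 0, gapExtension = 3)
  Biostrings::score(pa)
}

# Exhaustive two-sided binomial p-value at p0 = 0.5: sum of the
# probabilities of all outcomes no more likely than the observed one.
brute_force_binom_p <- function(x, n) {
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-9)])
}

# Per-position information content computed directly from an observation
# multiset (character vector of bases), relative to a background.
brute_force_ic <- function(obs, background) {
  obs <- obs[obs %in% c("A", "C", "G", "T")]
  if (!length(obs)) return(0)
  tot <- 0
  for (b in unique(obs)) {
    f <- sum(obs == b) / length(obs)
    tot <- tot + f * log2(f / background[[b]])
  }
  tot
}

# Exhaustive sliding-window matcher: every (position, strand) where the
# spacer matches the subject with at most max_sub substitutions.
sliding_window_hits <- function(spacer, subject, max_sub = 3) {
  L <- nchar(spacer)
  n <- nchar(subject)
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") spacer else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(spacer)))
    qc <- strsplit(q, "")[[1]]
    for (s in 0:(n - L)) {
      w <- strsplit(substr(subject, s + 1, s + L), "")[[1]]
      if (sum(qc != w) <= max_sub) {
        out[[length(out) + 1]] <- data.frame(s_start = s, s_end = s + L,
                                             strand = strand)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(s_start = integer(), s_end = integer(), strand = character())
}

rc <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
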