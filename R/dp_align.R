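# Vectorised alignment DPs used on the hot paths. Scoring follows the
# published scheme (match +1, mismatch 0, 3 per gapped position). Two
# flavours:
#   * ends-free ("overlap") alignment for the repeat-vs-flank array test --
#     leading/trailing gaps in either sequence are free, which is what makes
#     the >13-identity threshold discriminative (a 23-nt flank can sit
#     flush inside a ~30-nt repeat without paying end gaps, while random
#     pairs rarely exceed 13 identities);
#   * pattern-global / subject-ends-free alignment for gapped hit
#     refinement (the whole spacer must align; the subject window is open).
# Both are vectorised across many (a, b) pairs of common lengths and report
# the maximum identity count among score-optimal alignments (deterministic
# tie-break), so results do not depend on which co-optimal alignment an
# external library happens to return.

# integer-code a character vector of equal-length sequences into an
# n x L matrix; non-ACGT -> 0 (never matches)
code_seq_matrix <- function(x, L) {
  ch <- matrix(unlist(strsplit(x, "")), ncol = L, byrow = TRUE)
  m <- matrix(match(ch, c("A", "C", "G", "T"), nomatch = 0L), ncol = L)
  m
}

# ends-free alignment of a[i] vs b[i] for all i; all a equal length, all b
# equal length. Returns list(score, n_ident).
ends_free_align_group <- function(a, b, gap = 3) {
  n <- length(a)
  La <- nchar(a[1]); Lb <- nchar(b[1])
  A <- code_seq_matrix(a, La)
  B <- code_seq_matrix(b, Lb)
  NEG <- -1e9
  # rows: DP over b positions 0..Lb for current a position
  S_prev <- matrix(0, n, Lb + 1L)   # free leading gaps
  I_prev <- matrix(0L, n, Lb + 1L)
  best_S <- rep(0, n)               # empty alignment allowed at the edges
  best_I <- rep(0L, n)
  for (i in seq_len(La)) {
    S_cur <- matrix(NEG, n, Lb + 1L)
    I_cur <- matrix(0L, n, Lb + 1L)
    S_cur[, 1] <- 0                 # free leading gaps in b
    for (j in seq_len(Lb)) {
      mt <- as.numeric(A[, i] > 0L & A[, i] == B[, j])
      s_diag <- S_prev[, j] + mt
      i_diag <- I_prev[, j] + as.integer(mt)
      s_up <- S_prev[, j + 1L] - gap
      i_up <- I_prev[, j + 1L]
      s_left <- S_cur[, j] - gap
      i_left <- I_cur[, j]
      s <- pmax(s_diag, s_up, s_left)
      # best identities among transitions achieving the optimal score
      id <- pmax(ifelse(s_diag >= s, i_diag, -1L),
                 ifelse(s_up >= s, i_up, -1L),
                 ifelse(s_left >= s, i_left, -1L))
      S_cur[, j + 1L] <- s
      I_cur[, j + 1L] <- id
    }
    # trailing gaps in b are free: alignment may end at the last a row (any j)
    if (i == La) {
      for (j in 0:Lb) {
        upd <- S_cur[, j + 1L] > best_S |
          (S_cur[, j + 1L] == best_S & I_cur[, j + 1L] > best_I)
        best_S[upd] <- S_cur[upd, j + 1L]
        best_I[upd] <- I_cur[upd, j + 1L]
      }
    } else {
      # trailing gaps in a are free: alignment may end at the last b column
      upd <- S_cur[, Lb + 1L] > best_S |
        (S_cur[, Lb + 1L] == best_S & I_cur[, Lb + 1L] > best_I)
      best_S[upd] <- S_cur[upd, Lb + 1L]
      best_I[upd] <- I_cur[upd, Lb + 1L]
    }
    S_prev <- S_cur
    I_prev <- I_cur
  }
  list(score = best_S, n_ident = best_I)
}

#' Ends-free alignment identities
#'
#' For each pair `(a[i], b[i])`, the maximum identity count among
#' score-optimal ends-free alignments under the scheme match +1, mismatch 0,
#' 3 per gapped position (leading/trailing gaps free). Pairs are grouped by
#' length internally; sequences within a vector may differ in length.
#'
#' @param a,b character vectors of DNA sequences (recycled to a common
#'   length).
#' @return list with numeric `score` and integer `n_ident` per pair.
#' @export
ends_free_identities <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  score <- numeric(n); n_ident <- integer(n)
  grp <- paste(nchar(a), nchar(b))
  for (g in unique(grp)) {
    sel <- grp == g
    r <- ends_free_align_group(a[sel], b[sel])
    score[sel] <- r$score
    n_ident[sel] <- r$n_ident
  }
  list(score = score, n_ident = n_ident)
}

# Pattern-global, subject-ends-free alignment of q[i] within window w[i]
# (identical lengths per group assumed by the caller). Returns per pair the
# identity count of the best alignment and the consumed subject interval
# (0-based half-open within the window). Used for gapped hit refinement.
glocal_align_group <- function(q, w, gap = 3) {
  n <- length(q)
  Lq <- nchar(q[1]); Lw <- nchar(w[1])
  A <- code_seq_matrix(q, Lq)
  B <- code_seq_matrix(w, Lw)
  NEG <- -1e9
  S_prev <- matrix(0, n, Lw + 1L)       # free leading subject gaps
  I_prev <- matrix(0L, n, Lw + 1L)
  T_prev <- matrix(0L, n, Lw + 1L)      # subject start carried along path
  T_prev[] <- matrix(rep(0:Lw, each = n), n, Lw + 1L)
  for (i in seq_len(Lq)) {
    S_cur <- matrix(NEG, n, Lw + 1L)
    I_cur <- matrix(0L, n, Lw + 1L)
    T_cur <- matrix(0L, n, Lw + 1L)
    S_cur[, 1] <- -gap * i              # pattern consumed against gaps
    for (j in seq_len(Lw)) {
      mt <- as.numeric(A[, i] > 0L & A[, i] == B[, j])
      cand_s <- cbind(S_prev[, j] + mt, S_prev[, j + 1L] - gap,
                      S_cur[, j] - gap)
      cand_i <- cbind(I_prev[, j] + as.integer(mt), I_prev[, j + 1L],
                      I_cur[, j])
      cand_t <- cbind(T_prev[, j], T_prev[, j + 1L], T_cur[, j])
      s <- pmax(cand_s[, 1], cand_s[, 2], cand_s[, 3])
      ok <- cand_s >= s - 1e-9
      ci <- ifelse(ok, cand_i, -1L)
      id <- pmax(ci[, 1], ci[, 2], ci[, 3])
      # among score+identity optimal, take the leftmost start
      ct <- ifelse(ok & ci == id, cand_t, .Machine$integer.max)
      tt <- pmin(ct[, 1], ct[, 2], ct[, 3])
      S_cur[, j + 1L] <- s
      I_cur[, j + 1L] <- id
      T_cur[, j + 1L] <- tt
    }
    S_prev <- S_cur; I_prev <- I_cur; T_prev <- T_cur
  }
  # free trailing subject gaps: best over final row
  best_j <- max.col(S_prev, ties.method = "first") # includes column j=0
  pick <- cbind(seq_len(n), best_j)
  list(n_ident = I_prev[pick],
       s_start = T_prev[pick],
       s_end = best_j - 1L,
       score = S_prev[pick])
}

# True global (Needleman-Wunsch) alignment for pairs (a[i], b[i]) of common
# lengths per group, same scoring scheme. Tie-break among co-optimal
# alignments: maximum identities, then most aligned pairs (shortest
# alignment). Returns score, n_ident and alignment length.
nw_align_group <- function(a, b, gap = 3) {
  n <- length(a)
  La <- nchar(a[1]); Lb <- nchar(b[1])
  A <- code_seq_matrix(a, La)
  B <- code_seq_matrix(b, Lb)
  S_prev <- matrix(rep(-gap * (0:Lb), each = n), n, Lb + 1L)
  I_prev <- matrix(0L, n, Lb + 1L)
  D_prev <- matrix(0L, n, Lb + 1L)  # diagonal (aligned-pair) steps
  for (i in seq_len(La)) {
    S_cur <- matrix(0, n, Lb + 1L)
    I_cur <- matrix(0L, n, Lb + 1L)
    D_cur <- matrix(0L, n, Lb + 1L)
    S_cur[, 1] <- -gap * i
    for (j in seq_len(Lb)) {
      mt <- as.numeric(A[, i] > 0L & A[, i] == B[, j])
      s_diag <- S_prev[, j] + mt
      s_up <- S_prev[, j + 1L] - gap
      s_left <- S_cur[, j] - gap
      s <- pmax(s_diag, s_up, s_left)
      i_diag <- ifelse(s_diag >= s, I_prev[, j] + as.integer(mt), -1L)
      i_up <- ifelse(s_up >= s, I_prev[, j + 1L], -1L)
      i_left <- ifelse(s_left >= s, I_cur[, j], -1L)
      id <- pmax(i_diag, i_up, i_left)
      dd <- pmax(ifelse(i_diag == id, D_prev[, j] + 1L, -1L),
                 ifelse(i_up == id, D_prev[, j + 1L], -1L),
                 ifelse(i_left == id, D_cur[, j], -1L))
      S_cur[, j + 1L] <- s
      I_cur[, j + 1L] <- id
      D_cur[, j + 1L] <- dd
    }
    S_prev <- S_cur; I_prev <- I_cur; D_prev <- D_cur
  }
  list(score = S_prev[, Lb + 1L],
       n_ident = I_prev[, Lb + 1L],
       align_len = La + Lb - D_prev[, Lb + 1L])
}

#' Global alignment identities over many pairs
#'
#' Vectorised Needleman-Wunsch (match +1, mismatch 0, 3 per gapped
#' position) reporting, per pair, the identity count, alignment length and
#' score of the optimal alignment (ties resolved towards more identities,
#' then shorter alignments).
#'
#' @param a,b character vectors of DNA sequences (recycled to a common
#'   length).
#' @return list with `score`, `n_ident`, `align_len` per pair.
#' @export
global_identities <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  score <- numeric(n); n_ident <- integer(n); align_len <- integer(n)
  grp <- paste(nchar(a), nchar(b))
  for (g in unique(grp)) {
    sel <- grp == g
    r <- nw_align_group(a[sel], b[sel])
    score[sel] <- r$score
    n_ident[sel] <- r$n_ident
    align_len[sel] <- r$align_len
  }
  list(score = score, n_ident = n_ident, align_len = align_len)
}
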