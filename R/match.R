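# Internal spacer->subject matcher: exact k-mer seeding (default word size
# 10) on both strands, ungapped extension along the seed diagonal over the
# full spacer length, and a banded gapped refinement (band 3) when the
# ungapped alignment leaves enough mismatches to hide an indel. The matcher
# approximates a permissive blastn-style search; no e-value is computed
# because filtering uses the matched fraction only.

# k-mer index over all subjects: data.table(kmer, sidx, pos) with pos 1-based
build_kmer_index <- function(subjects, k) {
  pieces <- lapply(seq_len(nrow(subjects)), function(i) {
    s <- subjects$sequence[i]
    n <- nchar(s)
    if (n < k) return(NULL)
    data.table::data.table(kmer = substring(s, 1:(n - k + 1), k:n),
                           sidx = i, pos = 1:(n - k + 1))
  })
  idx <- data.table::rbindlist(pieces)
  if (nrow(idx)) data.table::setkey(idx, kmer)
  idx
}

# identities of `query_chars` laid along subject at 0-based start `d`
# (no gaps); counts over the in-bounds overlap only
diagonal_identities <- function(query_chars, subject, d) {
  L <- length(query_chars)
  n <- nchar(subject)
  lo <- max(0L, d)
  hi <- min(n, d + L)
  if (hi <= lo) return(0L)
  win <- strsplit(substr(subject, lo + 1L, hi), "")[[1]]
  q <- query_chars[(lo - d + 1L):(hi - d)]
  sum(q == win & q %in% c("A", "C", "G", "T"))
}

#' Find spacer matches in subject sequences
#'
#' Seed-and-extend search of every spacer against every subject, on both
#' strands. Matches share at least one exact `config$seed_word`-mer with the
#' subject; identities come from ungapped extension along the seed diagonal,
#' refined by a banded (band 3) gapped alignment when enough mismatches
#' remain to hide an indel. Hits of the same spacer overlapping a better hit
#' by at least half are collapsed to the best one.
#'
#' @param records spacer record table; spacers shorter than
#'   `config$seed_word` yield no hits.
#' @param subjects subject table ([read_fasta()]).
#' @param config [pipeline_config()].
#' @param min_fraction report only hits with matched fraction at or above
#'   this value (default 0.5; the two-step filter applies the published
#'   thresholds later).
#' @return hit table: `spacer_id`, `subject_id`, `s_start`, `s_end` (0-based
#'   half-open, plus strand), `strand`, `n_ident`, `q_len`,
#'   `matched_fraction`.
#' @export
find_hits <- function(records, subjects, config = pipeline_config(),
                      min_fraction = 0.5) {
  k <- config$seed_word
  empty <- data.frame(spacer_id = character(), subject_id = character(),
                      s_start = integer(), s_end = integer(),
                      strand = character(), n_ident = integer(),
                      q_len = integer(), matched_fraction = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(records) == 0L || nrow(subjects) == 0L) return(empty)
  idx <- build_kmer_index(subjects, k)
  if (nrow(idx) == 0L) return(empty)

  # query k-mer table over all spacers and both strands
  qpieces <- list()
  qseqs <- list()
  for (ri in seq_len(nrow(records))) {
    sp <- records$sequence[ri]
    L <- nchar(sp)
    if (L < k) next
    for (strand in c("+", "-")) {
      q <- if (strand == "+") sp else revcomp(sp)
      key <- paste0(ri, strand)
      qseqs[[key]] <- q
      qpieces[[key]] <- data.table::data.table(
        kmer = substring(q, 1:(L - k + 1), k:L),
        rid = ri, strand = strand, qpos = 1:(L - k + 1))
    }
  }
  if (!length(qpieces)) return(empty)
  qk <- data.table::rbindlist(qpieces)
  cand <- idx[qk, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(cand) == 0L) return(empty)
  cand[, d := pos - qpos]
  cand <- unique(cand[, c("rid", "strand", "sidx", "d")])

  # vectorised ungapped extension along every seed diagonal
  key <- paste0(cand$rid, cand$strand)
  qvec <- unlist(qseqs)[key]
  L <- nchar(qvec)
  subj_seq <- subjects$sequence[cand$sidx]
  subj_len <- nchar(subj_seq)
  s_start <- pmax(0L, cand$d)
  s_end <- pmin(subj_len, cand$d + L)
  n_ident <- integer(nrow(cand))
  full <- s_start == cand$d & s_end == cand$d + L
  for (Lg in unique(L[full])) {
    sel <- which(full & L == Lg)
    W <- code_seq_matrix(substr(subj_seq[sel], cand$d[sel] + 1L,
                                cand$d[sel] + Lg), Lg)
    Q <- code_seq_matrix(qvec[sel], Lg)
    n_ident[sel] <- rowSums(Q > 0L & Q == W)
  }
  for (ci in which(!full)) {
    n_ident[ci] <- diagonal_identities(strsplit(qvec[ci], "")[[1]],
                                       subj_seq[ci], cand$d[ci])
  }
  # banded gapped refinement where the ungapped diagonal may hide an indel;
  # batched by (query, window) length for the vectorised DP
  frac <- n_ident / L
  band <- 3L
  ref_idx <- which(frac < 1 & frac >= 0.55 & frac <= 0.92)
  if (length(ref_idx)) {
    lo <- pmax(0L, cand$d[ref_idx] - band)
    hi <- pmin(subj_len[ref_idx], cand$d[ref_idx] + L[ref_idx] + band)
    valid <- hi - lo >= L[ref_idx] - band
    ref_idx <- ref_idx[valid]; lo <- lo[valid]; hi <- hi[valid]
    if (length(ref_idx)) {
      win <- substr(subj_seq[ref_idx], lo + 1L, hi)
      grp <- paste(L[ref_idx], nchar(win))
      for (g in unique(grp)) {
        sel <- grp == g
        r <- glocal_align_group(qvec[ref_idx[sel]], win[sel])
        better <- r$n_ident > n_ident[ref_idx[sel]]
        upd <- ref_idx[sel][better]
        n_ident[upd] <- r$n_ident[better]
        s_start[upd] <- lo[sel][better] + r$s_start[better]
        s_end[upd] <- lo[sel][better] + r$s_end[better]
      }
    }
  }
  keep <- n_ident / L >= min_fraction
  if (!any(keep)) return(empty)
  res <- data.frame(
    spacer_id = records$spacer_id[cand$rid[keep]],
    subject_id = subjects$subject_id[cand$sidx[keep]],
    s_start = as.integer(s_start[keep]), s_end = as.integer(s_end[keep]),
    strand = cand$strand[keep],
    n_ident = as.integer(n_ident[keep]), q_len = as.integer(L[keep]),
    matched_fraction = n_ident[keep] / L[keep],
    stringsAsFactors = FALSE)
  res <- unique(res)
  pieces <- split(res, res$spacer_id)
  res <- do.call(rbind, lapply(pieces, collapse_overlapping_hits))
  res <- res[order(res$spacer_id, res$subject_id, res$s_start, res$strand), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# collapse hits of one spacer overlapping >=50% (relative to the shorter
# interval) with a better hit on the same subject
collapse_overlapping_hits <- function(h) {
  if (nrow(h) <= 1L) return(h)
  keep <- logical(nrow(h))
  ord <- order(-h$matched_fraction, h$subject_id, h$s_start, h$strand)
  for (i in ord) {
    ov <- FALSE
    for (j in which(keep)) {
      if (h$subject_id[i] != h$subject_id[j]) next
      inter <- min(h$s_end[i], h$s_end[j]) - max(h$s_start[i], h$s_start[j])
      shorter <- min(h$s_end[i] - h$s_start[i], h$s_end[j] - h$s_start[j])
      if (inter > 0 && inter / shorter >= 0.5) { ov <- TRUE; break }
    }
    keep[i] <- !ov
  }
  h[sort(which(keep)), , drop = FALSE]
}

#' Extract protospacer flanks
#'
#' Adds `upstream_flank` and `downstream_flank` columns (`config$flank_len`
#' nt each) to a hit table. Flanks are reported 5'->3' on the strand whose
#' sequence matches the spacer as stored: for minus-strand hits the flanks
#' are taken from the reverse complement of the subject, so "upstream" is
#' always the side 5' of the protospacer as the spacer reads. Positions
#' beyond the contig edge are padded with N.
#'
#' @param hits hit table ([find_hits()] or [read_hit_table()]).
#' @param subjects subject table.
#' @param config [pipeline_config()].
#' @return `hits` with `upstream_flank` and `downstream_flank` columns.
#' @export
extract_flanks <- function(hits, subjects, config = pipeline_config()) {
  fl <- config$flank_len
  m <- match(hits$subject_id, subjects$subject_id)
  if (anyNA(m)) {
    stop("unknown subject_id: ", hits$subject_id[which(is.na(m))[1]])
  }
  subj <- subjects$sequence[m]
  n <- nchar(subj)
  left <- substr(subj, pmax(1L, hits$s_start - fl + 1L), hits$s_start)
  left <- paste0(strrep("N", pmax(0L, fl - nchar(left))), left)
  right <- substr(subj, hits$s_end + 1L, pmin(n, hits$s_end + fl))
  right <- paste0(right, strrep("N", pmax(0L, fl - nchar(right))))
  minus <- hits$strand == "-"
  up <- left; dn <- right
  if (any(minus)) {
    up[minus] <- revcomp(right[minus])
    dn[minus] <- revcomp(left[minus])
  }
  hits$upstream_flank <- up
  hits$downstream_flank <- dn
  hits
}

#' Flag hits that fall inside CRISPR arrays
#'
#' A hit is an array hit when an ends-free alignment (match +1, mismatch 0,
#' 3 per gapped position; leading/trailing gaps free) of the spacer's
#' repeat -- in either orientation -- against either extracted flank has
#' strictly more than `config$array_identity_min` (default 13) identical
#' positions: inside an array, a flank is a repeat fragment and aligns
#' nearly end to end, while random flanks rarely reach the threshold.
#'
#' @param hits hit table with flanks ([extract_flanks()]).
#' @param records spacer record table supplying each spacer's repeat.
#' @param config [pipeline_config()].
#' @return `hits` with a logical `in_array` column.
#' @export
flag_array_hits <- function(hits, records, config = pipeline_config()) {
  rep_of <- stats::setNames(records$repeat_seq, records$spacer_id)
  reps <- rep_of[hits$spacer_id]
  if (anyNA(reps)) {
    stop("hits reference spacer_ids absent from the spacer table: ",
         paste(utils::head(unique(hits$spacer_id[is.na(reps)])),
               collapse = ", "))
  }
  if (!nrow(hits)) {
    hits$in_array <- logical(0)
    return(hits)
  }
  flanks <- c(hits$upstream_flank, hits$downstream_flank)
  reps2 <- c(reps, reps)
  best <- pmax(ends_free_identities(flanks, reps2)$n_ident,
               ends_free_identities(flanks, revcomp(reps2))$n_ident)
  m <- matrix(best > config$array_identity_min, ncol = 2)
  hits$in_array <- m[, 1] | m[, 2]
  hits
}

#' Array-hit test for a single hit
#'
#' Scalar wrapper around the rule of [flag_array_hits()].
#'
#' @param upstream_flank,downstream_flank extracted flanks.
#' @param repeat_seq the spacer's repeat.
#' @param config [pipeline_config()].
#' @return `TRUE` when either flank aligns to the repeat (either
#'   orientation) with more than `config$array_identity_min` identities.
#' @export
is_array_hit <- function(upstream_flank, downstream_flank, repeat_seq,
                         config = pipeline_config()) {
  flanks <- c(upstream_flank, downstream_flank)
  best <- pmax(ends_free_identities(flanks, repeat_seq)$n_ident,
               ends_free_identities(flanks, revcomp(repeat_seq))$n_ident)
  any(best > config$array_identity_min)
}
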