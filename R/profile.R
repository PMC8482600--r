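# Flank profiles: per-spacer consensus flanks are accumulated into
# per-cluster position x base count matrices, and position-wise information
# content is computed as relative entropy against a background derived from
# the cluster's mean spacer GC content.

BASES <- c("A", "C", "G", "T")

# plurality base per position over a set of equal-length flanks;
# N observations excluded, ties -> N
consensus_string <- function(flanks) {
  flanks <- flanks[nchar(flanks) > 0]
  stopifnot(length(flanks) > 0)
  L <- unique(nchar(flanks))
  stopifnot(length(L) == 1L)
  m <- do.call(rbind, strsplit(flanks, ""))
  out <- vapply(seq_len(L), function(j) {
    col <- m[, j]
    col <- col[col %in% BASES]
    if (!length(col)) return("N")
    tab <- table(col)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) top else "N"
  }, "")
  paste(out, collapse = "")
}

#' Consensus flanks of one spacer over its kept hits
#'
#' Per position, the plurality base across the spacer's hits; N observations
#' are excluded and ties yield N. Each spacer thus contributes one flank
#' observation to its cluster's profile regardless of how many database hits
#' it has.
#'
#' @param upstream_flanks,downstream_flanks character vectors of equal-length
#'   flanks from the hits of a single spacer.
#' @return list with `upstream` and `downstream` consensus strings.
#' @export
consensus_flanks <- function(upstream_flanks, downstream_flanks) {
  list(upstream = consensus_string(upstream_flanks),
       downstream = consensus_string(downstream_flanks))
}

#' Per-spacer consensus flank pairs for every cluster
#'
#' @param hits kept hit table with flanks.
#' @param membership `spacer_id` -> `cluster_id` mapping
#'   ([cluster_repeats()]`$membership`).
#' @return data.frame `cluster_id`, `spacer_id`, `upstream`, `downstream`.
#' @export
cluster_consensus_pairs <- function(hits, membership) {
  cl_of <- stats::setNames(membership$cluster_id, membership$spacer_id)
  sp <- unique(hits$spacer_id)
  rows <- lapply(sp, function(s) {
    sel <- hits$spacer_id == s
    cf <- consensus_flanks(hits$upstream_flank[sel], hits$downstream_flank[sel])
    data.frame(cluster_id = cl_of[[s]] %||% NA_character_, spacer_id = s,
               upstream = cf$upstream, downstream = cf$downstream,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[!is.na(out$cluster_id), , drop = FALSE]
}

gc_background <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

count_matrix <- function(flanks, L) {
  m <- matrix(0L, nrow = 4, ncol = L, dimnames = list(BASES, NULL))
  if (length(flanks)) {
    ch <- do.call(rbind, strsplit(flanks, ""))
    for (b in BASES) m[b, ] <- colSums(ch == b)
  }
  m
}

#' Position-wise information content of a count matrix
#'
#' Relative entropy of the observed base frequencies against the background:
#' `ic_j = sum_b f_bj * log2(f_bj / p_b)` with `0 * log 0 == 0`. Frequencies
#' are over non-N observations; positions with no observations score 0.
#'
#' @param counts 4 x L count matrix (rows A, C, G, T).
#' @param background named base probability vector (see `gc_background`);
#'   default uniform.
#' @return numeric vector of length L, in bits.
#' @export
information_content <- function(counts,
                                background = c(A = .25, C = .25,
                                               G = .25, T = .25)) {
  stopifnot(all(rownames(counts) == BASES), all(background > 0))
  tot <- colSums(counts)
  ic <- numeric(ncol(counts))
  nz <- tot > 0
  if (any(nz)) {
    f <- sweep(counts[, nz, drop = FALSE], 2, tot[nz], "/")
    term <- f * log2(sweep(f, 1, background[BASES], "/"))
    term[f == 0] <- 0
    ic[nz] <- colSums(term)
  }
  ic
}

#' Build the flank profiles of a repeat cluster
#'
#' Accumulates one observation per spacer per position from the per-spacer
#' consensus flank pairs. Identical (upstream, downstream) pairs within the
#' cluster are collapsed to a single unique protospacer before counting, so
#' redundant database records of one protospacer are not over-weighted.
#' The background is derived from the cluster's mean spacer GC:
#' `p_A = p_T = (1-GC)/2`, `p_C = p_G = GC/2`. The median information
#' content pools the positions of both flanks.
#'
#' @param pairs data.frame with `upstream`, `downstream` consensus flanks
#'   (one row per spacer of the cluster).
#' @param gc cluster mean spacer GC content in (0, 1).
#' @param cluster_id label carried through to the result.
#' @return object of class `flank_profiles`: list with `upstream` and
#'   `downstream` (each `counts`, `ic`, `positions`), `background`,
#'   `median_ic`, `n_protospacers`, `cluster_id`.
#' @export
build_profile <- function(pairs, gc, cluster_id = NA_character_) {
  pairs <- unique(pairs[, c("upstream", "downstream"), drop = FALSE])
  n <- nrow(pairs)
  stopifnot(n >= 1L)
  Lu <- nchar(pairs$upstream[1])
  Ld <- nchar(pairs$downstream[1])
  bg <- gc_background(gc)
  up_counts <- count_matrix(pairs$upstream, Lu)
  dn_counts <- count_matrix(pairs$downstream, Ld)
  up_ic <- information_content(up_counts, bg)
  dn_ic <- information_content(dn_counts, bg)
  structure(list(
    cluster_id = cluster_id,
    upstream = list(counts = up_counts, ic = up_ic,
                    positions = seq(-Lu, -1L)),
    downstream = list(counts = dn_counts, ic = dn_ic,
                      positions = seq(1L, Ld)),
    background = bg,
    median_ic = stats::median(c(up_ic, dn_ic)),
    n_protospacers = n
  ), class = "flank_profiles")
}

#' @export
print.flank_profiles <- function(x, ...) {
  cat(sprintf("flank profiles for cluster %s: %d unique protospacers, GC %.2f\n",
              x$cluster_id, x$n_protospacers, 2 * x$background[["C"]]))
  cat(sprintf("  median IC %.4f bits; max upstream %.3f, max downstream %.3f\n",
              x$median_ic, max(x$upstream$ic), max(x$downstream$ic)))
  invisible(x)
}

# flip consensus pairs to the opposite array orientation:
# (up, dn) -> (revcomp(dn), revcomp(up))
flip_consensus_pairs <- function(pairs) {
  data.frame(upstream = revcomp(pairs$downstream),
             downstream = revcomp(pairs$upstream),
             stringsAsFactors = FALSE)
}
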