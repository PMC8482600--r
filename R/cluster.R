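#' Cluster CRISPR repeats by identity
#'
#' Greedy incremental clustering of the repeat sequences of a spacer table:
#' unique repeats are sorted by descending abundance then lexicographically,
#' and each repeat joins the first existing cluster whose representative has
#' the same length and a global identity at or above
#' `config$repeat_cluster_identity` (default 0.90); otherwise it founds a new
#' cluster. The canonical ordering makes the partition deterministic and
#' independent of input row order.
#'
#' Repeats are clustered in their stored orientation; orientation correction
#' happens downstream during orientation prediction, not here.
#'
#' @param records spacer record table ([read_spacer_table()]).
#' @param config [pipeline_config()].
#' @param references optional subtype reference repeats
#'   ([read_subtype_references()]); when supplied, each cluster's subtype is
#'   assigned from its representative via [assign_subtype()], otherwise the
#'   modal non-unassigned subtype among member records is used.
#' @return list of class `repeat_clustering` with
#'   \describe{
#'     \item{clusters}{data.frame: `cluster_id`, `representative`, `subtype`,
#'       `n_members` (spacers), `mean_spacer_gc`.}
#'     \item{membership}{data.frame: `spacer_id`, `cluster_id`.}
#'   }
#' @export
cluster_repeats <- function(records, config = pipeline_config(),
                            references = NULL) {
  reps <- records$repeat_seq
  tab <- table(reps)
  uniq <- names(tab)[order(-as.integer(tab), names(tab))]

  cluster_rep <- character(0)
  rep_chars <- list()   # coded char vectors of representatives
  assignment <- integer(length(uniq))
  thr <- config$repeat_cluster_identity
  for (i in seq_along(uniq)) {
    r <- uniq[i]
    rc <- match(strsplit(r, "")[[1]], c("A", "C", "G", "T"), nomatch = 0L)
    Lr <- length(rc)
    placed <- 0L
    same_len <- which(nchar(cluster_rep) == Lr)
    if (length(same_len)) {
      # ungapped identity screens the gapped alignment: for equal lengths
      # the optimal-alignment identity fraction is never below the ungapped
      # fraction, and gaps (3 per position) can lift it by < 0.25
      m0 <- vapply(same_len, function(k) {
        sum(rc > 0L & rc == rep_chars[[k]])
      }, integer(1)) / Lr
      for (ki in seq_along(same_len)) {
        if (m0[ki] >= thr) {
          placed <- same_len[ki]
        } else if (m0[ki] >= thr - 0.25 &&
                   global_identity(r, cluster_rep[same_len[ki]]) >= thr) {
          placed <- same_len[ki]
        }
        if (placed > 0L) break
      }
    }
    if (placed == 0L) {
      cluster_rep <- c(cluster_rep, r)
      rep_chars[[length(cluster_rep)]] <- rc
      placed <- length(cluster_rep)
    }
    assignment[i] <- placed
  }

  rep_to_cluster <- stats::setNames(assignment, uniq)
  member_cluster <- rep_to_cluster[reps]
  cluster_id <- sprintf("RC%03d", seq_along(cluster_rep))

  subtype <- character(length(cluster_rep))
  mean_gc <- numeric(length(cluster_rep))
  n_members <- integer(length(cluster_rep))
  for (k in seq_along(cluster_rep)) {
    idx <- which(member_cluster == k)
    n_members[k] <- length(idx)
    mean_gc[k] <- mean(gc_content(records$sequence[idx]))
    if (!is.null(references)) {
      subtype[k] <- assign_subtype(cluster_rep[k], references, config)
    } else {
      st <- records$subtype[idx]
      st <- st[!is.na(st) & st != "unassigned" & st != ""]
      subtype[k] <- if (length(st)) names(sort(table(st), decreasing = TRUE))[1]
                    else "unassigned"
    }
  }

  structure(list(
    clusters = data.frame(cluster_id = cluster_id,
                          representative = cluster_rep,
                          subtype = subtype,
                          n_members = n_members,
                          mean_spacer_gc = mean_gc,
                          stringsAsFactors = FALSE),
    membership = data.frame(spacer_id = records$spacer_id,
                            cluster_id = cluster_id[member_cluster],
                            stringsAsFactors = FALSE)
  ), class = "repeat_clustering")
}

#' @export
print.repeat_clustering <- function(x, ...) {
  cat(sprintf("repeat clustering: %d clusters over %d spacers\n",
              nrow(x$clusters), nrow(x$membership)))
  print(utils::head(x$clusters, 10))
  invisible(x)
}

#' Assign a CRISPR-Cas subtype to a repeat from reference repeats
#'
#' The repeat is compared to every reference in both orientations; the label
#' of the best-identity reference is returned when that identity reaches
#' `config$subtype_identity` (default 0.74), otherwise `"unassigned"`.
#' Ties are broken by higher identity, then lexicographic subtype label.
#'
#' @param repeat_seq repeat sequence (stored orientation).
#' @param references data.frame with `repeat_seq`, `subtype`.
#' @param config [pipeline_config()].
#' @return subtype label, or `"unassigned"`.
#' @export
assign_subtype <- function(repeat_seq, references, config = pipeline_config()) {
  stopifnot(nrow(references) > 0)
  nref <- nrow(references)
  ident <- pmax(
    global_identity(rep(repeat_seq, nref), references$repeat_seq),
    global_identity(rep(revcomp(repeat_seq), nref), references$repeat_seq))
  ord <- order(-ident, references$subtype)
  best <- ord[1]
  if (ident[best] >= config$subtype_identity) references$subtype[best]
  else "unassigned"
}

#' Write a repeat clustering to CSV
#'
#' @param clustering a `repeat_clustering` object.
#' @param path output CSV path (`cluster_id`, `representative`, `subtype`,
#'   `n_members`, `mean_spacer_gc`).
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clustering, path) {
  utils::write.csv(clustering$clusters, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
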