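#' Run the full spacer-target analysis pipeline
#'
#' Chains every stage: hit finding (or ingestion), flank extraction,
#' array-hit removal, the two-step matched-fraction filter, repeat
#' clustering and subtype assignment, per-cluster flank profiles with
#' GC-corrected information content, orientation prediction, PAM calling
#' (profiles of reverse-oriented clusters are flipped and rebuilt), strand
#' classification against ORF annotations, and grouped strand-bias tests.
#'
#' @param records spacer record table.
#' @param subjects subject table.
#' @param config [pipeline_config()].
#' @param hits optional pre-computed hit table ([read_hit_table()]); when
#'   `NULL` the internal matcher runs.
#' @param orfs optional ORF table (GFF-derived); when `NULL` every primary
#'   target subject is scanned with [find_orfs()].
#' @param references optional subtype reference repeats.
#' @param group_by grouping of the strand-bias summary.
#' @return list of class `spacerscope_run`: `hits` (raw, flagged), `kept`
#'   (filtered hits), `clustering`, `profiles` (per cluster, oriented),
#'   `orientations` (data.frame), `pam_catalog`, `strand_calls`,
#'   `strand_bias`, `config`.
#' @export
run_pipeline <- function(records, subjects, config = pipeline_config(),
                         hits = NULL, orfs = NULL, references = NULL,
                         group_by = "subtype") {
  if (is.null(hits)) hits <- find_hits(records, subjects, config)
  hits <- extract_flanks(hits, subjects, config)
  hits <- flag_array_hits(hits, records, config)
  kept <- apply_two_step_filter(hits, records, config)

  clustering <- cluster_repeats(records, config, references)
  pairs <- cluster_consensus_pairs(kept, clustering$membership)

  cl <- clustering$clusters
  profiles <- list()
  ori_rows <- list()
  pam_rows <- list()
  oriented_repeat <- stats::setNames(cl$representative, cl$cluster_id)
  for (i in seq_len(nrow(cl))) {
    cid <- cl$cluster_id[i]
    pr <- pairs[pairs$cluster_id == cid, , drop = FALSE]
    if (!nrow(pr)) {
      ori_rows[[cid]] <- data.frame(
        cluster_id = cid, orientation = "undetermined", source = "pam_based",
        n_protospacers = 0L, stringsAsFactors = FALSE)
      next
    }
    prof <- build_profile(pr, cl$mean_spacer_gc[i], cid)
    ocall <- predict_orientation(prof, cl$subtype[i], config)
    if (identical(ocall$orientation, "reverse")) {
      prof <- build_profile(flip_consensus_pairs(pr), cl$mean_spacer_gc[i], cid)
      oriented_repeat[[cid]] <- revcomp(cl$representative[i])
    }
    profiles[[cid]] <- prof
    ori_rows[[cid]] <- data.frame(
      cluster_id = cid, orientation = ocall$orientation, source = ocall$source,
      n_protospacers = prof$n_protospacers, stringsAsFactors = FALSE)
    pcall <- call_pam(prof, cl$subtype[i], config)
    pam_rows[[cid]] <- data.frame(
      cluster_id = cid, representative = oriented_repeat[[cid]],
      subtype = cl$subtype[i],
      PAM = if (is.null(pcall)) NA_character_ else pcall$motif,
      side = if (is.null(pcall)) NA_character_ else pcall$side,
      n_protospacers = prof$n_protospacers, stringsAsFactors = FALSE)
  }
  orientations <- do.call(rbind, ori_rows)
  rownames(orientations) <- NULL
  pam_catalog <- if (length(pam_rows)) do.call(rbind, pam_rows) else
    data.frame(cluster_id = character(), representative = character(),
               subtype = character(), PAM = character(), side = character(),
               n_protospacers = integer(), stringsAsFactors = FALSE)
  rownames(pam_catalog) <- NULL

  if (is.null(orfs)) {
    targets <- unique(kept$subject_id)
    orfs <- do.call(rbind, lapply(targets, function(sj) {
      find_orfs(sj, subjects$sequence[match(sj, subjects$subject_id)])
    }))
    if (is.null(orfs)) {
      orfs <- data.frame(subject_id = character(), start = integer(),
                         end = integer(), strand = character(),
                         stringsAsFactors = FALSE)
    }
  }
  ori_vec <- stats::setNames(orientations$orientation,
                             orientations$cluster_id)
  calls <- if (nrow(kept)) {
    strand_calls(kept, subjects, orfs, clustering$membership, ori_vec)
  } else {
    data.frame(spacer_id = character(), subject_id = character(),
               call = character(), stringsAsFactors = FALSE)
  }
  bias <- group_strand_bias(calls, records, group_by, alpha = config$alpha)

  structure(list(hits = hits, kept = kept, clustering = clustering,
                 pairs = pairs, profiles = profiles,
                 orientations = orientations, pam_catalog = pam_catalog,
                 strand_calls = calls, strand_bias = bias, config = config),
            class = "spacerscope_run")
}

#' @export
print.spacerscope_run <- function(x, ...) {
  cat(sprintf(paste0(
    "spacerscope run [config %s]\n",
    "  %d raw hits -> %d kept (%d step1, %d step2)\n",
    "  %d repeat clusters; %d orientation calls determined; %d PAM calls\n"),
    config_hash(x$config), nrow(x$hits), nrow(x$kept),
    sum(x$kept$kept_step == "step1"), sum(x$kept$kept_step == "step2"),
    nrow(x$clustering$clusters),
    sum(x$orientations$orientation %in% c("forward", "reverse") &
          x$orientations$source == "pam_based"),
    sum(!is.na(x$pam_catalog$PAM))))
  invisible(x)
}

#' Write the PAM catalog
#'
#' CSV with the standard export column order `repeat,PAM,subtype` (clusters
#' without a PAM call are omitted); extra columns follow.
#'
#' @param pam_catalog the `pam_catalog` element of a [run_pipeline()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pam_catalog <- function(pam_catalog, path) {
  keep <- !is.na(pam_catalog$PAM)
  out <- data.frame("repeat" = pam_catalog$representative[keep],
                    PAM = pam_catalog$PAM[keep],
                    subtype = pam_catalog$subtype[keep],
                    cluster_id = pam_catalog$cluster_id[keep],
                    side = pam_catalog$side[keep],
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-spacer annotations
#'
#' One row per spacer mirroring the standard per-spacer export schema: spacer,
#' repeat, accession, subtype, hit (0/1), repeat_cluster,
#' orientation_PAMbased (1 forward, 0 reverse, -1 undetermined),
#' strand_call (1 coding, 0 template, -1 undetermined), PAM, and a reason
#' column for undetermined strand calls.
#'
#' @param run a [run_pipeline()] result.
#' @param records the spacer record table the run was built from.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spacer_annotations <- function(run, records, path) {
  m <- match(records$spacer_id, run$clustering$membership$spacer_id)
  cluster <- run$clustering$membership$cluster_id[m]
  ori <- run$orientations$orientation[
    match(cluster, run$orientations$cluster_id)]
  pam <- run$pam_catalog$PAM[match(cluster, run$pam_catalog$cluster_id)]
  sc <- run$strand_calls$call[match(records$spacer_id,
                                    run$strand_calls$spacer_id)]
  has_hit <- records$spacer_id %in% run$kept$spacer_id
  code_ori <- ifelse(is.na(ori) | ori == "undetermined", -1L,
                     ifelse(ori == "forward", 1L, 0L))
  code_sc <- ifelse(is.na(sc) | sc == "undetermined", -1L,
                    ifelse(sc == "coding", 1L, 0L))
  reason <- ifelse(!has_hit, "no_kept_hit",
            ifelse(is.na(sc), "no_primary_target",
            ifelse(sc == "undetermined", "outside_single_orf_or_unoriented",
                   "")))
  out <- data.frame(
    spacer = records$sequence,
    "repeat" = records$repeat_seq,
    accession = records$host_accession,
    subtype = records$subtype,
    hit = as.integer(has_hit),
    repeat_cluster = cluster,
    orientation_PAMbased = code_ori,
    strand_call = code_sc,
    PAM = ifelse(is.na(pam), "", pam),
    undetermined_reason = reason,
    spacer_id = records$spacer_id,
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the compatibility table
#'
#' CSV with the deposited columns `accession,subtypes,PAM,category`.
#'
#' @param compat a [categorize_cohort()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_compatibility_table <- function(compat, path) {
  utils::write.csv(compat[, c("accession", "subtypes", "PAM", "category")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
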