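# Synthetic universe generator. Emits a fully labelled cohort -- spacer
# table, target contigs with ORFs, planted PAMs and orientations, genus
# structure, decoy spacers and array-embedded self hits -- plus a
# machine-readable truth bundle, so every pipeline stage can be scored
# against planted ground truth.

# default PAM per subtype: motif and side relative to the transcribed spacer
DEFAULT_PAMS <- list(
  "I-E" = list(motif = "AAG", side = "upstream"),
  "I-B" = list(motif = "TTC", side = "upstream"),
  "I-C" = list(motif = "TTC", side = "upstream"),
  "II-A" = list(motif = "GGT", side = "downstream"),
  "III-B" = NULL  # type III: no PAM requirement
)

#' Parameters of the synthetic universe
#'
#' Defaults describe a cohort of 20 repeat clusters of 30 spacers each:
#' 29-nt repeats (type I/III repeats end in the crRNA-handle motif
#' ATTGAAAC), 32-nt spacers, subtype-specific 3-nt PAMs planted at 90%
#' adherence, one quarter of clusters stored in reverse orientation,
#' targets at GC 0.5 with a 2% per-base substitution rate and 1-3 hits per
#' spacer, subtype-specific coding-strand fractions mirroring reported
#' biases (III-B 0.65, I-B 0.55, II-A 0.50, I-E 0.43), 20 decoy spacers
#' around the filter boundary and 10 array-embedded self hits.
#'
#' @param n_clusters number of repeat clusters.
#' @param spacers_per_cluster spacers per cluster.
#' @param repeat_len,spacer_len sequence lengths (nt).
#' @param subtypes subtype labels recycled over clusters.
#' @param pams named list `subtype -> list(motif, side)` or `NULL` for no
#'   PAM.
#' @param pam_adherence probability a planted protospacer carries the PAM.
#' @param reverse_fraction fraction of PAM-bearing clusters stored
#'   reverse-complemented.
#' @param target_gc GC content of target contigs and spacers.
#' @param substitution_rate per-base substitution probability per
#'   protospacer copy.
#' @param hits_per_spacer integer range (min, max) of placements per spacer.
#' @param coding_fraction named per-subtype probability that a placement
#'   targets the coding strand.
#' @param orf_density approximate fraction of each contig covered by its
#'   ORF.
#' @param orf_len ORF length in nt (multiple of 3).
#' @param n_decoy_spacers decoy spacers with targets around the
#'   matched-fraction filter boundary.
#' @param n_step2_pairs contigs carrying an exact hit of one spacer plus a
#'   weak (0.875-fraction) hit of a same-genus spacer, exercising the
#'   second filter step.
#' @param n_array_embedded_hits self hits planted inside synthetic arrays.
#' @param redundancy_rate per-base substitution rate between redundant
#'   database copies of one protospacer context (extra hits of a spacer are
#'   near-copies of its first context, as in redundant sequence databases).
#' @param genera genus labels recycled over clusters.
#' @param rng_seed integer seed; fixed seed gives byte-identical output.
#' @return validated list of class `generator_params`.
#' @export
generator_params <- function(n_clusters = 20L,
                             spacers_per_cluster = 30L,
                             repeat_len = 29L,
                             spacer_len = 32L,
                             subtypes = c("I-E", "I-B", "II-A", "III-B"),
                             pams = DEFAULT_PAMS,
                             pam_adherence = 0.9,
                             reverse_fraction = 0.25,
                             target_gc = 0.5,
                             substitution_rate = 0.02,
                             hits_per_spacer = c(1L, 3L),
                             coding_fraction = c("I-E" = 0.43, "I-B" = 0.55,
                                                 "II-A" = 0.50, "III-B" = 0.65),
                             orf_density = 0.6,
                             orf_len = 201L,
                             n_decoy_spacers = 20L,
                             n_step2_pairs = 15L,
                             n_array_embedded_hits = 10L,
                             redundancy_rate = 0.005,
                             genera = c("Escherichia", "Bacillus",
                                        "Streptococcus", "Moraxella",
                                        "Pseudomonas"),
                             rng_seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$pam_adherence >= 0, p$pam_adherence <= 1,
            p$reverse_fraction >= 0, p$reverse_fraction <= 1,
            p$target_gc > 0, p$target_gc < 1,
            p$substitution_rate >= 0, p$substitution_rate <= 1,
            all(p$coding_fraction >= 0), all(p$coding_fraction <= 1),
            p$orf_len %% 3 == 0, p$orf_len >= 90)
  if (p$orf_len < p$spacer_len + 18L) {
    stop("orf_len too short to contain a protospacer with margins",
         call. = FALSE)
  }
  class(p) <- "generator_params"
  p
}

mutate_seq <- function(seq, n_sub = NULL, rate = NULL) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  pos <- if (!is.null(n_sub)) {
    if (n_sub == 0) integer(0) else sample.int(n, min(n_sub, n))
  } else {
    which(stats::runif(n) < rate)
  }
  for (i in pos) ch[i] <- sample(setdiff(BASES, ch[i]), 1)
  paste(ch, collapse = "")
}

random_codons <- function(n_codons, gc) {
  out <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cod <- random_dna(1, 3, gc)
      if (!cod %in% c("TAA", "TAG", "TGA")) break
    }
    out[i] <- cod
  }
  paste(out, collapse = "")
}

# an ORF sequence in its own coding orientation
random_orf_seq <- function(orf_len, gc) {
  paste0("ATG", random_codons(orf_len / 3 - 2L, gc), "TAA")
}

# overwrite `insert` into `seq` at 0-based position `at`
splice_seq <- function(seq, insert, at) {
  paste0(substr(seq, 1, at), insert,
         substr(seq, at + nchar(insert) + 1L, nchar(seq)))
}

#' Plant a protospacer (with PAM) inside an ORF-bearing contig
#'
#' Builds one contig containing a single ORF and embeds a copy of the
#' spacer such that the spacer-identical strand is the ORF's template
#' strand when `strand_class` is `"coding"` (the crRNA can then base-pair
#' the mRNA) and the coding strand otherwise. When `pam` is non-NULL the
#' motif is written adjacent to the protospacer on the spacer-identical
#' strand at the planted side (when adherent).
#'
#' @param spacer spacer sequence in transcribed orientation.
#' @param pam `list(motif, side)` or `NULL`.
#' @param strand_class `"coding"` or `"template"`.
#' @param adherent logical; write the PAM motif or random bases.
#' @param params [generator_params()].
#' @return list with `contig` (sequence), `orf` (start, end, strand),
#'   `s_start`, `s_end`, `s_strand` (spacer-identical strand),
#'   `planted_copy` (the possibly mutated protospacer as planted).
#' @export
plant_protospacers <- function(spacer, pam, strand_class, adherent = TRUE,
                               params = generator_params()) {
  L <- nchar(spacer)
  gc <- params$target_gc
  orf_len <- params$orf_len
  pad <- max(30L, as.integer(round(orf_len * (1 - params$orf_density) /
                                     (2 * params$orf_density))))
  orf_strand <- sample(c("+", "-"), 1)
  s_strand <- if (strand_class == "coding") {
    if (orf_strand == "+") "-" else "+"
  } else {
    orf_strand
  }

  orf_seq <- random_orf_seq(orf_len, gc)
  # position of the protospacer inside the ORF (ORF's own orientation)
  off <- sample(seq(9L, orf_len - L - 9L), 1)
  copy <- mutate_seq(spacer, rate = params$substitution_rate)
  # sequence as it must appear on the ORF's own strand
  spacer_on_orf <- if (s_strand == orf_strand) copy else revcomp(copy)
  orf_seq <- splice_seq(orf_seq, spacer_on_orf, off)

  contig <- paste0(random_dna(1, pad, gc),
                   if (orf_strand == "+") orf_seq else revcomp(orf_seq),
                   random_dna(1, pad, gc))
  orf_start <- pad
  orf_end <- pad + orf_len
  # protospacer interval on the contig plus strand
  if (orf_strand == "+") {
    s_start <- pad + off
  } else {
    s_start <- pad + (orf_len - off - L)
  }
  s_end <- s_start + L

  if (!is.null(pam)) {
    k <- nchar(pam$motif)
    block <- if (adherent) pam$motif else random_dna(1, k, gc)
    # upstream = 5' of the protospacer on the spacer-identical strand
    if (s_strand == "+") {
      at <- if (pam$side == "upstream") s_start - k else s_end
      ins <- block
    } else {
      at <- if (pam$side == "upstream") s_end else s_start - k
      ins <- revcomp(block)
    }
    contig <- splice_seq(contig, ins, at)
  }

  list(contig = contig,
       orf = list(start = orf_start, end = orf_end, strand = orf_strand),
       s_start = s_start, s_end = s_end, s_strand = s_strand,
       planted_copy = copy)
}

#' Generate a synthetic spacer-target universe
#'
#' Deterministic for a fixed `params$rng_seed`. See [generator_params()]
#' for the cohort structure. Each genuine placement lives on its own contig
#' with one ORF; decoy spacers receive targets with matched fractions
#' around the 0.8-0.9 filter boundary; array-embedded contigs carry
#' repeat-spacer-repeat copies to exercise the array-hit test. The context
#' table places each cluster's array near a cas cluster of its subtype
#' (half of the type III cas clusters lack cas1-cas2).
#'
#' @param params [generator_params()].
#' @return list of class `synthetic_universe` with `records` (spacer
#'   table), `subjects`, `orfs`, `context`, `references` (subtype reference
#'   repeats) and `truth` (planted cluster/spacer/placement tables).
#' @export
generate_universe <- function(params = generator_params()) {
  set.seed(params$rng_seed)
  nc <- params$n_clusters
  subtypes <- rep_len(params$subtypes, nc)
  genera <- rep_len(params$genera, nc)
  has_pam <- !vapply(params$pams[subtypes], is.null, TRUE)
  orientation <- rep("forward", nc)
  rev_idx <- which(has_pam)
  n_rev <- round(params$reverse_fraction * length(rev_idx))
  if (n_rev > 0) orientation[sample(rev_idx, n_rev)] <- "reverse"

  records <- list(); subjects <- list(); orfs <- list()
  truth_clusters <- list(); truth_spacers <- list(); placements <- list()
  sidx <- 0L

  for (k in seq_len(nc)) {
    st <- subtypes[k]
    pam <- params$pams[[st]]
    handle <- major_type(st) %in% c("I", "III")
    rep_true <- if (handle) {
      paste0(random_dna(1, params$repeat_len - 8L, params$target_gc),
             "ATTGAAAC")
    } else {
      random_dna(1, params$repeat_len, params$target_gc)
    }
    acc <- sprintf("GEN%03d", k)
    cl_id <- sprintf("PC%03d", k)
    cfrac <- params$coding_fraction[[st]] %||% 0.5

    truth_clusters[[k]] <- data.frame(
      cluster_id = cl_id, subtype = st, repeat_true = rep_true,
      pam_motif = if (is.null(pam)) NA_character_ else pam$motif,
      pam_side = if (is.null(pam)) NA_character_ else pam$side,
      orientation = orientation[k], accession = acc, genus = genera[k],
      coding_fraction = cfrac, stringsAsFactors = FALSE)

    for (j in seq_len(params$spacers_per_cluster)) {
      sp_id <- sprintf("%s_s%02d", cl_id, j)
      sp_true <- random_dna(1, params$spacer_len, params$target_gc)
      rep_member <- mutate_seq(rep_true, n_sub = sample(0:1, 1))
      stored_sp <- sp_true; stored_rep <- rep_member
      if (orientation[k] == "reverse") {
        stored_sp <- revcomp(sp_true)
        stored_rep <- revcomp(rep_member)
      }
      n_hits <- sample(params$hits_per_spacer[1]:params$hits_per_spacer[2], 1)
      strand_class <- if (stats::runif(1) < cfrac) "coding" else "template"
      truth_spacers[[length(truth_spacers) + 1L]] <- data.frame(
        spacer_id = sp_id, cluster_id = cl_id, strand_class = strand_class,
        genus = genera[k], n_hits = n_hits, stringsAsFactors = FALSE)
      records[[length(records) + 1L]] <- data.frame(
        spacer_id = sp_id, sequence = stored_sp, repeat_seq = stored_rep,
        host_accession = acc, genus = genera[k],
        array_id = paste0(cl_id, "_arr"), position_in_array = j,
        subtype = st, cas_genes = st, stringsAsFactors = FALSE)
      # one protospacer context per spacer; extra hits are redundant
      # near-copies of it, as in overlapping sequence databases
      adherent <- stats::runif(1) < params$pam_adherence
      pl <- plant_protospacers(sp_true, pam, strand_class, adherent, params)
      for (h in seq_len(n_hits)) {
        sidx <- sidx + 1L
        sj_id <- sprintf("CTG%05d", sidx)
        contig <- if (h == 1L) pl$contig else
          mutate_seq(pl$contig, rate = params$redundancy_rate)
        subjects[[sidx]] <- data.frame(
          subject_id = sj_id, sequence = contig,
          source_class = "nucleotide_db", length = nchar(contig),
          stringsAsFactors = FALSE)
        orfs[[length(orfs) + 1L]] <- data.frame(
          subject_id = sj_id, start = pl$orf$start, end = pl$orf$end,
          strand = pl$orf$strand, stringsAsFactors = FALSE)
        placements[[length(placements) + 1L]] <- data.frame(
          spacer_id = sp_id, subject_id = sj_id, s_start = pl$s_start,
          s_end = pl$s_end, s_strand = pl$s_strand,
          strand_class = strand_class, pam_adherent = adherent,
          provenance = "genuine", stringsAsFactors = FALSE)
      }
    }
  }

  # decoy spacers: targets with matched fractions around the filter boundary
  decoy_genus <- rep_len(params$genera, params$n_decoy_spacers)
  for (d in seq_len(params$n_decoy_spacers)) {
    sp_id <- sprintf("DECOY_s%02d", d)
    sp <- random_dna(1, params$spacer_len, params$target_gc)
    records[[length(records) + 1L]] <- data.frame(
      spacer_id = sp_id, sequence = sp,
      repeat_seq = random_dna(1, params$repeat_len, params$target_gc),
      host_accession = sprintf("DGEN%03d", d), genus = decoy_genus[d],
      array_id = sprintf("DEC%02d_arr", d), position_in_array = 1L,
      subtype = "unassigned", cas_genes = "", stringsAsFactors = FALSE)
    sidx <- sidx + 1L
    sj_id <- sprintf("CTG%05d", sidx)
    n_sub <- sample(c(2L, 4L, 6L), 1)   # fractions 0.94, 0.875, 0.81 at 32 nt
    copy <- mutate_seq(sp, n_sub = n_sub)
    contig <- paste0(random_dna(1, 60, params$target_gc), copy,
                     random_dna(1, 60, params$target_gc))
    subjects[[sidx]] <- data.frame(
      subject_id = sj_id, sequence = contig, source_class = "nucleotide_db",
      length = nchar(contig), stringsAsFactors = FALSE)
    placements[[length(placements) + 1L]] <- data.frame(
      spacer_id = sp_id, subject_id = sj_id, s_start = 60L,
      s_end = 60L + params$spacer_len, s_strand = "+",
      strand_class = "undetermined", pam_adherent = FALSE,
      provenance = "decoy", stringsAsFactors = FALSE)
    truth_spacers[[length(truth_spacers) + 1L]] <- data.frame(
      spacer_id = sp_id, cluster_id = NA_character_,
      strand_class = "undetermined", genus = decoy_genus[d], n_hits = 1L,
      stringsAsFactors = FALSE)
  }

  # step-2 pairs: one contig with an exact hit of one spacer plus a weak
  # (4-substitution) hit of another spacer of the same genus/cluster
  rec_df <- do.call(rbind, records)
  cluster_ids <- sprintf("PC%03d", seq_len(nc))
  for (i in seq_len(params$n_step2_pairs)) {
    k <- ((i - 1L) %% nc) + 1L
    tsd <- do.call(rbind, truth_spacers)
    ids <- tsd$spacer_id[tsd$cluster_id %in% cluster_ids[k]]
    if (length(ids) < 2L) next
    pair <- sample(ids, 2L)
    seq_a <- rec_df$sequence[match(pair[1], rec_df$spacer_id)]
    seq_b <- rec_df$sequence[match(pair[2], rec_df$spacer_id)]
    if (orientation[k] == "reverse") {
      seq_a <- revcomp(seq_a); seq_b <- revcomp(seq_b)
    }
    copy_b <- mutate_seq(seq_b, n_sub = 4L)
    sidx <- sidx + 1L
    sj_id <- sprintf("CTG%05d", sidx)
    contig <- paste0(random_dna(1, 50, params$target_gc), seq_a,
                     random_dna(1, 30, params$target_gc), copy_b,
                     random_dna(1, 50, params$target_gc))
    subjects[[sidx]] <- data.frame(
      subject_id = sj_id, sequence = contig, source_class = "nucleotide_db",
      length = nchar(contig), stringsAsFactors = FALSE)
    La <- nchar(seq_a)
    placements[[length(placements) + 1L]] <- data.frame(
      spacer_id = pair[1], subject_id = sj_id, s_start = 50L,
      s_end = 50L + La, s_strand = "+", strand_class = "undetermined",
      pam_adherent = FALSE, provenance = "step2_pair_strong",
      stringsAsFactors = FALSE)
    placements[[length(placements) + 1L]] <- data.frame(
      spacer_id = pair[2], subject_id = sj_id, s_start = 80L + La,
      s_end = 80L + La + nchar(copy_b), s_strand = "+",
      strand_class = "undetermined", pam_adherent = FALSE,
      provenance = "step2_pair_weak", stringsAsFactors = FALSE)
  }

  # array-embedded self hits: repeat-spacer-repeat copies inside contigs
  genuine_ids <- rec_df$spacer_id[!grepl("^DECOY", rec_df$spacer_id)]
  emb <- sample(genuine_ids, min(params$n_array_embedded_hits,
                                 length(genuine_ids)))
  for (sp_id in emb) {
    r <- rec_df[rec_df$spacer_id == sp_id, ]
    sidx <- sidx + 1L
    sj_id <- sprintf("CTG%05d", sidx)
    contig <- paste0(random_dna(1, 80, params$target_gc),
                     r$repeat_seq, r$sequence, r$repeat_seq,
                     random_dna(1, 80, params$target_gc))
    subjects[[sidx]] <- data.frame(
      subject_id = sj_id, sequence = contig, source_class = "nucleotide_db",
      length = nchar(contig), stringsAsFactors = FALSE)
    placements[[length(placements) + 1L]] <- data.frame(
      spacer_id = sp_id, subject_id = sj_id,
      s_start = 80L + nchar(r$repeat_seq),
      s_end = 80L + nchar(r$repeat_seq) + nchar(r$sequence),
      s_strand = "+", strand_class = "undetermined", pam_adherent = FALSE,
      provenance = "array_embedded", stringsAsFactors = FALSE)
  }

  # context: per genome, the array and a cas cluster of its subtype nearby;
  # half of the type III cas clusters lack cas1-cas2
  tc <- do.call(rbind, truth_clusters)
  ctx <- list()
  third <- which(major_type(tc$subtype) == "III")
  lacks12 <- third[seq_along(third) %% 2 == 1]
  for (k in seq_len(nrow(tc))) {
    ctx[[length(ctx) + 1L]] <- data.frame(
      accession = tc$accession[k], kind = "array",
      start = 10000L, end = 12000L,
      array_id = paste0(tc$cluster_id[k], "_arr"),
      repeat_cluster_id = tc$cluster_id[k],
      subtype = NA_character_, has_cas1_cas2 = NA_integer_,
      stringsAsFactors = FALSE)
    ctx[[length(ctx) + 1L]] <- data.frame(
      accession = tc$accession[k], kind = "cas_cluster",
      start = 14000L, end = 20000L, array_id = NA_character_,
      repeat_cluster_id = NA_character_, subtype = tc$subtype[k],
      has_cas1_cas2 = if (k %in% lacks12) 0L else 1L,
      stringsAsFactors = FALSE)
  }

  # subtype reference repeats: the true cluster repeats, labelled
  refs <- unique(data.frame(repeat_seq = tc$repeat_true,
                            subtype = tc$subtype, stringsAsFactors = FALSE))

  structure(list(
    records = rec_df,
    subjects = do.call(rbind, subjects),
    orfs = do.call(rbind, orfs),
    context = do.call(rbind, ctx),
    references = refs,
    truth = list(clusters = tc,
                 spacers = do.call(rbind, truth_spacers),
                 placements = do.call(rbind, placements)),
    params = params
  ), class = "synthetic_universe")
}

#' @export
print.synthetic_universe <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic universe: %d spacers in %d clusters, %d subjects ",
    "(%d genuine, %d decoy, %d array-embedded placements)\n"),
    nrow(x$records), nrow(x$truth$clusters), nrow(x$subjects),
    sum(x$truth$placements$provenance == "genuine"),
    sum(x$truth$placements$provenance == "decoy"),
    sum(x$truth$placements$provenance == "array_embedded")))
  invisible(x)
}

#' Simulate the consensus flank pairs of one repeat cluster
#'
#' Direct generator for the orientation/PAM recovery experiments: flank
#' backgrounds are i.i.d. at the given GC and the motif is written at the
#' planted side's protospacer-proximal positions with the given adherence.
#' Uses the current RNG state (seed in the caller).
#'
#' @param n_protospacers number of unique protospacers.
#' @param pam `list(motif, side)` or `NULL` for a PAM-free cluster.
#' @param adherence per-protospacer probability of carrying the motif.
#' @param gc background GC content.
#' @param flank_len flank length (default 23).
#' @return data.frame with `upstream`, `downstream`.
#' @export
simulate_cluster_flanks <- function(n_protospacers, pam = NULL,
                                    adherence = 0.9, gc = 0.5,
                                    flank_len = 23L) {
  up <- random_dna(n_protospacers, flank_len, gc)
  dn <- random_dna(n_protospacers, flank_len, gc)
  if (!is.null(pam)) {
    k <- nchar(pam$motif)
    hit <- stats::runif(n_protospacers) < adherence
    if (pam$side == "upstream") {
      up[hit] <- paste0(substr(up[hit], 1, flank_len - k), pam$motif)
    } else {
      dn[hit] <- paste0(pam$motif, substr(dn[hit], k + 1, flank_len))
    }
  }
  data.frame(upstream = up, downstream = dn, stringsAsFactors = FALSE)
}

#' Generate a labelled compatibility cohort
#'
#' Builds context tables and a PAM catalog for genomes planted as category
#' 1 (two DNA-targeting subtypes, distinct repeat clusters, shared PAM),
#' category 2 (DNA- plus RNA-targeting, distinct repeat clusters, shared
#' PAM), category 3 (one repeat cluster linked to cas clusters of two
#' subtypes) and negatives (distinct PAMs, no shared linkage).
#'
#' @param n_per_class genomes per planted class.
#' @return list with `context`, `pam_catalog`, `truth` (accession ->
#'   planted category).
#' @export
generate_compatibility_cohort <- function(n_per_class = 5L) {
  ctx <- list(); pams <- list(); truth <- list()
  rcn <- 0L
  add_row <- function(acc, kind, start, end, array_id = NA, rc = NA,
                      subtype = NA, has12 = NA) {
    data.frame(accession = acc, kind = kind, start = start, end = end,
               array_id = as.character(array_id),
               repeat_cluster_id = as.character(rc),
               subtype = as.character(subtype),
               has_cas1_cas2 = as.integer(has12), stringsAsFactors = FALSE)
  }
  new_rc <- function() { rcn <<- rcn + 1L; sprintf("RCC%03d", rcn) }

  for (i in seq_len(n_per_class)) {
    # category 1: I-B and I-C arrays, distinct repeat clusters, shared PAM
    acc <- sprintf("CAT1_%02d", i)
    r1 <- new_rc(); r2 <- new_rc()
    ctx[[length(ctx) + 1L]] <- rbind(
      add_row(acc, "array", 10000, 12000, "a1", r1),
      add_row(acc, "cas_cluster", 13000, 18000, subtype = "I-B", has12 = 1),
      add_row(acc, "array", 200000, 202000, "a2", r2),
      add_row(acc, "cas_cluster", 203000, 208000, subtype = "I-C", has12 = 1))
    pams[[length(pams) + 1L]] <- data.frame(
      cluster_id = c(r1, r2), subtype = c("I-B", "I-C"),
      PAM = c("TTC", "TTC"), stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      accession = acc, category = "1", stringsAsFactors = FALSE)

    # category 2: I-B plus III-B, distinct repeat clusters, shared PAM
    acc <- sprintf("CAT2_%02d", i)
    r1 <- new_rc(); r2 <- new_rc()
    ctx[[length(ctx) + 1L]] <- rbind(
      add_row(acc, "array", 10000, 12000, "a1", r1),
      add_row(acc, "cas_cluster", 13000, 18000, subtype = "I-B", has12 = 1),
      add_row(acc, "array", 200000, 202000, "a2", r2),
      add_row(acc, "cas_cluster", 203000, 208000, subtype = "III-B",
              has12 = 0))
    pams[[length(pams) + 1L]] <- data.frame(
      cluster_id = c(r1, r2), subtype = c("I-B", "III-B"),
      PAM = c("TTC", "TTC"), stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      accession = acc, category = "2", stringsAsFactors = FALSE)

    # category 3: one repeat cluster within 25 kb of I-B and III-A cas
    # clusters, no other arrays
    acc <- sprintf("CAT3_%02d", i)
    r1 <- new_rc()
    ctx[[length(ctx) + 1L]] <- rbind(
      add_row(acc, "array", 50000, 52000, "a1", r1),
      add_row(acc, "cas_cluster", 30000, 42000, subtype = "I-B", has12 = 1),
      add_row(acc, "cas_cluster", 55000, 62000, subtype = "III-A",
              has12 = 0))
    pams[[length(pams) + 1L]] <- data.frame(
      cluster_id = r1, subtype = "I-B", PAM = "TTC", stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      accession = acc, category = "3", stringsAsFactors = FALSE)

    # negative: distinct PAMs, each array linked only to its own system
    acc <- sprintf("NEG_%02d", i)
    r1 <- new_rc(); r2 <- new_rc()
    ctx[[length(ctx) + 1L]] <- rbind(
      add_row(acc, "array", 10000, 12000, "a1", r1),
      add_row(acc, "cas_cluster", 13000, 18000, subtype = "I-E", has12 = 1),
      add_row(acc, "array", 200000, 202000, "a2", r2),
      add_row(acc, "cas_cluster", 203000, 208000, subtype = "I-F", has12 = 1))
    pams[[length(pams) + 1L]] <- data.frame(
      cluster_id = c(r1, r2), subtype = c("I-E", "I-F"),
      PAM = c("AAG", "CC"), stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      accession = acc, category = "none", stringsAsFactors = FALSE)
  }
  list(context = do.call(rbind, ctx),
       pam_catalog = do.call(rbind, pams),
       truth = do.call(rbind, truth))
}

#' Write / read the truth bundle of a synthetic universe
#'
#' Structured JSON with stable key order; reading a written bundle returns
#' the same tables.
#'
#' @param truth the `truth` element of a [generate_universe()] result.
#' @param path JSON path.
#' @return `write_truth_bundle()` returns `path` invisibly;
#'   `read_truth_bundle()` returns the truth list.
#' @export
write_truth_bundle <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", auto_unbox = FALSE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_truth_bundle
#' @export
read_truth_bundle <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(tab) as.data.frame(tab, stringsAsFactors = FALSE))
}

#' Write a synthetic universe to a directory
#'
#' Emits `spacers.csv`, `subjects.fasta`, `orfs.gff3`, `context.csv`,
#' `references.fasta` and `truth.json`.
#'
#' @param universe a [generate_universe()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_universe <- function(universe, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_spacer_table(universe$records, file.path(dir, "spacers.csv"))
  write_fasta(universe$subjects, file.path(dir, "subjects.fasta"))
  write_gff(universe$orfs, file.path(dir, "orfs.gff3"))
  write_context(universe$context, file.path(dir, "context.csv"))
  refs <- universe$references
  ss <- Biostrings::DNAStringSet(refs$repeat_seq)
  names(ss) <- sprintf("ref%03d %s", seq_len(nrow(refs)), refs$subtype)
  Biostrings::writeXStringSet(ss, file.path(dir, "references.fasta"))
  write_truth_bundle(universe$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
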