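# Orientation and PAM calling from flank profiles. The PAM side is a
# mechanistic constant per system type (5' of the protospacer for types I,
# IV and V; 3' for type II), so the side carrying the conserved flank signal
# fixes the transcription orientation of the array.

#' PAM side expected for a CRISPR-Cas subtype
#'
#' @param subtype subtype label (e.g. `"I-E"`, `"II-A"`, `"IV"`, `"V"`).
#' @return `"upstream"` (types I, IV, V), `"downstream"` (type II) or `NA`
#'   for types without a PAM requirement usable here (III, VI, unassigned).
#' @export
subtype_pam_side <- function(subtype) {
  vapply(as.character(subtype), function(st) {
    if (is.na(st) || st == "" || st == "unassigned") return(NA_character_)
    major <- sub("-.*$", "", st)
    switch(major,
           "I" = "upstream", "IV" = "upstream", "V" = "upstream",
           "II" = "downstream",
           NA_character_)
  }, "", USE.NAMES = FALSE)
}

side_qualifies <- function(ic, median_ic, config) {
  qual <- ic > config$orient_bits_min & ic > config$orient_median_factor * median_ic
  list(n = sum(qual), score = sum(ic[qual]))
}

#' Predict the transcription orientation of a repeat cluster
#'
#' A flank side qualifies when at least two positions exceed both
#' `config$orient_bits_min` bits and `config$orient_median_factor` times the
#' median information content of both flanks. The orientation is `forward`
#' when the qualifying (or better-scoring, if both qualify) side is the
#' subtype's known PAM side, `reverse` when it is the opposite side, and
#' `undetermined` when fewer than `config$min_protospacers` unique
#' protospacers are available or neither side qualifies.
#'
#' For subtypes without a usable PAM side (type III, VI, unassigned) the
#' externally supplied orientation is returned unchanged with source
#' `"external"`.
#'
#' @param profiles [build_profile()] result.
#' @param subtype cluster subtype label.
#' @param config [pipeline_config()].
#' @param external_orientation orientation to pass through for subtypes
#'   without a PAM side (default `"forward"`, i.e. as stored).
#' @return list of class `orientation_call`: `cluster_id`, `orientation`
#'   (`forward`/`reverse`/`undetermined`), `source` (`pam_based`/`external`),
#'   `pam_side`, `qualifying_positions` and `conservation_score` per side.
#' @export
predict_orientation <- function(profiles, subtype,
                                config = pipeline_config(),
                                external_orientation = "forward") {
  side <- subtype_pam_side(subtype)
  up <- side_qualifies(profiles$upstream$ic, profiles$median_ic, config)
  dn <- side_qualifies(profiles$downstream$ic, profiles$median_ic, config)
  call <- list(cluster_id = profiles$cluster_id,
               orientation = "undetermined",
               source = "pam_based",
               pam_side = side,
               qualifying_positions = c(upstream = up$n, downstream = dn$n),
               conservation_score = c(upstream = up$score,
                                      downstream = dn$score))
  if (is.na(side)) {
    call$orientation <- external_orientation
    call$source <- "external"
    class(call) <- "orientation_call"
    return(call)
  }
  if (profiles$n_protospacers < config$min_protospacers) {
    class(call) <- "orientation_call"
    return(call)
  }
  up_ok <- up$n >= 2L
  dn_ok <- dn$n >= 2L
  signal_side <- if (up_ok && dn_ok) {
    if (up$score >= dn$score) "upstream" else "downstream"
  } else if (up_ok) "upstream" else if (dn_ok) "downstream" else NA_character_
  if (!is.na(signal_side)) {
    call$orientation <- if (signal_side == side) "forward" else "reverse"
  }
  class(call) <- "orientation_call"
  call
}

#' @export
print.orientation_call <- function(x, ...) {
  cat(sprintf("cluster %s: orientation %s (%s; PAM side %s)\n",
              x$cluster_id, x$orientation, x$source,
              x$pam_side %||% "none"))
  invisible(x)
}

#' Render the base frequencies of one flagged position as an IUPAC code
#'
#' The smallest base set, filled in descending frequency, whose cumulative
#' frequency reaches 0.8 is mapped to its IUPAC character. Frequency ties
#' are broken alphabetically for determinism.
#'
#' @param freqs named numeric vector over A, C, G, T summing to 1.
#' @param cum_threshold cumulative frequency the set must reach (default 0.8).
#' @return a single IUPAC character.
#' @examples
#' motif_to_iupac(c(A = 0.5, C = 0, G = 0.05, T = 0.45)) # "W"
#' @export
motif_to_iupac <- function(freqs, cum_threshold = 0.8) {
  stopifnot(all(BASES %in% names(freqs)))
  f <- freqs[BASES]
  ord <- order(-f, BASES)
  cum <- cumsum(f[ord])
  k <- which(cum >= cum_threshold - 1e-12)[1]
  if (is.na(k)) k <- 4L
  SET_TO_IUPAC[[paste(sort(BASES[ord][1:k]), collapse = "")]]
}

#' Call the PAM of an oriented repeat cluster
#'
#' On the subtype's PAM side, positions with information content above
#' `config$pam_bits_min` bits and `config$pam_median_factor` times the
#' median of both flanks are flagged. A call is made when the profile has at
#' least `config$min_protospacers` unique protospacers and at least
#' `config$pam_min_size` flagged positions. The motif spans from the most
#' distal flagged position through -1 (upstream PAMs) or from +1 through the
#' most distal flagged position (downstream PAMs); unflagged interior
#' positions are rendered N and flagged positions via [motif_to_iupac()].
#'
#' @param profiles [build_profile()] result, already in the resolved
#'   orientation.
#' @param subtype cluster subtype label.
#' @param config [pipeline_config()].
#' @param side PAM side override; defaults to the subtype's side.
#' @return list of class `pam_call` with `cluster_id`, `side`,
#'   `flagged_positions` (signed positions), `motif`, `freqs` (base
#'   frequency matrix over the motif span), or `NULL` when no call is made.
#' @export
call_pam <- function(profiles, subtype, config = pipeline_config(),
                     side = NULL) {
  side <- side %||% subtype_pam_side(subtype)
  if (is.na(side)) side <- "upstream"
  if (profiles$n_protospacers < config$min_protospacers) return(NULL)
  prof <- profiles[[side]]
  flag <- prof$ic > config$pam_bits_min &
    prof$ic > config$pam_median_factor * profiles$median_ic
  if (sum(flag) < config$pam_min_size) return(NULL)

  pos <- prof$positions
  L <- length(pos)
  if (side == "upstream") {
    span <- which(flag)[1]:L        # most distal flagged position .. -1
  } else {
    span <- 1:max(which(flag))      # +1 .. most distal flagged position
  }
  tot <- colSums(prof$counts)
  motif <- vapply(span, function(j) {
    if (!flag[j]) return("N")
    if (tot[j] == 0) return("N")
    motif_to_iupac(prof$counts[, j] / tot[j])
  }, "")
  freqs <- sweep(prof$counts[, span, drop = FALSE], 2, pmax(1, tot[span]), "/")
  colnames(freqs) <- pos[span]
  structure(list(cluster_id = profiles$cluster_id,
                 side = side,
                 flagged_positions = pos[flag],
                 motif = paste(motif, collapse = ""),
                 freqs = freqs),
            class = "pam_call")
}

#' @export
print.pam_call <- function(x, ...) {
  cat(sprintf("cluster %s: PAM %s (%s, positions %s)\n",
              x$cluster_id, x$motif, x$side,
              paste(x$flagged_positions, collapse = ",")))
  invisible(x)
}

#' Compare a repeat's spacer-proximal end with the called PAM
#'
#' For upstream PAMs of length k the PAM positions -k..-1 are compared with
#' the last k bases of the repeat (the repeat bases occupying the same
#' positions relative to the spacer inside the array); for downstream PAMs
#' the positions +1..+k are compared with the first k bases of the repeat on
#' the other side. A position matches when the repeat base is contained in
#' the IUPAC set of the PAM character.
#'
#' @param repeat_seq repeat sequence, oriented per the cluster's orientation
#'   call.
#' @param pam_call a [call_pam()] result.
#' @return data.frame with `position`, `repeat_base`, `pam_base`, `match`.
#' @export
compare_repeat_pam <- function(repeat_seq, pam_call) {
  k <- nchar(pam_call$motif)
  rl <- nchar(repeat_seq)
  stopifnot(k >= 1, rl >= k)
  pam_chars <- strsplit(pam_call$motif, "")[[1]]
  if (pam_call$side == "upstream") {
    rep_chars <- strsplit(substr(repeat_seq, rl - k + 1L, rl), "")[[1]]
    positions <- seq(-k, -1L)
  } else {
    rep_chars <- strsplit(substr(repeat_seq, 1L, k), "")[[1]]
    positions <- seq(1L, k)
  }
  match <- vapply(seq_len(k), function(i) {
    rep_chars[i] %in% IUPAC_SETS[[pam_chars[i]]]
  }, logical(1))
  data.frame(position = positions, repeat_base = rep_chars,
             pam_base = pam_chars, match = match, stringsAsFactors = FALSE)
}

#' Detect the conserved crRNA 5' handle motif at a repeat's 3' end
#'
#' Many type I and type III repeats end in the motif ATTGAAAC, which is
#' transcribed into the 5' handle of the crRNA held by the effector complex.
#'
#' @param repeat_seq repeat sequence in transcription orientation.
#' @param max_mismatch mismatches tolerated (default 1).
#' @param window the motif must lie within this many nt of the 3' end
#'   (default 10).
#' @return list with `found` (logical) and `offset` (nt between the motif's
#'   last base and the repeat's 3' end; `NA` when not found).
#' @export
detect_crRNA_handle_motif <- function(repeat_seq, max_mismatch = 1L,
                                      window = 10L) {
  motif <- "ATTGAAAC"
  k <- nchar(motif)
  rl <- nchar(repeat_seq)
  if (rl < k) return(list(found = FALSE, offset = NA_integer_))
  mchars <- strsplit(motif, "")[[1]]
  starts <- seq(max(1L, rl - window + 1L), rl - k + 1L)
  best <- NA_integer_
  for (s in rev(starts)) {  # prefer the most 3' occurrence
    wchars <- strsplit(substr(repeat_seq, s, s + k - 1L), "")[[1]]
    if (sum(wchars != mchars) <= max_mismatch) {
      best <- rl - (s + k - 1L)
      break
    }
  }
  list(found = !is.na(best), offset = best)
}
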