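#' Apply the two-step matched-fraction filter
#'
#' Reproduces the published filtering of raw spacer hits:
#' \enumerate{
#'   \item spacers shorter than `config$min_spacer_len` (default 27 nt) are
#'     removed entirely;
#'   \item hits inside CRISPR arrays (`in_array`) are removed;
#'   \item step 1 keeps hits with matched fraction strictly above
#'     `config$step1_frac` (default 0.90);
#'   \item step 2 additionally keeps hits with matched fraction strictly
#'     above `config$step2_frac` (default 0.80) when the same subject
#'     received a step-1 hit from a different spacer of the same genus.
#' }
#' Step 2 can never introduce a subject absent from the step-1 results.
#' Spacers without a genus cannot participate in step 2; they are kept on
#' step-1 evidence only and a message notes how many were affected.
#'
#' @param hits hit table with `matched_fraction` and `in_array` computed.
#' @param records spacer record table supplying genus and spacer length.
#' @param config [pipeline_config()].
#' @return the kept hits with a `kept_step` column (`"step1"` or `"step2"`).
#' @export
apply_two_step_filter <- function(hits, records, config = pipeline_config()) {
  if (!"in_array" %in% names(hits)) {
    stop("hits must carry an 'in_array' column; run flag_array_hits() first")
  }
  len_of <- stats::setNames(nchar(records$sequence), records$spacer_id)
  genus_of <- stats::setNames(records$genus, records$spacer_id)

  h <- hits[len_of[hits$spacer_id] >= config$min_spacer_len & !hits$in_array,
            , drop = FALSE]
  step1 <- h$matched_fraction > config$step1_frac

  # subjects with a step-1 hit, per genus of the hitting spacer
  g <- genus_of[h$spacer_id]
  s1_pairs <- unique(data.frame(subject_id = h$subject_id[step1],
                                genus = g[step1],
                                spacer_id = h$spacer_id[step1],
                                stringsAsFactors = FALSE))
  no_genus <- !step1 & h$matched_fraction > config$step2_frac &
    (is.na(g) | g == "")
  if (any(no_genus)) {
    message(sprintf(
      "%d candidate step-2 hit(s) lack a genus and stay step-1-only",
      sum(no_genus)))
  }
  step2 <- vapply(seq_len(nrow(h)), function(i) {
    if (step1[i] || h$matched_fraction[i] <= config$step2_frac) return(FALSE)
    gi <- g[[i]]
    if (is.na(gi) || gi == "") return(FALSE)
    any(s1_pairs$subject_id == h$subject_id[i] & s1_pairs$genus == gi &
          s1_pairs$spacer_id != h$spacer_id[i])
  }, logical(1))

  kept <- h[step1 | step2, , drop = FALSE]
  kept$kept_step <- ifelse(kept$matched_fraction > config$step1_frac,
                           "step1", "step2")
  rownames(kept) <- NULL
  kept
}
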