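# Coding- vs template-strand targeting. "Targeting strand X" means the
# crRNA base-pairs (hybridises) strand X, so a coding-strand call is
# synonymous with the ability to also base-pair the mRNA.

#' Select the primary target subject of a spacer
#'
#' One target sequence per spacer: among the subjects of its kept hits,
#' subjects from the nucleotide database take priority over metagenomes
#' (which take priority over synthetic subjects); within a class the longest
#' subject wins, ties broken by lexicographic subject id.
#'
#' @param kept_hits kept hit table rows of one spacer.
#' @param subjects subject table with `source_class` and `length`.
#' @return a `subject_id`.
#' @export
select_primary_target <- function(kept_hits, subjects) {
  stopifnot(nrow(kept_hits) >= 1)
  sub <- subjects[match(unique(kept_hits$subject_id), subjects$subject_id),
                  , drop = FALSE]
  prio <- match(sub$source_class, c("nucleotide_db", "metagenome", "synthetic"))
  ord <- order(prio, -sub$length, sub$subject_id)
  sub$subject_id[ord[1]]
}

#' Scan a subject for open reading frames
#'
#' Simple six-frame scanner (bacterial code): per stop codon, the longest
#' open frame starting at ATG, GTG or TTG and ending at the stop, reported
#' when its total length (start through stop codon) is at least `min_len`.
#' Coordinates are 0-based half-open on the plus strand and include the stop
#' codon; lengths are divisible by 3. A GFF annotation, when available,
#' should be preferred over this fallback.
#'
#' @param subject_id,sequence the subject to scan.
#' @param min_len minimum ORF length in nt (default 90).
#' @return ORF table: `subject_id`, `start`, `end`, `strand`.
#' @export
find_orfs <- function(subject_id, sequence, min_len = 90L) {
  scan_strand <- function(seq, strand) {
    n <- nchar(seq)
    if (n < min_len) return(NULL)
    ch <- strsplit(seq, "")[[1]]
    codon_at <- function(i) paste(ch[i:(i + 2L)], collapse = "")
    res <- list()
    for (frame in 0:2) {
      starts_pending <- integer(0)
      i <- frame + 1L
      while (i + 2L <= n) {
        cod <- codon_at(i)
        if (cod %in% c("ATG", "GTG", "TTG")) {
          starts_pending <- c(starts_pending, i)
        }
        if (cod %in% c("TAA", "TAG", "TGA")) {
          if (length(starts_pending)) {
            s <- starts_pending[1]     # longest frame for this stop
            if (i + 2L - s + 1L >= min_len) {
              res[[length(res) + 1L]] <- c(s, i + 3L)  # 1-based, half-open end+1
            }
          }
          starts_pending <- integer(0)
        }
        i <- i + 3L
      }
    }
    if (!length(res)) return(NULL)
    m <- do.call(rbind, res)
    if (strand == "+") {
      data.frame(start = m[, 1] - 1L, end = m[, 2] - 1L, strand = "+",
                 stringsAsFactors = FALSE)
    } else {
      # map back to plus-strand coordinates
      data.frame(start = n - (m[, 2] - 1L), end = n - (m[, 1] - 1L),
                 strand = "-", stringsAsFactors = FALSE)
    }
  }
  out <- rbind(scan_strand(sequence, "+"),
               scan_strand(revcomp(sequence), "-"))
  if (is.null(out)) {
    return(data.frame(subject_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  cbind(data.frame(subject_id = subject_id, stringsAsFactors = FALSE), out)
}

#' Classify a hit as coding- or template-strand targeting
#'
#' Let s be the subject strand whose sequence matches the spacer in its
#' transcribed orientation (the stored strand of the hit, flipped when the
#' cluster orientation is `reverse`). The crRNA base-pairs the complement of
#' its own sequence, so the targeted strand is the complement of s: the call
#' is `coding` when s is the ORF's template strand (s differs from the ORF
#' strand), `template` when s is the coding strand. The protospacer must lie
#' fully inside exactly one ORF; otherwise (intergenic, boundary-straddling,
#' overlapping genes, or unresolved orientation) the call is `undetermined`.
#'
#' @param hit one hit row (uses `subject_id`, `s_start`, `s_end`, `strand`).
#' @param orfs ORF table for the subject.
#' @param orientation cluster orientation (`forward`, `reverse`,
#'   `undetermined`).
#' @return one of `"coding"`, `"template"`, `"undetermined"`.
#' @export
classify_strand <- function(hit, orfs, orientation = "forward") {
  if (!orientation %in% c("forward", "reverse")) return("undetermined")
  o <- orfs[orfs$subject_id == hit$subject_id &
              orfs$start <= hit$s_start & orfs$end >= hit$s_end, , drop = FALSE]
  if (nrow(o) != 1L) return("undetermined")
  s <- hit$strand
  if (orientation == "reverse") s <- if (s == "+") "-" else "+"
  if (s != o$strand) "coding" else "template"
}

#' Exact two-sided binomial test for strand bias
#'
#' Tests the counts against an expected probability of 0.5. Two-sided in the
#' minimum-likelihood sense: the p-value sums the probabilities of all
#' outcomes no more likely than the observed one.
#'
#' @param n_coding,n_template strand call counts (total >= 1).
#' @return p-value in `[0, 1]`.
#' @examples
#' binomial_strand_test(15, 5) # 0.04139
#' @export
binomial_strand_test <- function(n_coding, n_template) {
  stopifnot(n_coding + n_template >= 1)
  stats::binom.test(n_coding, n_coding + n_template, p = 0.5)$p.value
}

# major type of a subtype label ("I-E" -> "I")
major_type <- function(subtype) sub("-.*$", "", as.character(subtype))

# which major effector types co-occur in the host, from the cas_genes field
cas_context_label <- function(cas_genes) {
  vapply(cas_genes, function(cg) {
    if (is.na(cg) || cg == "") return("none")
    types <- unique(major_type(trimws(strsplit(cg, "[,;|]")[[1]])))
    types <- types[types != ""]
    if (!length(types)) "none" else paste(sort(types), collapse = "+")
  }, "", USE.NAMES = FALSE)
}

#' Grouped strand-bias summaries
#'
#' Aggregates per-spacer strand calls into per-group coding/template counts
#' with an exact binomial test at p0 = 0.5. Undetermined calls are excluded;
#' groups with no determined calls are omitted.
#'
#' @param strand_calls data.frame with `spacer_id`, `call`.
#' @param records spacer record table (supplies subtype, genus, cas_genes).
#' @param group_by one of `"subtype"`, `"genus_subtype"`,
#'   `"subtype_cas_context"`.
#' @param alpha significance level (default 0.01).
#' @return data.frame: `group`, `n_coding`, `n_template`, `fraction_coding`,
#'   `p_value`, `significant`.
#' @export
group_strand_bias <- function(strand_calls, records, group_by = "subtype",
                              alpha = 0.01) {
  choices <- c("subtype", "genus_subtype", "subtype_cas_context")
  if (!group_by %in% choices) {
    stop("unknown group key '", group_by, "'; expected one of: ",
         paste(choices, collapse = ", "), call. = FALSE)
  }
  m <- match(strand_calls$spacer_id, records$spacer_id)
  grp <- switch(group_by,
    subtype = records$subtype[m],
    genus_subtype = paste(records$genus[m], records$subtype[m]),
    subtype_cas_context = paste(records$subtype[m], "|",
                                cas_context_label(records$cas_genes[m])))
  det <- strand_calls$call %in% c("coding", "template")
  grp <- grp[det]
  call <- strand_calls$call[det]
  if (!length(grp)) {
    return(data.frame(group = character(), n_coding = integer(),
                      n_template = integer(), fraction_coding = numeric(),
                      p_value = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(sort(unique(grp)), function(g) {
    nc <- sum(call == "coding" & grp == g)
    nt <- sum(call == "template" & grp == g)
    p <- binomial_strand_test(nc, nt)
    data.frame(group = g, n_coding = nc, n_template = nt,
               fraction_coding = nc / (nc + nt), p_value = p,
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-spacer strand calls over a cohort
#'
#' Applies [select_primary_target()] and [classify_strand()] to every spacer
#' with kept hits, using per-cluster orientation calls.
#'
#' @param kept_hits kept hit table.
#' @param subjects subject table.
#' @param orfs ORF table (GFF-derived or [find_orfs()] output).
#' @param membership spacer -> cluster mapping.
#' @param orientations named character vector `cluster_id` -> orientation.
#' @return data.frame: `spacer_id`, `subject_id`, `call`.
#' @export
strand_calls <- function(kept_hits, subjects, orfs, membership, orientations) {
  cl_of <- stats::setNames(membership$cluster_id, membership$spacer_id)
  sp <- unique(kept_hits$spacer_id)
  rows <- lapply(sp, function(s) {
    hs <- kept_hits[kept_hits$spacer_id == s, , drop = FALSE]
    target <- select_primary_target(hs, subjects)
    hs <- hs[hs$subject_id == target, , drop = FALSE]
    hs <- hs[order(-hs$matched_fraction, hs$s_start), , drop = FALSE]
    ori <- orientations[[cl_of[[s]] %||% ""]] %||% "undetermined"
    data.frame(spacer_id = s, subject_id = target,
               call = classify_strand(hs[1, ], orfs, ori),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
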