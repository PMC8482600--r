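#' Read a spacer table
#'
#' Parses a delimited spacer export (CRISPRCasdb-style) into the canonical
#' spacer record table used throughout the pipeline. The default dialect
#' recognises the standard export column names (`Spacers`, `Repeats`,
#' `Accessionnrs`, `Subtype`, `cas_genes`, `Genus`, ...) as well as plain
#' lower-case equivalents. Unknown columns are carried through untouched.
#'
#' Sequences are upcased; IUPAC ambiguity codes other than N are mapped to N
#' with a warning. A character that is not an IUPAC nucleotide code at all is
#' a record-level error reported with its row number.
#'
#' @param path delimited text file with a header row.
#' @param dialect named list mapping canonical fields (`spacer`, `repeat`,
#'   `accession`, `genus`, `subtype`, `cas_genes`, `array_id`, `position`,
#'   `spacer_id`, taxonomy ranks) to candidate column names; defaults cover
#'   the standard export schema.
#' @param sep field separator (default `,`).
#' @return data.frame of spacer records with canonical columns `spacer_id`,
#'   `sequence`, `repeat_seq`, `host_accession`, `genus`, `array_id`,
#'   `position_in_array`, `subtype`, `cas_genes`, plus any extra input columns.
#' @export
read_spacer_table <- function(path, dialect = spacer_table_dialect(), sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  pick <- function(field) {
    cand <- dialect[[field]]
    hit <- cand[cand %in% names(raw)]
    if (length(hit)) hit[[1]] else NA_character_
  }
  mandatory <- c("spacer", "repeat", "accession")
  for (f in mandatory) {
    if (is.na(pick(f))) {
      stop(sprintf(
        "spacer table is missing a mandatory column for '%s' (looked for: %s)",
        f, paste(dialect[[f]], collapse = ", ")), call. = FALSE)
    }
  }
  n <- nrow(raw)
  get_or <- function(field, default) {
    col <- pick(field)
    if (is.na(col)) rep(default, n) else as.character(raw[[col]])
  }

  check_seq <- function(x, what) {
    x <- toupper(x)
    bad <- grepl("[^ACGTURYSWKMBDHVN]", x)
    if (any(bad)) {
      stop(sprintf("invalid character in %s at row %d: '%s'",
                   what, which(bad)[1], x[which(bad)[1]]), call. = FALSE)
    }
    normalize_dna(x, what)
  }

  spacer_seq <- check_seq(as.character(raw[[pick("spacer")]]), "spacer")
  repeat_seq <- check_seq(as.character(raw[[pick("repeat")]]), "repeat")

  ids <- if (!is.na(pick("spacer_id"))) {
    as.character(raw[[pick("spacer_id")]])
  } else {
    sprintf("sp%05d", seq_len(n))
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate spacer_id '%s' in spacer table",
                 ids[duplicated(ids)][1]), call. = FALSE)
  }

  rec <- data.frame(
    spacer_id = ids,
    sequence = spacer_seq,
    repeat_seq = repeat_seq,
    host_accession = as.character(raw[[pick("accession")]]),
    genus = get_or("genus", NA_character_),
    array_id = get_or("array_id", NA_character_),
    position_in_array = suppressWarnings(
      as.integer(get_or("position", NA_character_))),
    subtype = get_or("subtype", "unassigned"),
    cas_genes = get_or("cas_genes", ""),
    stringsAsFactors = FALSE
  )
  rec$subtype[is.na(rec$subtype) | rec$subtype == ""] <- "unassigned"

  used <- vapply(names(dialect), pick, "")
  extra <- setdiff(names(raw), used[!is.na(used)])
  for (col in extra) rec[[col]] <- raw[[col]]
  rec
}

#' @rdname read_spacer_table
#' @export
spacer_table_dialect <- function() {
  list(
    spacer = c("Spacers", "spacer", "sequence", "spacer_sequence"),
    "repeat" = c("Repeats", "repeat", "repeat_seq", "repeat_sequence"),
    accession = c("Accessionnrs", "accession", "host_accession"),
    genus = c("Genus", "genus"),
    subtype = c("Subtype", "subtype"),
    cas_genes = c("cas_genes", "Cas_genes"),
    array_id = c("array_id", "Array"),
    position = c("position_in_array", "position", "Position"),
    spacer_id = c("spacer_id", "Spacer_id")
  )
}

#' Write a spacer table
#'
#' Inverse of [read_spacer_table()]: writes the canonical record table with
#' the standard export column names so the output round-trips through the reader.
#'
#' @param records spacer record data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spacer_table <- function(records, path) {
  out <- data.frame(
    spacer_id = records$spacer_id,
    Spacers = records$sequence,
    Repeats = records$repeat_seq,
    Accessionnrs = records$host_accession,
    Genus = records$genus,
    array_id = records$array_id,
    position_in_array = records$position_in_array,
    Subtype = records$subtype,
    cas_genes = records$cas_genes,
    stringsAsFactors = FALSE
  )
  canon <- c("spacer_id", "sequence", "repeat_seq", "host_accession", "genus",
             "array_id", "position_in_array", "subtype", "cas_genes")
  for (col in setdiff(names(records), canon)) out[[col]] <- records[[col]]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarise the fraction of spacers with kept hits per group
#'
#' @param records spacer record table.
#' @param hits hit table (only `spacer_id` is consulted; pass the kept hits).
#' @param group_by name of a grouping column in `records` (e.g. `subtype`,
#'   `genus`, or a taxonomy rank column).
#' @param min_group_size groups below this size are flagged (`small = TRUE`)
#'   rather than dropped.
#' @return data.frame with `group`, `n_spacers`, `n_with_hit`, `fraction`,
#'   `small`.
#' @export
summarize_hit_fractions <- function(records, hits, group_by = "subtype",
                                    min_group_size = 1L) {
  if (!group_by %in% names(records)) {
    stop(sprintf("unknown group key '%s': not a column of the spacer table",
                 group_by), call. = FALSE)
  }
  grp <- as.character(records[[group_by]])
  keep <- !is.na(grp) & grp != ""
  records <- records[keep, , drop = FALSE]
  grp <- grp[keep]
  with_hit <- records$spacer_id %in% unique(hits$spacer_id)
  tab <- stats::aggregate(
    cbind(n_spacers = rep(1L, length(grp)), n_with_hit = as.integer(with_hit)),
    by = list(group = grp), FUN = sum)
  tab$fraction <- tab$n_with_hit / tab$n_spacers
  tab$small <- tab$n_spacers < min_group_size
  tab[order(tab$group), , drop = FALSE]
}
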