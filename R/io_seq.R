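#' Read subject sequences from FASTA
#'
#' @param path FASTA file of candidate target sequences.
#' @param source_class provenance label attached to every subject
#'   (`nucleotide_db`, `metagenome` or `synthetic`); used by
#'   [select_primary_target()] to prioritise databases.
#' @return data.frame with `subject_id` (FASTA id up to first whitespace),
#'   `sequence` (upcased, ambiguity codes mapped to N), `source_class`,
#'   `length`.
#' @export
read_fasta <- function(path, source_class = "nucleotide_db") {
  source_class <- match.arg(source_class,
                            c("nucleotide_db", "metagenome", "synthetic"))
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(data.frame(subject_id = character(), sequence = character(),
                      source_class = character(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sequence id '%s' in %s",
                 ids[duplicated(ids)][1], path), call. = FALSE)
  }
  seqs <- normalize_dna(as.character(ss), "subject")
  data.frame(subject_id = ids, sequence = unname(seqs),
             source_class = source_class, length = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Write subject sequences to FASTA
#'
#' @param subjects subject table as returned by [read_fasta()].
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(subjects, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(subjects$sequence)
  names(ss) <- subjects$subject_id
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

HIT_TABLE_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                    "gapopen", "qstart", "qend", "sstart", "send",
                    "evalue", "bitscore", "qlen", "nident")

#' Read a tabular hit file (blastn outfmt-6 style with qlen and nident)
#'
#' Expects the 12 standard tabular columns followed by the `qlen` and
#' `nident` extensions. Strand is inferred from `sstart > send`; subject
#' coordinates are converted to 0-based half-open intervals on the plus
#' strand.
#'
#' @param path tab-separated hit file without a header.
#' @return data.frame with `spacer_id`, `subject_id`, `s_start`, `s_end`
#'   (0-based half-open, plus strand), `strand` (`+`/`-`), `n_ident`,
#'   `q_len`, `matched_fraction`.
#' @export
read_hit_table <- function(path) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < length(HIT_TABLE_COLS)) {
    stop(sprintf(paste0(
      "hit table has %d columns but %d are required; expected the standard ",
      "tabular columns plus the extensions 'qlen' and 'nident' ",
      "(outfmt \"6 %s\")"),
      ncol(raw), length(HIT_TABLE_COLS),
      paste(HIT_TABLE_COLS, collapse = " ")), call. = FALSE)
  }
  names(raw)[seq_along(HIT_TABLE_COLS)] <- HIT_TABLE_COLS
  minus <- raw$sstart > raw$send
  lo <- ifelse(minus, raw$send, raw$sstart)
  hi <- ifelse(minus, raw$sstart, raw$send)
  data.frame(
    spacer_id = as.character(raw$qseqid),
    subject_id = as.character(raw$sseqid),
    s_start = as.integer(lo - 1L),
    s_end = as.integer(hi),
    strand = ifelse(minus, "-", "+"),
    n_ident = as.integer(raw$nident),
    q_len = as.integer(raw$qlen),
    matched_fraction = raw$nident / raw$qlen,
    stringsAsFactors = FALSE
  )
}

#' Write hits in the extended tabular format
#'
#' Inverse coordinate conversion of [read_hit_table()]: internal 0-based
#' half-open plus-strand intervals become 1-based inclusive coordinates with
#' `sstart > send` encoding a minus-strand hit.
#'
#' @param hits internal hit table.
#' @param path output path (tab-separated, no header).
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  minus <- hits$strand == "-"
  out <- data.frame(
    qseqid = hits$spacer_id,
    sseqid = hits$subject_id,
    pident = round(100 * hits$n_ident / pmax(1L, hits$s_end - hits$s_start), 3),
    length = hits$s_end - hits$s_start,
    mismatch = pmax(0L, (hits$s_end - hits$s_start) - hits$n_ident),
    gapopen = 0L,
    qstart = 1L,
    qend = hits$q_len,
    sstart = ifelse(minus, hits$s_end, hits$s_start + 1L),
    send = ifelse(minus, hits$s_start + 1L, hits$s_end),
    evalue = 0,
    bitscore = 2 * hits$n_ident,
    qlen = hits$q_len,
    nident = hits$n_ident,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read CDS annotations from GFF3
#'
#' Only `CDS` features are retained. 1-based closed GFF coordinates become
#' 0-based half-open.
#'
#' @param path GFF3 file.
#' @return data.frame with `subject_id`, `start`, `end` (0-based half-open),
#'   `strand`.
#' @export
read_gff <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  empty <- data.frame(subject_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (!length(body_idx)) {
    warning("no features in GFF file: ", path, call. = FALSE)
    return(empty)
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8L)) {
    stop(sprintf("malformed GFF line %d: expected >= 8 tab-separated fields",
                 body_idx[which(nf < 8L)[1]]), call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:8))
  is_cds <- m[, 3] == "CDS"
  if (!any(is_cds)) {
    warning("GFF file contains no CDS features: ", path, call. = FALSE)
    return(empty)
  }
  m <- m[is_cds, , drop = FALSE]
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  bad <- is.na(start1) | is.na(end1) | start1 > end1
  if (any(bad)) {
    stop(sprintf("malformed GFF line %d: invalid coordinates",
                 body_idx[is_cds][which(bad)[1]]), call. = FALSE)
  }
  data.frame(subject_id = m[, 1], start = start1 - 1L, end = end1,
             strand = m[, 7], stringsAsFactors = FALSE)
}

#' Write CDS annotations to GFF3
#'
#' @param orfs ORF table (`subject_id`, `start`, `end`, `strand`),
#'   0-based half-open.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(orfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(orfs)) {
    writeLines(sprintf("%s\tspacerscope\tCDS\t%d\t%d\t.\t%s\t0\tID=cds%d",
                       orfs$subject_id, orfs$start + 1L, orfs$end,
                       orfs$strand, seq_len(nrow(orfs))), con)
  }
  invisible(path)
}

#' Read subtype reference repeats from FASTA
#'
#' Each record's description (the text after the id) names the subtype,
#' e.g. `>ref1 I-E`.
#'
#' @param path FASTA file of reference repeats.
#' @return data.frame with `repeat_seq`, `subtype`.
#' @export
read_subtype_references <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  subtype <- trimws(sub("^\\S+\\s*", "", names(ss)))
  if (any(subtype == "")) {
    stop("subtype reference FASTA records must carry the subtype label in ",
         "the description, e.g. '>ref1 I-E'", call. = FALSE)
  }
  data.frame(repeat_seq = unname(normalize_dna(as.character(ss), "reference repeat")),
             subtype = subtype, stringsAsFactors = FALSE)
}
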