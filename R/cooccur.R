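# Multi-effector compatible CRISPR arrays: genomes where spacers of one
# array satisfy the targeting requirements of cas gene clusters from more
# than one subtype. Cas cluster intervals and subtype/targeting-mode labels
# are inputs (from a context table); cas gene detection itself is out of
# scope.

#' Targeting mode of a CRISPR-Cas subtype
#'
#' @param subtype subtype label.
#' @return `"DNA"` for types I, II, IV and V; `"RNA"` for III and VI.
#' @export
targeting_mode <- function(subtype) {
  ifelse(major_type(subtype) %in% c("III", "VI"), "RNA", "DNA")
}

#' Read a cas-context table
#'
#' One row per element of a genome: `kind` is `cas_cluster` or `array`.
#' Cas cluster rows carry `subtype`, `has_cas1_cas2` (0/1); array rows carry
#' `array_id` and `repeat_cluster_id`. All rows carry `accession`, `start`,
#' `end` (0-based half-open).
#'
#' @param path CSV path.
#' @return context data.frame.
#' @export
read_context <- function(path) {
  ctx <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("accession", "kind", "start", "end")
  miss <- setdiff(need, names(ctx))
  if (length(miss)) {
    stop("context table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ctx
}

#' Write a cas-context table
#'
#' @param ctx context data.frame ([read_context()] schema).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_context <- function(ctx, path) {
  utils::write.csv(ctx, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# edge-to-edge distance of two half-open intervals (0 when overlapping)
interval_distance <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}

#' Link CRISPR arrays to nearby cas gene clusters
#'
#' An array is linked to every cas cluster of the same genome whose interval
#' lies within `config$proximity_bp` (default 25000 bp, exclusive) of the
#' array, edge to edge.
#'
#' @param context context table for one or more genomes.
#' @param config [pipeline_config()].
#' @return data.frame of links: `accession`, `array_id`,
#'   `repeat_cluster_id`, `cas_subtype`, `distance`.
#' @export
link_arrays_to_systems <- function(context, config = pipeline_config()) {
  arrays <- context[context$kind == "array", , drop = FALSE]
  cas <- context[context$kind == "cas_cluster", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(arrays))) {
    a <- arrays[i, ]
    cc <- cas[cas$accession == a$accession, , drop = FALSE]
    if (!nrow(cc)) next
    d <- interval_distance(a$start, a$end, cc$start, cc$end)
    sel <- d < config$proximity_bp
    if (any(sel)) {
      out[[length(out) + 1L]] <- data.frame(
        accession = a$accession, array_id = a$array_id,
        repeat_cluster_id = a$repeat_cluster_id,
        cas_subtype = cc$subtype[sel], distance = d[sel],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(accession = character(), array_id = character(),
                      repeat_cluster_id = character(),
                      cas_subtype = character(), distance = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# strip flanking N from a motif string for PAM comparison
trim_pam <- function(motif) gsub("^N+|N+$", "", motif)

#' Classify a genome's multi-effector compatibility category
#'
#' Three organisations of compatible co-occurring systems are recognised:
#' \describe{
#'   \item{category 1}{two repeat clusters of different DNA-targeting
#'     subtypes in the genome carry the same PAM motif (own repeats, own
#'     adaptation machinery).}
#'   \item{category 2}{a DNA-targeting and an RNA-targeting cluster with
#'     distinct repeat clusters carry the same PAM (distinct repeats,
#'     shared acquisition machinery).}
#'   \item{category 3}{cas gene clusters of at least two different subtypes
#'     are linked (within the proximity window) to arrays of a single
#'     repeat cluster, and the genome has no other arrays linked to those
#'     cas clusters (shared repeats, shared acquisition machinery).}
#' }
#' "Same PAM" is exact motif-string equality after trimming flanking N;
#' IUPAC near-matches are surfaced in `soft_pam_match` but never drive a
#' category. When several categories hold, the most-shared one (3 > 2 > 1)
#' is reported with all evidence.
#'
#' @param context context table of one genome.
#' @param pam_catalog data.frame with `cluster_id`, `subtype`, `PAM` (from
#'   the PAM calling stage); clusters without a call may be absent or have
#'   `PAM = NA`.
#' @param config [pipeline_config()].
#' @return list of class `compatibility_call`: `accession`, `category`
#'   (`"1"`, `"2"`, `"3"` or `"none"`), `subtype_pair`, `shared_pam`,
#'   `evidence` (character vector), `soft_pam_match`.
#' @export
categorize_compatibility <- function(context, pam_catalog,
                                     config = pipeline_config()) {
  acc <- unique(context$accession)
  stopifnot(length(acc) == 1L)
  links <- link_arrays_to_systems(context, config)
  arrays <- context[context$kind == "array", , drop = FALSE]

  cats <- list()
  soft <- FALSE

  # categories 1 and 2: same PAM on different-subtype repeat clusters
  rc <- unique(arrays$repeat_cluster_id)
  pc <- pam_catalog[match(rc, pam_catalog$cluster_id), , drop = FALSE]
  pc$cluster_id <- rc
  pc <- pc[!is.na(pc$PAM) & trim_pam(pc$PAM) != "", , drop = FALSE]
  if (nrow(pc) >= 2L) {
    for (i in seq_len(nrow(pc) - 1L)) {
      for (j in (i + 1L):nrow(pc)) {
        if (pc$subtype[i] == pc$subtype[j]) next
        same <- trim_pam(pc$PAM[i]) == trim_pam(pc$PAM[j])
        if (!same) {
          if (iupac_compatible(trim_pam(pc$PAM[i]), trim_pam(pc$PAM[j]))) {
            soft <- TRUE
          }
          next
        }
        modes <- targeting_mode(c(pc$subtype[i], pc$subtype[j]))
        cat_id <- if (all(modes == "DNA")) "1"
                  else if ("RNA" %in% modes && "DNA" %in% modes) "2"
                  else NA_character_
        if (!is.na(cat_id)) {
          cats[[length(cats) + 1L]] <- list(
            category = cat_id,
            subtype_pair = paste(sort(c(pc$subtype[i], pc$subtype[j])),
                                 collapse = "/"),
            shared_pam = trim_pam(pc$PAM[i]),
            evidence = sprintf("clusters %s,%s share PAM %s",
                               pc$cluster_id[i], pc$cluster_id[j],
                               trim_pam(pc$PAM[i])))
        }
      }
    }
  }

  # category 3: >=2 subtypes of cas clusters linked to one repeat cluster,
  # with no other arrays linked to those cas clusters
  if (nrow(links)) {
    for (r in unique(links$repeat_cluster_id)) {
      lr <- links[links$repeat_cluster_id == r, , drop = FALSE]
      subs <- unique(lr$cas_subtype)
      if (length(subs) < 2L) next
      other <- links$repeat_cluster_id != r &
        links$cas_subtype %in% subs
      if (any(other)) next
      pam <- pam_catalog$PAM[match(r, pam_catalog$cluster_id)]
      cats[[length(cats) + 1L]] <- list(
        category = "3",
        subtype_pair = paste(sort(subs), collapse = "/"),
        shared_pam = if (!is.na(pam)) trim_pam(pam) else NA_character_,
        evidence = sprintf("repeat cluster %s linked to cas clusters: %s",
                           r, paste(sort(subs), collapse = ",")))
    }
  }

  if (!length(cats)) {
    res <- list(accession = acc, category = "none",
                subtype_pair = NA_character_, shared_pam = NA_character_,
                evidence = character(0), soft_pam_match = soft)
  } else {
    prec <- vapply(cats, function(x) x$category, "")
    best <- cats[[order(-as.integer(prec))[1]]]
    res <- list(accession = acc, category = best$category,
                subtype_pair = best$subtype_pair,
                shared_pam = best$shared_pam,
                evidence = vapply(cats, function(x) x$evidence, ""),
                soft_pam_match = soft)
  }
  class(res) <- "compatibility_call"
  res
}

# TRUE when two equal-length IUPAC motifs are position-wise intersecting
iupac_compatible <- function(a, b) {
  if (nchar(a) != nchar(b) || nchar(a) == 0) return(FALSE)
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  all(vapply(seq_along(ca), function(i) {
    length(intersect(IUPAC_SETS[[ca[i]]], IUPAC_SETS[[cb[i]]])) > 0
  }, logical(1)))
}

#' @export
print.compatibility_call <- function(x, ...) {
  cat(sprintf("%s: category %s (%s; PAM %s)\n", x$accession, x$category,
              x$subtype_pair %||% "-", x$shared_pam %||% "-"))
  invisible(x)
}

#' Compatibility calls over a cohort of genomes
#'
#' @param context context table of many genomes.
#' @param pam_catalog see [categorize_compatibility()].
#' @param config [pipeline_config()].
#' @return data.frame: `accession`, `subtypes`, `PAM`, `category`.
#' @export
categorize_cohort <- function(context, pam_catalog,
                              config = pipeline_config()) {
  accs <- unique(context$accession)
  rows <- lapply(accs, function(a) {
    cc <- categorize_compatibility(
      context[context$accession == a, , drop = FALSE], pam_catalog, config)
    data.frame(accession = a,
               subtypes = cc$subtype_pair %||% NA_character_,
               PAM = cc$shared_pam %||% NA_character_,
               category = cc$category, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' PAM-call frequency by subtype and acquisition-module presence
#'
#' Restricted to repeat clusters with at least `min_hits` unique
#' protospacers, reports per group the fraction of clusters with a PAM call.
#' Type III clusters are split by cas1-cas2 presence (acquisition module),
#' taken from the context table's cas clusters linked to each repeat
#' cluster.
#'
#' @param clusters cluster table with `cluster_id`, `subtype`,
#'   `n_protospacers`.
#' @param pam_catalog data.frame with `cluster_id`, `PAM`.
#' @param context optional context table used to resolve cas1-cas2 presence
#'   for type III clusters.
#' @param min_hits minimum unique protospacers (default 25; clusters must
#'   exceed this).
#' @param config [pipeline_config()].
#' @return data.frame: `group`, `n_clusters`, `n_with_pam`, `fraction`.
#' @export
pam_frequency_by_acquisition <- function(clusters, pam_catalog,
                                         context = NULL, min_hits = 25L,
                                         config = pipeline_config()) {
  cl <- clusters[clusters$n_protospacers > min_hits, , drop = FALSE]
  if (!nrow(cl)) {
    return(data.frame(group = character(), n_clusters = integer(),
                      n_with_pam = integer(), fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  grp <- cl$subtype
  if (!is.null(context)) {
    links <- link_arrays_to_systems(context, config)
    cas <- context[context$kind == "cas_cluster", , drop = FALSE]
    is3 <- major_type(cl$subtype) == "III"
    for (i in which(is3)) {
      lr <- links[links$repeat_cluster_id == cl$cluster_id[i], , drop = FALSE]
      own <- cas[cas$accession %in% lr$accession &
                   cas$subtype %in% lr$cas_subtype &
                   major_type(cas$subtype) == "III", , drop = FALSE]
      has12 <- nrow(own) > 0 && any(own$has_cas1_cas2 == 1)
      grp[i] <- paste0(cl$subtype[i],
                       if (has12) " (cas1-2 present)" else " (cas1-2 absent)")
    }
  }
  with_pam <- cl$cluster_id %in%
    pam_catalog$cluster_id[!is.na(pam_catalog$PAM) & pam_catalog$PAM != ""]
  out <- lapply(sort(unique(grp)), function(g) {
    sel <- grp == g
    data.frame(group = g, n_clusters = sum(sel),
               n_with_pam = sum(with_pam & sel),
               fraction = sum(with_pam & sel) / sum(sel),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
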