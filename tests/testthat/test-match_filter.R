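cfg <- pipeline_config()

one_spacer <- function(seq, id = "sp1", genus = "Escherichia") {
  data.frame(spacer_id = id, sequence = seq,
             repeat_seq = "GTGTTCCCCGCGCCAGCGGGGATAAACCG",
             host_accession = "A1", genus = genus, array_id = "a1",
             position_in_array = 1L, subtype = "I-E", cas_genes = "I-E",
             stringsAsFactors = FALSE)
}

one_subject <- function(seq, id = "ctg1") {
  data.frame(subject_id = id, sequence = seq, source_class = "nucleotide_db",
             length = nchar(seq), stringsAsFactors = FALSE)
}

test_that("exact, mismatched and seedless spacers behave as specified", {
  set.seed(201)
  sp <- random_dna(1, 32, 0.5)
  ctx <- paste0(random_dna(1, 100, 0.5), sp, random_dna(1, 100, 0.5))
  h <- find_hits(one_spacer(sp), one_subject(ctx), cfg)
  expect_equal(nrow(h), 1)
  expect_equal(h$matched_fraction, 1.0)
  expect_equal(h$s_start, 100L)
  expect_equal(h$s_end, 132L)
  expect_equal(h$strand, "+")

  # two substitutions far apart -> 30/32
  mut <- sp
  substr(mut, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                               substr(sp, 3, 3))[1]
  substr(mut, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                 substr(sp, 30, 30))[1]
  ctx2 <- paste0(random_dna(1, 80, 0.5), mut, random_dna(1, 80, 0.5))
  h2 <- find_hits(one_spacer(sp), one_subject(ctx2), cfg)
  expect_equal(h2$n_ident, 30L)
  expect_equal(h2$matched_fraction, 30 / 32)

  # no shared 10-mer -> no hits (all-A spacer vs all-C subject)
  h3 <- find_hits(one_spacer(strrep("AT", 16)),
                  one_subject(strrep("GC", 200)), cfg)
  expect_equal(nrow(h3), 0)
})

test_that("matcher reports every sliding-window location at <= 3 substitutions", {
  set.seed(202)
  subject <- random_dna(1, 2000, 0.5)
  sp <- random_dna(1, 32, 0.5)
  # plant copies at various identities and strands
  plant <- function(s, seq, at) paste0(substr(s, 1, at),
                                       seq, substr(s, at + nchar(seq) + 1,
                                                   nchar(s)))
  m1 <- sp
  substr(m1, 5, 5) <- "A"; substr(m1, 20, 20) <- "C"
  subject <- plant(subject, sp, 100)
  subject <- plant(subject, m1, 600)
  subject <- plant(subject, rc(sp), 1200)
  oracle <- sliding_window_hits(sp, subject, max_sub = 3)
  h <- find_hits(one_spacer(sp), one_subject(subject), cfg)
  for (i in seq_len(nrow(oracle))) {
    expect_true(any(h$s_start == oracle$s_start[i] &
                      h$s_end == oracle$s_end[i] &
                      h$strand == oracle$strand[i]),
                info = sprintf("oracle hit at %d (%s) missing",
                               oracle$s_start[i], oracle$strand[i]))
  }
})

test_that("matching and flank extraction are strand-symmetric", {
  set.seed(203)
  sp <- random_dna(1, 32, 0.5)
  ctx <- paste0(random_dna(1, 90, 0.5), sp, random_dna(1, 90, 0.5))
  fwd <- extract_flanks(find_hits(one_spacer(sp), one_subject(ctx), cfg),
                        one_subject(ctx), cfg)
  rev_subj <- one_subject(rc(ctx))
  rev <- extract_flanks(find_hits(one_spacer(sp), rev_subj, cfg),
                        rev_subj, cfg)
  expect_equal(nrow(rev), nrow(fwd))
  expect_equal(rev$strand, ifelse(fwd$strand == "+", "-", "+"))
  expect_equal(rev$upstream_flank, fwd$upstream_flank)
  expect_equal(rev$downstream_flank, fwd$downstream_flank)
  expect_equal(rev$s_start, nchar(ctx) - fwd$s_end)
})

test_that("flank extraction follows the protospacer-orientation convention", {
  set.seed(204)
  subj <- one_subject(random_dna(1, 400, 0.5))
  hit <- data.frame(spacer_id = "sp1", subject_id = "ctg1",
                    s_start = 100L, s_end = 132L, strand = "+",
                    n_ident = 32L, q_len = 32L, matched_fraction = 1,
                    stringsAsFactors = FALSE)
  fl <- extract_flanks(hit, subj, cfg)
  expect_equal(fl$upstream_flank, substr(subj$sequence, 78, 100))
  expect_equal(fl$downstream_flank, substr(subj$sequence, 133, 155))

  hit$strand <- "-"
  flm <- extract_flanks(hit, subj, cfg)
  expect_equal(flm$upstream_flank, rc(substr(subj$sequence, 133, 155)))
  expect_equal(flm$downstream_flank, rc(substr(subj$sequence, 78, 100)))

  # hit starting at position 5: upstream left-padded with 18 N
  hit$strand <- "+"; hit$s_start <- 5L; hit$s_end <- 37L
  fle <- extract_flanks(hit, subj, cfg)
  expect_equal(nchar(fle$upstream_flank), 23L)
  expect_equal(substr(fle$upstream_flank, 1, 18), strrep("N", 18))
})

test_that("array-hit rule fires above exactly 13 identities", {
  rep_seq <- "GTGTTCCCCGCGCCAGCGGGGATAAACCG"
  # flank equal to the repeat's first 23 nt -> 23 identities
  expect_true(is_array_hit(substr(rep_seq, 1, 23), strrep("N", 23),
                           rep_seq, cfg))
  # reverse complement of the repeat is also recognised
  expect_true(is_array_hit(rc(substr(rep_seq, 1, 23)), strrep("N", 23),
                           rep_seq, cfg))
  # exactly 14 identities -> true; exactly 13 -> false (N never matches)
  f14 <- paste0(substr(rep_seq, 1, 14), strrep("N", 9))
  f13 <- paste0(substr(rep_seq, 1, 13), strrep("N", 10))
  expect_equal(max(ends_free_identities(f14, rep_seq)$n_ident,
                   ends_free_identities(f14, rc(rep_seq))$n_ident), 14L)
  expect_equal(max(ends_free_identities(f13, rep_seq)$n_ident,
                   ends_free_identities(f13, rc(rep_seq))$n_ident), 13L)
  expect_true(is_array_hit(f14, strrep("N", 23), rep_seq, cfg))
  expect_false(is_array_hit(f13, strrep("N", 23), rep_seq, cfg))
})

test_that("random flanks rarely trigger the array-hit rule", {
  set.seed(205)
  n <- 1000
  flanks <- random_dna(n, 23, 0.5)
  reps <- random_dna(n, 29, 0.5)
  ident <- pmax(ends_free_identities(flanks, reps)$n_ident,
                ends_free_identities(flanks, rc(reps))$n_ident)
  expect_gte(mean(ident <= cfg$array_identity_min), 0.95)
  # the null sits far below the threshold on average
  expect_lt(mean(ident), 11)
})

test_that("two-step filter applies the published rules", {
  rec <- rbind(one_spacer(strrep("ACGT", 8), "s1"),
               one_spacer(strrep("TTGA", 8), "s2"),
               one_spacer(strrep("GCCA", 8), "s3", genus = "Bacillus"))
  base <- data.frame(
    spacer_id = c("s1", "s2", "s3"),
    subject_id = c("ctg1", "ctg1", "ctg1"),
    s_start = c(0L, 100L, 200L), s_end = c(32L, 132L, 232L),
    strand = "+", n_ident = c(30L, 26L, 26L), q_len = 32L,
    matched_fraction = c(30, 26, 26) / 32,
    in_array = FALSE, stringsAsFactors = FALSE)
  kept <- apply_two_step_filter(base, rec, cfg)
  # 0.9375 -> step 1; 0.8125 kept in step 2 only with a same-genus co-hit
  expect_equal(kept$kept_step[kept$spacer_id == "s1"], "step1")
  expect_equal(kept$kept_step[kept$spacer_id == "s2"], "step2")
  expect_false("s3" %in% kept$spacer_id)  # other genus: no step-1 co-hit

  # without the step-1 co-hit the 0.8125 hit is dropped
  alone <- base[2, ]
  expect_equal(nrow(apply_two_step_filter(alone, rec, cfg)), 0)

  # array hits and short spacers are removed
  arr <- base; arr$in_array <- c(TRUE, FALSE, FALSE)
  expect_false("s1" %in% apply_two_step_filter(arr, rec, cfg)$spacer_id)
  short <- rec; short$sequence[1] <- strrep("ACGT", 6)  # 24 nt < 27
  expect_false("s1" %in% apply_two_step_filter(base, short, cfg)$spacer_id)

  # missing genus: step-2 candidate stays step-1-only, with a message
  nog <- rec; nog$genus[2] <- NA
  expect_message(k2 <- apply_two_step_filter(base, nog, cfg), "genus")
  expect_false("s2" %in% k2$spacer_id)
})

test_that("step 2 never introduces new subjects and the filter is monotone", {
  u <- universe_fixture()
  run <- pipeline_fixture()
  s1 <- unique(run$kept$subject_id[run$kept$kept_step == "step1"])
  expect_true(all(unique(run$kept$subject_id) %in% s1))
  expect_gt(sum(run$kept$kept_step == "step2"), 0)

  stricter <- pipeline_config(step1_frac = 0.95)
  kept95 <- apply_two_step_filter(run$hits, u$records, stricter)
  key <- function(k) paste(k$spacer_id, k$subject_id, k$s_start, k$strand)
  expect_true(all(key(kept95) %in% key(run$kept)))
})
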