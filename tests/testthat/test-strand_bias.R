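cfg <- pipeline_config()

test_that("primary target selection prefers nucleotide-db then length", {
  subjects <- data.frame(
    subject_id = c("meta5k", "db3k", "db6k", "db6k2"),
    sequence = "", source_class = c("metagenome", "nucleotide_db",
                                    "nucleotide_db", "nucleotide_db"),
    length = c(5000L, 3000L, 6000L, 6000L), stringsAsFactors = FALSE)
  hit <- function(ids) data.frame(spacer_id = "s", subject_id = ids,
                                  stringsAsFactors = FALSE)
  expect_equal(select_primary_target(hit("meta5k"), subjects), "meta5k")
  # database hit beats a longer metagenome hit
  expect_equal(select_primary_target(hit(c("meta5k", "db3k")), subjects),
               "db3k")
  # within the class, the longest subject
  expect_equal(select_primary_target(hit(c("db3k", "db6k")), subjects),
               "db6k")
  # ties broken lexicographically
  expect_equal(select_primary_target(hit(c("db6k2", "db6k")), subjects),
               "db6k")
})

test_that("the ORF scanner recovers planted frames on both strands", {
  set.seed(501)
  orf_seq <- spacerscope:::random_orf_seq(300, 0.5)
  # start-codon-free flanks so the planted frame is recovered exactly
  subj_plus <- paste0(strrep("C", 120), orf_seq, strrep("C", 120))
  found <- find_orfs("ctg", subj_plus)
  expect_true(any(found$start == 120 & found$end == 420 &
                    found$strand == "+"))

  subj_minus <- paste0(strrep("C", 75), rc(orf_seq), strrep("C", 75))
  found_m <- find_orfs("ctg", subj_minus)
  expect_true(any(found_m$start == 75 & found_m$end == 375 &
                    found_m$strand == "-"))
  expect_true(all((found_m$end - found_m$start) %% 3 == 0))

  # a 60-nt frame is below the length threshold
  short <- paste0(strrep("C", 90), "ATG", strrep("CAG", 18), "TAA",
                  strrep("C", 90))
  found_s <- find_orfs("ctg", short)
  expect_false(any(found_s$start == 90 & found_s$strand == "+"))
})

test_that("strand classification follows the base-pairing convention", {
  orfs <- data.frame(subject_id = "ctg", start = 100L, end = 400L,
                     strand = "+", stringsAsFactors = FALSE)
  hit <- data.frame(spacer_id = "s", subject_id = "ctg", s_start = 200L,
                    s_end = 232L, strand = "-", stringsAsFactors = FALSE)
  # ORF on +, spacer matches -: crRNA can base-pair the mRNA -> coding
  expect_equal(classify_strand(hit, orfs, "forward"), "coding")
  hit$strand <- "+"
  expect_equal(classify_strand(hit, orfs, "forward"), "template")
  # reverse array orientation flips the transcribed strand
  expect_equal(classify_strand(hit, orfs, "reverse"), "coding")
  # unresolved orientation -> undetermined
  expect_equal(classify_strand(hit, orfs, "undetermined"), "undetermined")
  # boundary-straddling or intergenic protospacers -> undetermined
  hit2 <- hit; hit2$s_start <- 390L; hit2$s_end <- 422L
  expect_equal(classify_strand(hit2, orfs, "forward"), "undetermined")
  hit3 <- hit; hit3$s_start <- 500L; hit3$s_end <- 532L
  expect_equal(classify_strand(hit3, orfs, "forward"), "undetermined")
  # overlapping genes covering the hit -> undetermined rather than counted
  orfs2 <- rbind(orfs, data.frame(subject_id = "ctg", start = 150L,
                                  end = 450L, strand = "-"))
  expect_equal(classify_strand(hit, orfs2, "forward"), "undetermined")
})

test_that("classification is invariant under reverse-complementing the subject", {
  set.seed(502)
  n <- 600L
  orfs <- data.frame(subject_id = "ctg", start = 120L, end = 420L,
                     strand = "+", stringsAsFactors = FALSE)
  hit <- data.frame(spacer_id = "s", subject_id = "ctg", s_start = 200L,
                    s_end = 232L, strand = "-", stringsAsFactors = FALSE)
  # flip everything to the other strand of the contig
  orfs_rc <- transform(orfs, start = n - end, end = n - start, strand = "-")
  hit_rc <- transform(hit, s_start = n - s_end, s_end = n - s_start,
                      strand = "+")
  expect_equal(classify_strand(hit, orfs, "forward"),
               classify_strand(hit_rc, orfs_rc, "forward"))
})

test_that("the exact binomial test matches enumeration and symmetry", {
  expect_equal(binomial_strand_test(5, 5), 1.0)
  expect_equal(binomial_strand_test(15, 5), 0.04139, tolerance = 1e-4)
  for (n in c(1, 2, 7, 13, 20, 25)) {
    for (x in 0:n) {
      expect_equal(binomial_strand_test(x, n - x),
                   brute_force_binom_p(x, n), tolerance = 1e-12,
                   info = sprintf("x=%d n=%d", x, n))
      expect_equal(binomial_strand_test(x, n - x),
                   binomial_strand_test(n - x, x), tolerance = 1e-14)
    }
  }
})

test_that("grouped summaries recover planted biases and control errors", {
  set.seed(503)
  make_cohort <- function(frac, n, subtype) {
    list(records = data.frame(spacer_id = sprintf("%s_%04d", subtype, 1:n),
                              subtype = subtype, genus = "G",
                              cas_genes = subtype, stringsAsFactors = FALSE),
         calls = data.frame(spacer_id = sprintf("%s_%04d", subtype, 1:n),
                            subject_id = "c",
                            call = ifelse(runif(n) < frac, "coding",
                                          "template"),
                            stringsAsFactors = FALSE))
  }
  co <- make_cohort(0.65, 500, "III-B")
  out <- group_strand_bias(co$calls, co$records, "subtype", alpha = 0.01)
  expect_lt(abs(out$fraction_coding - 0.65), 0.05)
  expect_true(out$significant)

  # planted 50%, n = 100: not significant at alpha 0.01
  co2 <- make_cohort(0.5, 100, "I-E")
  out2 <- group_strand_bias(co2$calls, co2$records, "subtype", alpha = 0.01)
  expect_false(out2$significant)

  # undetermined calls are excluded; all-undetermined groups are omitted
  calls <- rbind(co$calls,
                 data.frame(spacer_id = "x1", subject_id = "c",
                            call = "undetermined"))
  recs <- rbind(co$records,
                data.frame(spacer_id = "x1", subtype = "IV", genus = "G",
                           cas_genes = "IV"))
  out3 <- group_strand_bias(calls, recs, "subtype")
  expect_false("IV" %in% out3$group)
  expect_equal(out3$n_coding + out3$n_template, 500L)

  expect_error(group_strand_bias(co$calls, co$records, "nope"),
               "unknown group key")
})

test_that("cas-context grouping splits by co-occurring effector types", {
  recs <- data.frame(spacer_id = c("a", "b"), subtype = c("I-B", "I-B"),
                     genus = "G", cas_genes = c("I-B,III-A", "I-B"),
                     stringsAsFactors = FALSE)
  calls <- data.frame(spacer_id = c("a", "b"), subject_id = "c",
                      call = c("coding", "template"),
                      stringsAsFactors = FALSE)
  out <- group_strand_bias(calls, recs, "subtype_cas_context")
  expect_equal(nrow(out), 2)
  expect_true(any(grepl("I\\+III", out$group)))
})
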