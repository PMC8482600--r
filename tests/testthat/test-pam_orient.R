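cfg <- pipeline_config()

test_that("consensus flanks take the per-position plurality with N ties", {
  cf <- consensus_flanks(c("AAG", "AAG", "AAC"), c("TTT", "TTT", "TTT"))
  expect_equal(cf$upstream, "AAG")
  expect_equal(cf$downstream, "TTT")
  # two hits tied A vs C at position 3 -> N there
  cf2 <- consensus_flanks(c("AAA", "AAC"), c("GG", "GG"))
  expect_equal(cf2$upstream, "AAN")
  # single hit: consensus equals its flanks
  cf3 <- consensus_flanks("ACGT", "TGCA")
  expect_equal(cf3$upstream, "ACGT")
  # N observations are excluded before counting
  cf4 <- consensus_flanks(c("AN", "AN", "AC"), c("T", "T", "T"))
  expect_equal(cf4$upstream, "AC")
})

test_that("profiles weigh each spacer once and use the GC background", {
  # duplicate identical consensus pairs collapse to one protospacer
  pairs <- data.frame(upstream = c("AAG", "AAG", "CCG"),
                      downstream = c("TTT", "TTT", "GGA"),
                      stringsAsFactors = FALSE)
  prof <- build_profile(pairs, 0.5, "c1")
  expect_equal(prof$n_protospacers, 2L)
  expect_true(all(colSums(prof$upstream$counts) <= 2))
  # GC 0.7 background
  prof7 <- build_profile(pairs, 0.7, "c1")
  expect_equal(unname(prof7$background),
               c(0.15, 0.35, 0.35, 0.15))
})

test_that("information content matches closed forms and the multiset oracle", {
  allA <- matrix(c(10, 0, 0, 0), 4, 1,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(information_content(allA), 2.0, tolerance = 1e-12)

  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  matched <- matrix(c(5, 5, 5, 5), 4, 1,
                    dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(information_content(matched, bg), 0, tolerance = 1e-12)

  bg7 <- c(A = 0.15, C = 0.35, G = 0.35, T = 0.15)
  allG <- matrix(c(0, 0, 12, 0), 4, 1,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(information_content(allG, bg7), log2(1 / 0.35),
               tolerance = 1e-12)

  set.seed(401)
  for (i in 1:20) {
    obs <- sample(c("A", "C", "G", "T", "N"), 30, replace = TRUE,
                  prob = c(.3, .25, .2, .15, .1))
    counts <- matrix(as.integer(table(factor(obs, c("A","C","G","T")))),
                     4, 1, dimnames = list(c("A","C","G","T"), NULL))
    expect_equal(information_content(counts, bg7),
                 brute_force_ic(obs, as.list(bg7)), tolerance = 1e-12)
  }
})

test_that("orientation calls recover planted sides and respect the gate", {
  set.seed(402)
  # type I, upstream PAM, 50 protospacers -> forward
  pr <- simulate_cluster_flanks(50, list(motif = "AAG", side = "upstream"),
                                0.9, 0.5)
  prof <- build_profile(pr, 0.5, "c1")
  oc <- predict_orientation(prof, "I-E", cfg)
  expect_equal(oc$orientation, "forward")
  expect_equal(oc$source, "pam_based")

  # stored reverse-complemented: reverse, and flipping restores the profile
  flipped <- data.frame(upstream = rc(pr$downstream),
                        downstream = rc(pr$upstream))
  prof_r <- build_profile(flipped, 0.5, "c1")
  oc_r <- predict_orientation(prof_r, "I-E", cfg)
  expect_equal(oc_r$orientation, "reverse")
  back <- build_profile(spacerscope:::flip_consensus_pairs(flipped), 0.5, "c1")
  expect_equal(back$upstream$counts, prof$upstream$counts)
  expect_equal(call_pam(back, "I-E", cfg)$motif, call_pam(prof, "I-E", cfg)$motif)

  # type II: downstream PAM side
  pr2 <- simulate_cluster_flanks(50, list(motif = "GGT", side = "downstream"),
                                 0.9, 0.5)
  oc2 <- predict_orientation(build_profile(pr2, 0.5, "c2"), "II-A", cfg)
  expect_equal(oc2$orientation, "forward")

  # fewer than 10 unique protospacers: always undetermined
  pr3 <- simulate_cluster_flanks(8, list(motif = "AAG", side = "upstream"),
                                 1.0, 0.5)
  oc3 <- predict_orientation(build_profile(pr3, 0.5, "c3"), "I-E", cfg)
  expect_equal(oc3$orientation, "undetermined")

  # type III: external orientation passed through
  oc4 <- predict_orientation(prof, "III-B", cfg,
                             external_orientation = "forward")
  expect_equal(oc4$orientation, "forward")
  expect_equal(oc4$source, "external")
})

test_that("PAM calls respect thresholds, size gate and motif span", {
  set.seed(403)
  pr <- simulate_cluster_flanks(50, list(motif = "AAG", side = "upstream"),
                                0.9, 0.5)
  prof <- build_profile(pr, 0.5, "c1")
  pc <- call_pam(prof, "I-E", cfg)
  expect_equal(pc$motif, "AAG")
  expect_equal(pc$flagged_positions, c(-3L, -2L, -1L))
  expect_equal(pc$side, "upstream")

  # no planted signal -> no call
  pr0 <- simulate_cluster_flanks(50, NULL, gc = 0.5)
  expect_null(call_pam(build_profile(pr0, 0.5, "c0"), "I-E", cfg))

  # single conserved position -> below the minimum PAM size, no call
  pr1 <- simulate_cluster_flanks(50, list(motif = "G", side = "upstream"),
                                 1.0, 0.5)
  expect_null(call_pam(build_profile(pr1, 0.5, "c1"), "I-E", cfg))

  # gapped motif: conserved at -4 and -1 renders N at unflagged interior
  up <- random_dna(50, 23, 0.5)
  substr(up, 20, 20) <- "T"   # -4
  substr(up, 23, 23) <- "G"   # -1
  prg <- data.frame(upstream = up, downstream = random_dna(50, 23, 0.5))
  pcg <- call_pam(build_profile(prg, 0.5, "cg"), "I-E", cfg)
  expect_equal(pcg$motif, "TNNG")
  expect_equal(pcg$flagged_positions, c(-4L, -1L))
})

test_that("IUPAC rendering uses the cumulative-0.8 rule", {
  expect_equal(motif_to_iupac(c(A = 1, C = 0, G = 0, T = 0)), "A")
  expect_equal(motif_to_iupac(c(A = 0.5, C = 0, G = 0.05, T = 0.45)), "W")
  expect_equal(motif_to_iupac(c(A = 0.3, C = 0.3, G = 0.3, T = 0.1)), "V")
  expect_equal(motif_to_iupac(c(A = 0.85, C = 0.05, G = 0.05, T = 0.05)), "A")
  expect_equal(motif_to_iupac(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)), "N")
})

test_that("repeat ends are compared position-wise with the PAM", {
  pam <- structure(list(cluster_id = "c", side = "upstream",
                        flagged_positions = c(-3L, -2L, -1L), motif = "AAG",
                        freqs = NULL), class = "pam_call")
  # repeat ending ...CAG: -3 C vs PAM A mismatches, -2/-1 match
  cmp <- compare_repeat_pam("GTGTTCCCCGCGCCAGCGGGGATAACAG", pam)
  expect_equal(cmp$position, c(-3L, -2L, -1L))
  expect_equal(cmp$match, c(FALSE, TRUE, TRUE))
  # repeat end identical to the PAM: all match
  cmp2 <- compare_repeat_pam("GTGTTCCCCGCGCCAGCGGGGATAAAAG", pam)
  expect_true(all(cmp2$match))
  # I-E-style repeat ending ...G with AAG PAM: match at -1
  cmp3 <- compare_repeat_pam("GTGTTCCCCGCGCCAGCGGGGATAACCG", pam)
  expect_true(cmp3$match[cmp3$position == -1])
  # downstream PAM compared with the first repeat bases
  pam_dn <- structure(list(cluster_id = "c", side = "downstream",
                           flagged_positions = c(1L, 2L), motif = "GG",
                           freqs = NULL), class = "pam_call")
  cmp4 <- compare_repeat_pam("GGTTTCCCCGCGCCAGCGGGGATAAACC", pam_dn)
  expect_equal(cmp4$match, c(TRUE, TRUE))
  # IUPAC containment: W covers A and T
  pam_w <- structure(list(cluster_id = "c", side = "upstream",
                          flagged_positions = c(-2L, -1L), motif = "WG",
                          freqs = NULL), class = "pam_call")
  cmp5 <- compare_repeat_pam("CCCCCCCCCCCCCCCCCCCCCCCCCCTG", pam_w)
  expect_equal(cmp5$match, c(TRUE, TRUE))
})

test_that("the crRNA handle motif is detected near the repeat 3' end", {
  expect_equal(detect_crRNA_handle_motif("GTGTTCCCCGCGCCAGCGGGGATTGAAAC"),
               list(found = TRUE, offset = 0L))
  # one mismatch tolerated
  expect_true(detect_crRNA_handle_motif("GTGTTCCCCGCGCCAGCGGGGATTGAAAT")$found)
  expect_false(detect_crRNA_handle_motif("GTGTTCCCCGCGCCAGCGGGGATTGAAAT",
                                         max_mismatch = 0)$found)
  # offset from the 3' end
  expect_equal(detect_crRNA_handle_motif("GTGTTCCCCGCGCCAGCATTGAAACGG")$offset,
               2L)
  set.seed(404)
  expect_false(detect_crRNA_handle_motif("GTGTTCCCCGCGCCAGCGGGGACCCCCAC")$found)
})
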