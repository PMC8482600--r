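cfg <- pipeline_config()

ctx_row <- function(acc, kind, start, end, array_id = NA, rc = NA,
                    subtype = NA, has12 = NA) {
  data.frame(accession = acc, kind = kind, start = start, end = end,
             array_id = as.character(array_id),
             repeat_cluster_id = as.character(rc),
             subtype = as.character(subtype),
             has_cas1_cas2 = as.integer(has12), stringsAsFactors = FALSE)
}

test_that("arrays link to cas clusters by edge-to-edge distance", {
  ctx <- rbind(
    ctx_row("G1", "array", 10000, 12000, "a1", "r1"),
    ctx_row("G1", "cas_cluster", 20000, 30000, subtype = "I-B", has12 = 1),
    ctx_row("G1", "cas_cluster", 38000, 40000, subtype = "III-A", has12 = 0),
    ctx_row("G1", "cas_cluster", 34000, 36500, subtype = "I-E", has12 = 1))
  links <- link_arrays_to_systems(ctx, cfg)
  # 8 kb: linked; 26 kb: not; 22.5 kb (I-E): linked -> two links
  expect_setequal(links$cas_subtype, c("I-B", "I-E"))
  expect_equal(links$distance[links$cas_subtype == "I-B"], 8000L)
})

test_that("compatibility categories follow the three organisations", {
  pams <- data.frame(cluster_id = c("r1", "r2"),
                     subtype = c("I-B", "III-B"),
                     PAM = c("TTC", "TTC"), stringsAsFactors = FALSE)
  # category 2: DNA- and RNA-targeting clusters, distinct repeats, same PAM
  ctx2 <- rbind(
    ctx_row("G1", "array", 10000, 12000, "a1", "r1"),
    ctx_row("G1", "cas_cluster", 13000, 18000, subtype = "I-B", has12 = 1),
    ctx_row("G1", "array", 200000, 202000, "a2", "r2"),
    ctx_row("G1", "cas_cluster", 203000, 208000, subtype = "III-B",
            has12 = 0))
  cc <- categorize_compatibility(ctx2, pams, cfg)
  expect_equal(cc$category, "2")
  expect_equal(cc$shared_pam, "TTC")
  expect_equal(cc$subtype_pair, "I-B/III-B")

  # category 1: two DNA-targeting subtypes sharing the PAM
  pams1 <- data.frame(cluster_id = c("r1", "r2"), subtype = c("I-B", "I-C"),
                      PAM = c("TTC", "TTC"), stringsAsFactors = FALSE)
  cc1 <- categorize_compatibility(ctx2, pams1, cfg)
  expect_equal(cc1$category, "1")

  # category 3: one repeat cluster linked to two subtypes, no other arrays
  ctx3 <- rbind(
    ctx_row("G2", "array", 50000, 52000, "a1", "r9"),
    ctx_row("G2", "cas_cluster", 30000, 42000, subtype = "I-B", has12 = 1),
    ctx_row("G2", "cas_cluster", 55000, 62000, subtype = "III-A", has12 = 0))
  cc3 <- categorize_compatibility(
    ctx3, data.frame(cluster_id = "r9", subtype = "I-B", PAM = "TTC"), cfg)
  expect_equal(cc3$category, "3")

  # distinct PAMs: no category
  pams_n <- data.frame(cluster_id = c("r1", "r2"), subtype = c("I-E", "I-F"),
                       PAM = c("AAG", "CC"), stringsAsFactors = FALSE)
  ccn <- categorize_compatibility(ctx2, pams_n, cfg)
  expect_equal(ccn$category, "none")
})

test_that("category 3 takes precedence and requires exclusive linkage", {
  # same repeat cluster near two subtypes AND a shared PAM with another
  # cluster: category 3 outranks 2
  pams <- data.frame(cluster_id = c("r1", "r2"),
                     subtype = c("I-B", "III-B"),
                     PAM = c("TTC", "TTC"), stringsAsFactors = FALSE)
  ctx <- rbind(
    ctx_row("G1", "array", 50000, 52000, "a1", "r1"),
    ctx_row("G1", "cas_cluster", 40000, 48000, subtype = "I-B", has12 = 1),
    ctx_row("G1", "cas_cluster", 55000, 62000, subtype = "III-B", has12 = 0),
    ctx_row("G1", "array", 500000, 502000, "a2", "r2"))
  cc <- categorize_compatibility(ctx, pams, cfg)
  expect_equal(cc$category, "3")
  expect_gt(length(cc$evidence), 1)

  # a second array linked to one of those cas clusters breaks category 3
  ctx_broken <- rbind(ctx[1:3, ],
                      ctx_row("G1", "array", 60000, 62000, "a3", "r2"))
  cc_b <- categorize_compatibility(ctx_broken, pams, cfg)
  expect_false(cc_b$category == "3")
})

test_that("category calls are invariant under relabeling and translation", {
  pams <- data.frame(cluster_id = "r9", subtype = "I-B", PAM = "TTC",
                     stringsAsFactors = FALSE)
  ctx <- rbind(
    ctx_row("G2", "array", 50000, 52000, "a1", "r9"),
    ctx_row("G2", "cas_cluster", 30000, 42000, subtype = "I-B", has12 = 1),
    ctx_row("G2", "cas_cluster", 55000, 62000, subtype = "III-A", has12 = 0))
  base <- categorize_compatibility(ctx, pams, cfg)
  shifted <- ctx
  shifted$start <- shifted$start + 1234567L
  shifted$end <- shifted$end + 1234567L
  relabeled <- shifted
  relabeled$array_id[1] <- "zz9"
  cc <- categorize_compatibility(relabeled, pams, cfg)
  expect_equal(cc$category, base$category)
  expect_equal(cc$subtype_pair, base$subtype_pair)
})

test_that("planted compatibility cohorts are classified perfectly", {
  cohort <- generate_compatibility_cohort(n_per_class = 5)
  calls <- categorize_cohort(cohort$context, cohort$pam_catalog, cfg)
  m <- match(calls$accession, cohort$truth$accession)
  expect_equal(calls$category, cohort$truth$category[m])
  # precision and recall per category
  for (cat in c("1", "2", "3")) {
    tp <- sum(calls$category == cat & cohort$truth$category[m] == cat)
    expect_equal(tp / sum(calls$category == cat), 1.0)
    expect_equal(tp / sum(cohort$truth$category == cat), 1.0)
  }
})

test_that("PAM frequency splits type III clusters by acquisition module", {
  clusters <- data.frame(
    cluster_id = sprintf("r%d", 1:10),
    subtype = c(rep("I-E", 3), rep("III-B", 6), "I-B"),
    n_protospacers = c(40, 40, 20, rep(40, 6), 40),
    stringsAsFactors = FALSE)
  # PAMs planted only in cas1-2-lacking III clusters (and the I-E ones)
  pam_catalog <- data.frame(cluster_id = c("r1", "r2", "r4", "r5", "r6"),
                            PAM = c("AAG", "AAG", "TTC", "TTC", "TTC"),
                            stringsAsFactors = FALSE)
  ctx <- do.call(rbind, lapply(1:10, function(i) rbind(
    ctx_row(sprintf("G%d", i), "array", 10000, 12000, "a", sprintf("r%d", i)),
    ctx_row(sprintf("G%d", i), "cas_cluster", 14000, 20000,
            subtype = clusters$subtype[i],
            has12 = if (i %in% 4:6) 0L else 1L))))
  tab <- pam_frequency_by_acquisition(clusters, pam_catalog, ctx,
                                      min_hits = 25, config = cfg)
  # the 20-protospacer cluster is excluded by the >25 gate
  expect_equal(sum(tab$n_clusters), 9)
  expect_equal(tab$n_clusters[tab$group == "I-E"], 2)
  lacks <- tab[grepl("absent", tab$group), ]
  has <- tab[grepl("present", tab$group), ]
  expect_equal(lacks$fraction, 1.0)
  expect_equal(has$fraction, 0.0)
  expect_gte(lacks$fraction - has$fraction, 0.8)
  expect_equal(tab$fraction[tab$group == "I-E"], 1.0)
})
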