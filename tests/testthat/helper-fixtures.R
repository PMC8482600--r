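# Shared fixtures. The default synthetic universe and its pipeline run are
# expensive (~0.5 min together), so they are computed once per test session
# and cached.

.fixture_env <- new.env(parent = emptyenv())

universe_fixture <- function() {
  if (is.null(.fixture_env$universe)) {
    .fixture_env$universe <- generate_universe(generator_params(rng_seed = 11))
  }
  .fixture_env$universe
}

pipeline_fixture <- function() {
  if (is.null(.fixture_env$run)) {
    u <- universe_fixture()
    .fixture_env$run <- run_pipeline(u$records, u$subjects, orfs = u$orfs,
                                     references = u$references)
  }
  .fixture_env$run
}

# small spacer record table built in code
toy_records <- function() {
  data.frame(
    spacer_id = c("s1", "s2", "s3"),
    sequence = c("ATGCATGCATGCATGCATGCATGCATGCATGC",
                 "GGGTTTAAACCCGGGTTTAAACCCGGGTTTAA",
                 "ACACACACGTGTGTGTACACACACGTGTGTGT"),
    repeat_seq = rep("GTGTTCCCCGCGCCAGCGGGGATAAACCG", 3),
    host_accession = c("ACC1", "ACC1", "ACC2"),
    genus = c("Escherichia", "Escherichia", "Bacillus"),
    array_id = c("a1", "a1", "a2"),
    position_in_array = 1:3,
    subtype = c("I-E", "I-E", "I-B"),
    cas_genes = c("I-E", "I-E", "I-B"),
    stringsAsFactors = FALSE
  )
}
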