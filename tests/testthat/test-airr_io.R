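test_that("a toy AIRR TSV parses identically, with ids in input order", {
  df <- toy_rearrangements(3)
  path <- write_toy_tsv(df)
  set <- read_rearrangements(path)
  expect_equal(nrow(set), 3L)
  expect_identical(set$sequence_id, df$sequence_id)
  expect_identical(set$junction, df$junction)
  expect_identical(set$productive, df$productive)
  expect_identical(set$duplicate_count, df$duplicate_count)
  expect_identical(provenance(set)$source, path)
})

test_that("missing optional columns receive documented defaults", {
  df <- toy_rearrangements(2)
  df$duplicate_count <- NULL
  df$productive <- NULL
  set <- read_rearrangements(write_toy_tsv(df))
  expect_identical(set$duplicate_count, c(1L, 1L))
  # junction is in frame and stop-free, so productivity is inferred TRUE
  expect_identical(set$productive, c(TRUE, TRUE))

  # out-of-frame junction infers non-productive
  df2 <- toy_rearrangements(1, junction = "TGTGCTAGATG", junction_aa = NA)
  df2$productive <- NULL
  set2 <- read_rearrangements(write_toy_tsv(df2))
  expect_false(set2$productive)
})

test_that("schema violations are reported by column name", {
  df <- toy_rearrangements(2)
  df$junction <- NULL
  df$junction_aa <- NULL
  expect_error(read_rearrangements(write_toy_tsv(df)), "junction")

  df3 <- toy_rearrangements(2)
  df3$sequence <- NULL
  expect_error(read_rearrangements(write_toy_tsv(df3)), "sequence")
})

test_that("duplicate sequence_id errors only in strict mode", {
  df <- toy_rearrangements(2, sequence_id = c("dup", "dup"))
  path <- write_toy_tsv(df)
  expect_warning(read_rearrangements(path), "duplicate")
  expect_error(read_rearrangements(path, strict = TRUE), "duplicate")
})

test_that("multi-assignment calls keep the first allele and are flagged", {
  df <- toy_rearrangements(2, v_call = c("IGHV4-34*01,IGHV4-34*02",
                                         "IGHV4-34*01"))
  set <- read_rearrangements(write_toy_tsv(df))
  expect_identical(set$v_call, c("IGHV4-34*01", "IGHV4-34*01"))
  expect_identical(set$v_call_multi, c(TRUE, FALSE))
})

test_that("collapse merges key-identical records and sums counts", {
  df <- toy_rearrangements(2, duplicate_count = c(1L, 2L))
  out <- collapse_transcripts(df)
  expect_equal(nrow(out), 1L)
  expect_equal(out$duplicate_count, 3L)
  expect_identical(out$sequence_id, "s01")   # first-seen id retained

  # same transcript, different isotype: kept distinct
  df2 <- toy_rearrangements(2, c_call = c("IGHM", "IGHG"))
  expect_equal(nrow(collapse_transcripts(df2)), 2L)

  # all-distinct input unchanged
  df3 <- toy_rearrangements(3,
    sequence = paste0(c("AAA", "CCC", "GGG"), VH434$sequence_nt))
  expect_equal(nrow(collapse_transcripts(df3)), 3L)
})

test_that("collapse conserves total duplicate_count and is idempotent", {
  set.seed(401)
  for (rep in 1:20) {
    n <- sample(1:40, 1)
    df <- toy_rearrangements(
      n,
      sequence = paste0("SEQ", sample(5, n, replace = TRUE)),
      c_call = sample(c("IGHM", "IGHG"), n, replace = TRUE),
      duplicate_count = sample(1:9, n, replace = TRUE)
    )
    once <- collapse_transcripts(df)
    expect_equal(sum(once$duplicate_count), sum(df$duplicate_count))
    twice <- collapse_transcripts(once)
    expect_equal(strip_set(twice), strip_set(once))
  }
})

test_that("filter and collapse commute when keys cover the filter fields", {
  set.seed(402)
  n <- 30
  df <- toy_rearrangements(
    n,
    sequence = paste0("SEQ", sample(6, n, replace = TRUE)),
    v_call = sample(c("IGHV4-34*01", "IGHV3-23*01"), n, replace = TRUE),
    c_call = sample(c("IGHM", "IGHG"), n, replace = TRUE),
    duplicate_count = sample(1:5, n, replace = TRUE)
  )
  keys <- c("sequence", "v_call", "c_call", "subject_id", "subset_label")
  a <- filter_rearrangements(collapse_transcripts(df, keys),
                             v_gene = "IGHV4-34", isotype = "IGHM")
  b <- collapse_transcripts(
    filter_rearrangements(df, v_gene = "IGHV4-34", isotype = "IGHM"), keys)
  expect_equal(strip_set(a), strip_set(b))
})

test_that("filtering applies all supplied predicates at the gene level", {
  df <- toy_rearrangements(
    4,
    v_call = c("IGHV4-34*01", "IGHV4-34*02", "IGHV3-23*01", "IGHV4-34*01"),
    c_call = c("IGHM", "IGHM", "IGHM", "IGHG"),
    productive = c(TRUE, FALSE, TRUE, TRUE)
  )
  out <- filter_rearrangements(df, v_gene = "IGHV4-34", isotype = "IGHM")
  expect_identical(out$sequence_id, c("s01", "s02"))

  # non-productive records retained unless asked otherwise
  expect_true(any(!out$productive))
  out2 <- filter_rearrangements(df, v_gene = "IGHV4-34", isotype = "IGHM",
                                productive_only = TRUE)
  expect_identical(out2$sequence_id, "s01")

  # no predicates: identity
  expect_identical(tibble::as_tibble(filter_rearrangements(df)),
                   tibble::as_tibble(df))

  expect_error(filter_rearrangements(df, isotype = "IGX"), "isotype")
})

test_that("read-write-read round trip preserves every core field", {
  sim <- simulate_repertoire(simulation_config(n_sequences = 40, seed = 9,
                                               shm_rate = 0.01))
  p1 <- tempfile(fileext = ".tsv")
  write_rearrangements(sim$set, p1)
  r1 <- read_rearrangements(p1)
  p2 <- tempfile(fileext = ".tsv")
  write_rearrangements(r1, p2)
  r2 <- read_rearrangements(p2)
  core <- c("sequence_id", "sequence", "locus", "v_call", "j_call", "c_call",
            "junction", "junction_aa", "productive", "duplicate_count",
            "subject_id", "subset_label")
  expect_identical(as.data.frame(r1)[core], as.data.frame(r2)[core])
  expect_identical(as.data.frame(sim$set)[core], as.data.frame(r1)[core])
})

test_that("germline FASTA + bounds round trip and validate", {
  fa <- tempfile(fileext = ".fasta")
  js <- tempfile(fileext = ".json")
  write_germline_reference(REFS, fa, js)
  back <- read_germline_reference(fa, js)
  expect_identical(names(back), names(REFS))
  expect_identical(back[["IGHV4-34"]]$sequence_nt, VH434$sequence_nt)
  # frame-1 translation matches the stored protein
  expect_identical(back[["IGHV4-34"]]$sequence_aa,
                   translate_nt(back[["IGHV4-34"]]$sequence_nt))

  # bounds past the protein end are rejected
  bad <- VH434$region_bounds
  bad$FR3 <- c(67L, 99L)
  expect_error(germline_reference("IGHV4-34*01", VH434$sequence_nt, bad),
               "exceeds")
})

test_that("packaged germline fixtures load and carry the hotspot residues", {
  fa <- system.file("extdata", "synthetic_ighv_family.fasta",
                    package = "vh4rep")
  js <- system.file("extdata", "synthetic_ighv_family_bounds.json",
                    package = "vh4rep")
  refs <- read_germline_reference(fa, js)
  g <- refs[["IGHV4-34"]]
  expect_identical(substr(g$sequence_aa, 24, 26), "AVY")
  expect_identical(substr(g$sequence_aa, 6, 7), "QW")
  expect_identical(substr(g$sequence_aa, 57, 59), "NHS")
  expect_identical(substr(g$sequence_aa, 90, 92), "KLS")
  expect_identical(region_of(g, c(25L, 58L, 91L)), c("FR1", "CDR2", "FR3"))
})
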