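test_that("identical junctions with shared V/J form one clone", {
  df <- toy_rearrangements(2)
  gr <- group_clones(df)
  expect_equal(nrow(gr), 1L)
  expect_equal(gr$size, 2L)
  expect_identical(sort(gr$member_ids[[1]]), c("s01", "s02"))
})

test_that("single linkage chains near-identical junctions into one clone", {
  # pairwise distance 1/12 between consecutive junctions; ends differ by 2/12
  j <- c("TGTGCTAGATGG", "TGTGCTAAATGG", "TGTGCTAACTGG")
  df <- toy_rearrangements(3, junction = j, junction_aa = NA)
  gr <- group_clones(df, distance_threshold = 0.15, linkage = "single")
  expect_equal(nrow(gr), 1L)
  # complete linkage at a threshold below the diameter splits the chain
  grc <- group_clones(df, distance_threshold = 0.15, linkage = "complete")
  expect_gt(nrow(grc), 1L)
})

test_that("V/J/length partition boundaries are never crossed", {
  df <- toy_rearrangements(2, j_call = c("IGHJ4*01", "IGHJ6*01"))
  expect_equal(nrow(group_clones(df)), 2L)
  df2 <- toy_rearrangements(2, junction = c("TGTGCTAGATGG", "TGTGCTAGAAGATGG"),
                            junction_aa = NA)
  expect_equal(nrow(group_clones(df2)), 2L)
})

test_that("records without a junction are excluded and tallied", {
  df <- toy_rearrangements(3, junction = c("TGTGCTAGATGG", NA, "TGTGCTAGATGG"),
                           junction_aa = NA)
  gr <- group_clones(df)
  expect_equal(attr(gr, "n_excluded"), 1L)
  expect_equal(sum(gr$size), 2L)
})

test_that("grouping equals the brute-force oracle on random instances", {
  set.seed(515)
  for (rep in 1:15) {
    n <- sample(2:120, 1)
    df <- toy_rearrangements(
      n,
      junction = random_junction_family(n),
      v_call = sample(c("IGHV4-34*01", "IGHV3-23*01"), n, replace = TRUE),
      j_call = sample(c("IGHJ4*01", "IGHJ6*01"), n, replace = TRUE),
      junction_aa = NA
    )
    gr <- group_clones(df, 0.15, "single")
    asg <- attr(gr, "assignments")
    got <- canonical_partition(asg$sequence_id, asg$clone_id)
    want <- canonical_partition(df$sequence_id, brute_force_clones(df, 0.15))
    expect_identical(got, want)
  }
})

test_that("grouping output partitions the non-excluded input", {
  set.seed(516)
  n <- 80
  df <- toy_rearrangements(n, junction = random_junction_family(n),
                           junction_aa = NA)
  gr <- group_clones(df)
  asg <- attr(gr, "assignments")
  expect_setequal(asg$sequence_id, df$sequence_id)
  expect_equal(anyDuplicated(asg$sequence_id), 0L)
  expect_equal(sum(gr$size), n)
})

test_that("raising the threshold never increases the clone count", {
  set.seed(517)
  n <- 60
  df <- toy_rearrangements(n, junction = random_junction_family(n),
                           junction_aa = NA)
  counts <- vapply(c(0, 0.05, 0.1, 0.2, 0.4, 1),
                   function(t) nrow(group_clones(df, t)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("clone sampling is seed-reproducible and size-correct", {
  set.seed(518)
  n <- 300
  df <- toy_rearrangements(n, junction = random_junction_family(n),
                           junction_aa = NA)
  gr <- group_clones(df)
  s1 <- sample_groups(gr, 20, seed = 7)
  s2 <- sample_groups(gr, 20, seed = 7)
  expect_identical(s1$clone_id, s2$clone_id)
  expect_equal(nrow(s1), 20L)
  s3 <- sample_groups(gr, 20, seed = 8)
  expect_false(identical(s1$clone_id, s3$clone_id))
  expect_equal(nrow(sample_groups(gr, 10 * nrow(gr), seed = 1)), nrow(gr))
  expect_error(sample_groups(gr, 0, seed = 1), "n must be")
})

test_that("connectivity graphs respect clone boundaries and the edge rule", {
  df1 <- toy_rearrangements(1)
  gr1 <- group_clones(df1)
  g1 <- build_connectivity_graph(gr1, df1)
  expect_equal(igraph::vcount(g1), 1L)
  expect_equal(igraph::ecount(g1), 0L)

  df3 <- toy_rearrangements(3)   # identical junctions -> triangle
  gr3 <- group_clones(df3)
  g3 <- build_connectivity_graph(gr3, df3)
  expect_equal(igraph::ecount(g3), 3L)

  # two clones (different J): no inter-clone edges
  df4 <- toy_rearrangements(4, j_call = rep(c("IGHJ4*01", "IGHJ6*01"), 2))
  gr4 <- group_clones(df4)
  g4 <- build_connectivity_graph(gr4, df4)
  cl <- igraph::V(g4)$clone_id
  ends <- igraph::as_edgelist(g4)
  m <- match(ends, igraph::V(g4)$name)
  expect_true(all(cl[m[seq_len(nrow(ends))]] ==
                  cl[m[nrow(ends) + seq_len(nrow(ends))]]))

  # edge rule 0 only connects identical junctions
  j <- c("TGTGCTAGATGG", "TGTGCTAAATGG", "TGTGCTAGATGG")
  df5 <- toy_rearrangements(3, junction = j, junction_aa = NA)
  gr5 <- group_clones(df5)
  g5 <- build_connectivity_graph(gr5, df5, edge_rule = 0L)
  expect_equal(igraph::ecount(g5), 1L)

  # exports are written
  gml <- tempfile(fileext = ".graphml")
  ets <- tempfile(fileext = ".tsv")
  export_graph(g3, gml, ets)
  expect_true(file.exists(gml) && file.exists(ets))
})

test_that("top-clone enumeration ranks heavy chains by distinct CDR3s", {
  v1 <- VH434$sequence_nt
  v2 <- paste0("T", substr(v1, 2, nchar(v1)))   # distinct heavy chain
  # interiors chosen so every junction has a distinct amino-acid CDR3
  juncs <- c("TGTGCTAGATGG", "TGTCGTCATTGG", "TGTGGTTTTTGG",
             "TGTTTTCATTGG", "TGTCATGGTTGG")
  aas <- translate_nt(juncs)
  df <- toy_rearrangements(
    7,
    sequence = c(paste0(v1, juncs), paste0(v2, juncs[1:2])),
    junction = c(juncs, juncs[1:2]),
    junction_aa = c(aas, aas[1:2]),
    c_call = c(rep("IGHM", 4), "IGHA", "IGHM", "IGHM")
  )
  tab <- enumerate_top_clones(df, 10)
  expect_equal(tab$rank, c(1L, 2L))
  expect_equal(tab$n_clones, c(5L, 2L))
  expect_equal(tab$IGHM[1], 4L)
  expect_equal(tab$IGHA[1], 1L)
  # per-isotype counts reconcile with unique (heavy chain, CDR3, isotype)
  expect_equal(sum(tab$IGHM) + sum(tab$IGHA), 7L)

  # all-identical records give a single row with one clone
  df1 <- toy_rearrangements(3)
  tab1 <- enumerate_top_clones(df1, 10)
  expect_equal(nrow(tab1), 1L)
  expect_equal(tab1$n_clones, 1L)

  expect_error(enumerate_top_clones(df, 0), "n must be")
})
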