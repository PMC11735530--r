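# Oracle for silent/replacement calls: direct lookup in the standard
# genetic code, independent of call_mutations().
aa_of <- function(codon) unname(Biostrings::GENETIC_CODE[[codon]])

edit_nt <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

test_that("germline aligned to itself yields an empty profile", {
  al <- align_to_germline(VH434$sequence_nt, VH434)
  expect_equal(al$identity, 1)
  prof <- call_mutations(al, VH434)
  expect_equal(prof$n_replacement, 0L)
  expect_equal(prof$n_silent, 0L)
  expect_false(prof$has_indel)
  expect_equal(classify_idiotope(prof), "GERMLINE")
})

test_that("a single substitution is called at the known coordinate", {
  # position 100 (codon 34, third base): germline codon and a synonymous edit
  codon <- substr(VH434$sequence_nt, 100, 102)
  expect_identical(codon, "CAA")                 # Gln
  mutant <- edit_nt(VH434$sequence_nt, 102, "G") # CAG, still Gln
  expect_identical(aa_of("CAG"), aa_of("CAA"))   # oracle: synonymous
  prof <- call_mutations(align_to_germline(mutant, VH434), VH434)
  expect_equal(nrow(prof$mutations), 1L)
  expect_equal(prof$mutations$nt_position, 102L)
  expect_equal(prof$mutations$aa_position, 34L)
  expect_true(prof$mutations$is_silent)
  expect_equal(prof$n_silent, 1L)
  expect_equal(classify_idiotope(prof), "SILENT_ONLY")
})

test_that("multi-hit codons are translated as whole codons", {
  # codon 40 spans nt 118..120 (ACT); two substitutions changing the residue
  codon <- substr(VH434$sequence_nt, 118, 120)
  expect_identical(codon, "ACT")
  mutant <- edit_nt(edit_nt(VH434$sequence_nt, 118, "G"), 119, "A")
  new_codon <- paste0("GA", substr(codon, 3, 3))
  expect_false(aa_of(new_codon) == aa_of(codon))  # oracle: replacement
  prof <- call_mutations(align_to_germline(mutant, VH434), VH434)
  expect_equal(nrow(prof$mutations), 2L)
  expect_true(all(!prof$mutations$is_silent))
  expect_true(all(prof$mutations$observed_aa == aa_of(new_codon)))
})

test_that("an engineered V25 replacement classifies as AVY in FR1", {
  # codon 25 (nt 73..75) is GTT = Val; GTT -> GAT = Asp
  expect_identical(substr(VH434$sequence_nt, 73, 75), "GTT")
  mutant <- edit_nt(VH434$sequence_nt, 74, "A")
  expect_identical(aa_of("GAT"), "D")
  prof <- call_mutations(align_to_germline(mutant, VH434), VH434)
  expect_equal(prof$mutations$aa_position, 25L)
  expect_equal(prof$mutations$region, "FR1")
  expect_false(prof$mutations$is_silent)
  expect_equal(classify_idiotope(prof), "AVY")
})

test_that("a KLS replacement plus a silent change elsewhere is KLS", {
  # codon 91 (nt 271..273) CTT -> CCT (Leu -> Pro); silent at codon 34
  mutant <- edit_nt(edit_nt(VH434$sequence_nt, 272, "C"), 102, "G")
  prof <- call_mutations(align_to_germline(mutant, VH434), VH434)
  expect_equal(prof$n_replacement, 1L)
  expect_equal(prof$n_silent, 1L)
  expect_equal(classify_idiotope(prof), "KLS")
})

test_that("a 3-nt deletion flags the profile and blocks classification", {
  mutant <- paste0(substr(VH434$sequence_nt, 1, 45),
                   substr(VH434$sequence_nt, 49, 294))
  prof <- call_mutations(align_to_germline(mutant, VH434), VH434)
  expect_true(prof$has_indel)
  expect_equal(classify_idiotope(prof), "UNCLASSIFIABLE")
})

test_that("ambiguous bases at mismatch sites are skipped and tallied", {
  mutant <- edit_nt(VH434$sequence_nt, 74, "N")
  prof <- call_mutations(align_to_germline(mutant, VH434), VH434)
  expect_equal(nrow(prof$mutations), 0L)
  expect_equal(prof$n_ambiguous, 1L)
})

test_that("alignment identity below the floor raises a misassignment error", {
  scrambled <- paste(rep("ACGT", 74), collapse = "")
  expect_error(align_to_germline(scrambled, VH434), "identity")
})

# --- precedence properties on synthetic profiles ---

make_profile <- function(aa_positions, silent) {
  m <- tibble::tibble(
    nt_position = 3L * aa_positions, germline_nt = "A", observed_nt = "G",
    aa_position = aa_positions, germline_aa = "K", observed_aa = "R",
    is_silent = silent, region = NA_character_
  )
  structure(list(mutations = m, n_replacement = sum(!silent),
                 n_silent = sum(silent), n_ambiguous = 0L,
                 has_indel = FALSE), class = "mutation_profile")
}

test_that("classification matches a brute-force precedence oracle", {
  scheme <- hotspot_scheme()
  oracle <- function(pos, silent) {
    repl <- pos[!silent]
    if (any(repl %in% 24:26)) "AVY"
    else if (any(repl %in% 57:59)) "NHS"
    else if (any(repl %in% 90:92)) "KLS"
    else if (length(repl)) "OTHER_REPLACEMENT"
    else if (any(silent)) "SILENT_ONLY"
    else "GERMLINE"
  }
  set.seed(777)
  for (i in 1:300) {
    k <- sample(0:6, 1)
    pos <- if (k) sample(98, k) else integer(0)
    silent <- if (k) sample(c(TRUE, FALSE), k, replace = TRUE) else logical(0)
    prof <- make_profile(pos, silent)
    expect_identical(classify_idiotope(prof, scheme), oracle(pos, silent))
  }
})

test_that("classification ignores mutation-list order", {
  prof <- make_profile(c(91L, 40L, 58L), c(FALSE, TRUE, FALSE))
  shuffled <- prof
  shuffled$mutations <- prof$mutations[c(3, 1, 2), ]
  expect_identical(classify_idiotope(prof), classify_idiotope(shuffled))
})

test_that("adding an AVY replacement never lowers the category precedence", {
  precedence <- c(AVY = 1, NHS = 2, KLS = 3, OTHER_REPLACEMENT = 4,
                  SILENT_ONLY = 5, GERMLINE = 6)
  set.seed(778)
  for (i in 1:100) {
    k <- sample(0:4, 1)
    pos <- if (k) sample(98, k) else integer(0)
    silent <- if (k) sample(c(TRUE, FALSE), k, replace = TRUE) else logical(0)
    before <- classify_idiotope(make_profile(pos, silent))
    after <- classify_idiotope(make_profile(c(pos, 25L), c(silent, FALSE)))
    expect_lte(precedence[after], precedence[before])
  }
})

test_that("zero-mutation profiles are GERMLINE under any scheme", {
  empty <- make_profile(integer(0), logical(0))
  expect_identical(classify_idiotope(empty, hotspot_scheme()), "GERMLINE")
  alt <- hotspot_scheme(avy_positions = c(10L, 11L), nhs_positions = 50L,
                        kls_positions = 80L, include_aux_in_avy = TRUE)
  expect_identical(classify_idiotope(empty, alt), "GERMLINE")
})

test_that("the auxiliary Q6/W7 pair triggers AVY only when enabled", {
  prof <- make_profile(6L, FALSE)
  expect_identical(classify_idiotope(prof, hotspot_scheme()),
                   "OTHER_REPLACEMENT")
  expect_identical(
    classify_idiotope(prof, hotspot_scheme(include_aux_in_avy = TRUE)),
    "AVY")
})

test_that("category tables partition their inputs with fractions summing to 1", {
  df <- tibble::tibble(
    subject_id = "A",
    idiotope_category = rep(c("GERMLINE", "AVY", "NHS"), c(4, 4, 2))
  )
  tab <- summarize_categories(df)
  expect_equal(sum(tab$count), 10L)
  expect_equal(tab$fraction[tab$category == "GERMLINE"], 0.4)
  expect_equal(tab$fraction[tab$category == "AVY"], 0.4)
  expect_equal(tab$fraction[tab$category == "NHS"], 0.2)
  expect_equal(sum(tab$fraction), 1, tolerance = 1e-9)

  two <- dplyr::bind_rows(df, tibble::tibble(
    subject_id = "B", idiotope_category = rep("KLS", 5)))
  tab2 <- summarize_categories(two)
  sums <- tapply(tab2$fraction, tab2$group, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_equal(sum(tab2$count), 15L)
})

test_that("profiling recovers an implanted category mix exactly", {
  mix <- c(GERMLINE = 0.3, AVY = 0.3, NHS = 0.2, KLS = 0.2)
  cfg <- simulation_config(
    n_sequences = 200, seed = 31, ighv4_34_fraction = 1,
    v_usage = c("IGHV4-34" = 1),
    clone_size_law = list(law = "zipf", alpha = 1.5, max_size = 1L),
    category_mix = mix, shm_rate = 0, nonproductive_fraction = 0
  )
  sim <- simulate_repertoire(cfg)
  prof <- profile_repertoire(sim$set, REFS)
  truth <- sim$truth$category[match(prof$sequence_id, sim$truth$sequence_id)]
  expect_identical(prof$idiotope_category, truth)
  tab <- summarize_categories(prof)
  expect_equal(tab$count[match(names(mix), tab$category)],
               as.integer(table(factor(truth, levels = names(mix)))))
})
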