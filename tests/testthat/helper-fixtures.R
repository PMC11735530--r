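# Shared fixture builders. All fixtures are constructed in code; the only
# on-disk fixtures are written into tempfiles by the tests themselves.

REFS <- synthetic_germline_set()
VH434 <- REFS[["IGHV4-34"]]

# A minimal rearrangement tibble; any column can be overridden.
toy_rearrangements <- function(n = 3, ...) {
  junction <- "TGTGCTAGATGG"            # C-A-R-W
  df <- tibble::tibble(
    sequence_id = sprintf("s%02d", seq_len(n)),
    sequence = paste0(VH434$sequence_nt, junction),
    locus = "IGH",
    v_call = "IGHV4-34*01",
    j_call = "IGHJ4*01",
    c_call = "IGHM",
    junction = junction,
    junction_aa = "CARW",
    productive = TRUE,
    duplicate_count = 1L,
    subject_id = "S1",
    subset_label = "CD27+IgM+"
  )
  over <- list(...)
  for (col in names(over)) df[[col]] <- over[[col]]
  df
}

write_toy_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  out <- df
  for (col in names(out)) {
    if (is.logical(out[[col]])) out[[col]] <- ifelse(out[[col]], "T", "F")
  }
  readr::write_tsv(out, path, na = "", progress = FALSE)
  path
}

# Random junction strings clustered around a few ancestors, so that clonal
# grouping instances contain both related and unrelated sequences.
random_junction_family <- function(n, lengths = c(12L, 15L, 18L)) {
  n_anc <- max(2L, n %/% 5L)
  anc <- vapply(seq_len(n_anc), function(i) {
    L <- sample(lengths, 1)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  vapply(seq_len(n), function(i) {
    a <- sample(anc, 1)
    bases <- strsplit(a, "")[[1]]
    k <- sample(0:3, 1)
    if (k > 0) {
      pos <- sample(length(bases), min(k, length(bases)))
      bases[pos] <- vapply(bases[pos], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
    }
    paste(bases, collapse = "")
  }, character(1))
}

# Drop set class and provenance so record content can be compared directly.
strip_set <- function(x) {
  x <- tibble::as_tibble(x)
  attr(x, "provenance") <- NULL
  x
}

# Canonical form of a clone partition: list of sorted member-id vectors,
# ordered by their first member, so two partitions compare with identical().
canonical_partition <- function(sequence_id, clone_label) {
  parts <- split(sequence_id, clone_label)
  parts <- lapply(parts, sort)
  parts <- parts[order(vapply(parts, `[`, "", 1L))]
  unname(parts)
}

# Independent single-linkage oracle: all-pairs normalized Hamming distance
# plus breadth-first transitive closure, with the same (v, j, length)
# pre-partition as the clonal-grouping contract. No igraph, no hclust.
brute_force_clones <- function(df, threshold) {
  v <- sub("\\*.*$", "", sub(",.*$", "", df$v_call))
  j <- sub("\\*.*$", "", sub(",.*$", "", df$j_call))
  key <- paste(v, j, nchar(df$junction))
  label <- character(nrow(df))
  next_id <- 0L
  for (k in unique(key)) {
    idx <- which(key == k)
    juncs <- df$junction[idx]
    n <- length(idx)
    L <- nchar(juncs[1])
    adj <- matrix(FALSE, n, n)
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        d <- sum(strsplit(juncs[a], "")[[1]] != strsplit(juncs[b], "")[[1]]) / L
        adj[a, b] <- d <= threshold
      }
    }
    seen <- rep(FALSE, n)
    for (start in seq_len(n)) {
      if (seen[start]) next
      next_id <- next_id + 1L
      queue <- start
      seen[start] <- TRUE
      while (length(queue)) {
        cur <- queue[1]
        queue <- queue[-1]
        label[idx[cur]] <- sprintf("bf%04d", next_id)
        nb <- which(adj[cur, ] & !seen)
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  label
}
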