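# Clonal inference: group rearrangements into clones by junction
# relatedness, build clonal connectivity graphs, subsample clone groups
# reproducibly, and enumerate the top expanded heavy chains.

#' Group rearrangements into clones by junction distance
#'
#' Records are first partitioned by (V gene, J gene, junction length); within
#' each partition, clones are clusters under normalized junction Hamming
#' distance at `distance_threshold`. Single linkage takes the connected
#' components of the threshold graph (distance <= threshold); complete
#' linkage cuts a complete-linkage dendrogram at the threshold. Records with
#' a missing junction are excluded and tallied in the `n_excluded` attribute.
#'
#' Clone ids are deterministic: clones are ordered by (v_gene, j_gene,
#' junction_length, lexicographically smallest member sequence_id) and
#' labelled sequentially.
#'
#' @param set Rearrangement set.
#' @param distance_threshold Normalized Hamming threshold in `[0, 1]`
#'   (default 0.15, the conventional junction-identity cutoff).
#' @param linkage "single" (default) or "complete".
#' @return Tibble of clone groups (clone_id, v_gene, j_gene,
#'   junction_length, size, member_ids list-column, and dominant_category
#'   when an `idiotope_category` column is present), with an `assignments`
#'   attribute mapping sequence_id to clone_id.
#' @export
group_clones <- function(set, distance_threshold = 0.15,
                         linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  if (distance_threshold < 0 || distance_threshold > 1) {
    stop("distance_threshold must be in [0, 1]")
  }
  df <- tibble::as_tibble(set)
  ok <- !is.na(df$junction) & nchar(df$junction) > 0L
  n_excluded <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0L) {
    out <- tibble::tibble(clone_id = character(), v_gene = character(),
                          j_gene = character(), junction_length = integer(),
                          size = integer(), member_ids = list())
    attr(out, "assignments") <- tibble::tibble(sequence_id = character(),
                                               clone_id = character())
    attr(out, "n_excluded") <- n_excluded
    return(out)
  }
  v_gene <- gene_from_call(df$v_call)
  j_gene <- gene_from_call(df$j_call)
  jlen <- nchar(df$junction)
  part_key <- paste(v_gene, j_gene, jlen, sep = "\r")

  clone_rows <- list()
  for (key in unique(part_key)) {
    idx <- which(part_key == key)
    memb <- cluster_partition(df$junction[idx], distance_threshold, linkage)
    for (cl in unique(memb)) {
      sel <- idx[memb == cl]
      ids <- sort(df$sequence_id[sel])
      row <- tibble::tibble(
        v_gene = v_gene[sel[1]],
        j_gene = j_gene[sel[1]],
        junction_length = jlen[sel[1]],
        size = length(sel),
        member_ids = list(ids)
      )
      if ("idiotope_category" %in% names(df)) {
        cats <- df$idiotope_category[sel]
        cats <- cats[!is.na(cats)]
        row$dominant_category <- if (length(cats)) {
          tt <- sort(table(cats), decreasing = TRUE)
          # plurality; ties broken by fixed category order
          winners <- names(tt)[tt == max(tt)]
          CLONE_CATEGORIES[CLONE_CATEGORIES %in% winners][1]
        } else NA_character_
      }
      clone_rows[[length(clone_rows) + 1L]] <- row
    }
  }
  groups <- dplyr::bind_rows(clone_rows)
  first_member <- vapply(groups$member_ids, `[`, "", 1L)
  ord <- order(groups$v_gene, groups$j_gene, groups$junction_length,
               first_member, method = "radix")
  groups <- groups[ord, , drop = FALSE]
  groups$clone_id <- sprintf("clone%05d", seq_len(nrow(groups)))
  groups <- groups[, c("clone_id", setdiff(names(groups), "clone_id"))]
  assignments <- tibble::tibble(
    sequence_id = unlist(groups$member_ids),
    clone_id = rep(groups$clone_id, groups$size)
  )
  attr(groups, "assignments") <- assignments
  attr(groups, "n_excluded") <- n_excluded
  groups
}

# Cluster one (v, j, length) partition; returns integer cluster labels.
cluster_partition <- function(junctions, threshold, linkage) {
  n <- length(junctions)
  if (n == 1L) return(1L)
  L <- nchar(junctions[1])
  d <- hamming_matrix(junctions) / L
  if (linkage == "single") {
    adj <- d <= threshold
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    igraph::components(g)$membership
  } else {
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    stats::cutree(hc, h = threshold)
  }
}

#' Subsample clone groups reproducibly
#'
#' Uniform sample without replacement of `min(n, nrow(groups))` clone
#' groups. Sampling is over groups, not sequences; an identical seed yields
#' an identical sample on every platform (Mersenne-Twister contract).
#'
#' @param groups Clone-group tibble from [group_clones()].
#' @param n Number of groups to draw (>= 1).
#' @param seed Integer seed.
#' @return Subsampled clone-group tibble.
#' @export
sample_groups <- function(groups, n, seed) {
  if (n < 1L) stop("n must be >= 1")
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  k <- min(n, nrow(groups))
  idx <- sample.int(nrow(groups), k, replace = FALSE)
  out <- groups[idx, , drop = FALSE]
  attr(out, "assignments") <- NULL
  out
}

#' Build a clonal connectivity graph
#'
#' One node per member sequence, carrying clone_id, idiotope category,
#' isotype and duplicate count for plotting parity; undirected edges connect
#' same-clone members whose junctions differ by at most `edge_rule`
#' nucleotides. Singleton clones appear as isolated nodes; edges never cross
#' clones.
#'
#' @param groups Clone-group tibble from [group_clones()].
#' @param set The rearrangement set the groups were built from.
#' @param edge_rule Maximum junction Hamming distance (nt) for an edge
#'   (default 1).
#' @return An igraph object.
#' @export
build_connectivity_graph <- function(groups, set, edge_rule = 1L) {
  df <- tibble::as_tibble(set)
  rownames_df <- df$sequence_id
  nodes <- tibble::tibble(
    name = unlist(groups$member_ids),
    clone_id = rep(groups$clone_id, groups$size)
  )
  m <- match(nodes$name, df$sequence_id)
  nodes$category <- if ("idiotope_category" %in% names(df)) {
    df$idiotope_category[m]
  } else NA_character_
  nodes$isotype <- if ("c_call" %in% names(df)) df$c_call[m] else NA_character_
  nodes$size <- df$duplicate_count[m]
  edges <- list()
  for (r in seq_len(nrow(groups))) {
    ids <- groups$member_ids[[r]]
    if (length(ids) < 2L) next
    juncs <- df$junction[match(ids, df$sequence_id)]
    d <- hamming_matrix(juncs)
    pair <- which(upper.tri(d) & d <= edge_rule, arr.ind = TRUE)
    if (nrow(pair)) {
      edges[[length(edges) + 1L]] <- tibble::tibble(
        from = ids[pair[, 1]], to = ids[pair[, 2]],
        junction_distance = d[pair]
      )
    }
  }
  edges <- if (length(edges)) dplyr::bind_rows(edges) else {
    tibble::tibble(from = character(), to = character(),
                   junction_distance = integer())
  }
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = as.data.frame(nodes))
}

#' Export a connectivity graph as GraphML and an edge-list TSV
#'
#' @param graph igraph object from [build_connectivity_graph()].
#' @param graphml_path Output GraphML path (skipped if NULL).
#' @param edges_path Output edge-list TSV path (skipped if NULL).
#' @return Invisibly, the written paths.
#' @export
export_graph <- function(graph, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(graph, graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) {
    el <- igraph::as_data_frame(graph, what = "edges")
    readr::write_tsv(tibble::as_tibble(el), edges_path, progress = FALSE)
  }
  invisible(c(graphml = graphml_path, edges = edges_path))
}

#' Enumerate the top expanded heavy chains
#'
#' Unique heavy-chain V-region amino-acid sequences ranked by the number of
#' distinct CDR3s (junction_aa) observed with them — the signature of a
#' germline heavy chain recurring across independent rearrangements. Ties
#' are broken lexicographically by sequence. Per-isotype columns count the
#' distinct (CDR3, isotype) pairs for each heavy chain.
#'
#' @param set Rearrangement set pre-filtered to the V gene of interest; the
#'   V-region amino-acid sequence is derived by translating the transcript
#'   upstream of the junction.
#' @param n Number of rows to return (>= 1).
#' @return Tibble: rank, heavy_chain_aa, n_clones, one count column per
#'   observed isotype, and dominant_category when profiling columns are
#'   present. The number of records whose V region could not be derived is
#'   in the `n_excluded` attribute.
#' @export
enumerate_top_clones <- function(set, n = 10L) {
  if (n < 1L) stop("n must be >= 1")
  df <- tibble::as_tibble(set)
  pos <- vapply(seq_len(nrow(df)), function(i) {
    if (is.na(df$junction[i]) || is.na(df$sequence[i])) return(NA_integer_)
    as.integer(regexpr(df$junction[i], df$sequence[i], fixed = TRUE))
  }, integer(1))
  ok <- !is.na(pos) & pos > 1L & (pos - 1L) %% 3L == 0L
  n_excluded <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0L) stop("no records with a derivable V-region aa sequence")
  v_nt <- substr(df$sequence, 1L, pos[ok] - 1L)
  df$heavy_chain_aa <- translate_nt(v_nt)
  df$isotype <- ifelse(is.na(df$c_call), "unknown", gene_from_call(df$c_call))

  per_hc <- df |>
    dplyr::distinct(.data$heavy_chain_aa, .data$junction_aa, .data$isotype) |>
    dplyr::count(.data$heavy_chain_aa, .data$isotype, name = "n_pairs")
  totals <- df |>
    dplyr::distinct(.data$heavy_chain_aa, .data$junction_aa) |>
    dplyr::count(.data$heavy_chain_aa, name = "n_clones")
  wide <- tidyr::pivot_wider(per_hc, names_from = "isotype",
                             values_from = "n_pairs", values_fill = 0L)
  out <- dplyr::left_join(totals, wide, by = "heavy_chain_aa")
  out <- out[order(-out$n_clones, out$heavy_chain_aa, method = "radix"), ]
  if ("idiotope_category" %in% names(df)) {
    dom <- vapply(out$heavy_chain_aa, function(hc) {
      cats <- df$idiotope_category[df$heavy_chain_aa == hc]
      cats <- cats[!is.na(cats)]
      if (!length(cats)) return(NA_character_)
      tt <- sort(table(cats), decreasing = TRUE)
      winners <- names(tt)[tt == max(tt)]
      CLONE_CATEGORIES[CLONE_CATEGORIES %in% winners][1]
    }, character(1))
    out$dominant_category <- unname(dom)
  }
  out <- utils::head(out, n)
  out <- tibble::add_column(out, rank = seq_len(nrow(out)), .before = 1)
  attr(out, "n_excluded") <- n_excluded
  out
}
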