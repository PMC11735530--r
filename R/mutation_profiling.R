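# Somatic mutation profiling against the germline V gene and classification
# of each clone by the VH4-34 self-reactivity hotspot scheme: the framework-1
# hydrophobic patch (A24-V25-Y26, auxiliary Q6-W7) that carries the 9G4
# idiotope, the CDR2 N-glycosylation site (N57-H58-S59), and the framework-3
# K90-L91-S92 triplet. Replacement mutations at these sites attenuate the
# intrinsic self-reactivity of germline-encoded VH4-34 receptors.

#' Hotspot scheme for VH4-34 idiotope classification
#'
#' Positions are 1-based amino-acid indices in the translated V region
#' (linear numbering FR1..FR3). The auxiliary hydrophobic-patch pair Q6/W7
#' is excluded from the AVY trigger by default; set `include_aux_in_avy` to
#' fold it in. An alternative numbering can be supplied by passing different
#' position sets.
#'
#' @param avy_positions Hydrophobic-patch core positions (default 24:26).
#' @param hydrophobic_patch_aux Auxiliary patch positions (default 6:7).
#' @param nhs_positions N-glycosylation site positions (default 57:59).
#' @param kls_positions FR3 triplet positions (default 90:92).
#' @param include_aux_in_avy Whether Q6/W7 replacements trigger AVY.
#' @return A `hotspot_scheme` object.
#' @export
hotspot_scheme <- function(avy_positions = c(24L, 25L, 26L),
                           hydrophobic_patch_aux = c(6L, 7L),
                           nhs_positions = c(57L, 58L, 59L),
                           kls_positions = c(90L, 91L, 92L),
                           include_aux_in_avy = FALSE) {
  sets <- list(avy = as.integer(avy_positions),
               aux = as.integer(hydrophobic_patch_aux),
               nhs = as.integer(nhs_positions),
               kls = as.integer(kls_positions))
  all_pos <- unlist(sets)
  if (anyDuplicated(all_pos)) {
    stop("hotspot position sets must be pairwise disjoint")
  }
  structure(
    c(sets, list(include_aux_in_avy = isTRUE(include_aux_in_avy))),
    class = "hotspot_scheme"
  )
}

scheme_positions <- function(scheme) {
  sort(unique(c(scheme$avy, scheme$aux, scheme$nhs, scheme$kls)))
}

check_scheme_span <- function(scheme, germline) {
  if (any(scheme_positions(scheme) > nchar(germline$sequence_aa))) {
    stop("hotspot scheme positions fall outside the germline V-region span")
  }
  invisible(TRUE)
}

#' Align a transcript to its germline V gene
#'
#' Global in the germline, local in the read: the full germline V region is
#' aligned to the best-matching substring of the transcript, so the junction
#' and any downstream constant-region sequence do not distort the V
#' alignment. Mismatch columns map one-to-one onto 1-based germline
#' coordinates.
#'
#' @param sequence_nt Transcript nucleotide sequence (or a `Rearrangement`
#'   row's `sequence`).
#' @param germline A `germline_reference`.
#' @param identity_floor Minimum fractional identity; lower identities raise
#'   a misassignment error (default 0.7).
#' @return A `v_alignment`: gapped query/germline strings, identity, allele.
#' @export
align_to_germline <- function(sequence_nt, germline, identity_floor = 0.7) {
  al <- align_many(sequence_nt, germline)[[1]]
  if (al$identity < identity_floor) {
    stop(sprintf("alignment identity %.3f below floor %.2f for allele %s",
                 al$identity, identity_floor, germline$allele_name))
  }
  al
}

# Vectorised core: aligns many reads against one germline.
align_many <- function(sequences, germline) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(sequences),
    subject = Biostrings::DNAString(germline$sequence_nt),
    type = "local-global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE),
    gapOpening = 6, gapExtension = 2
  )
  ident <- Biostrings::pid(pa) / 100
  ind <- Biostrings::nindel(pa)
  gapless <- Biostrings::insertion(ind)[, "WidthSum"] == 0 &
    Biostrings::deletion(ind)[, "WidthSum"] == 0
  p_start <- IRanges::start(Biostrings::pattern(pa))
  p_end <- IRanges::end(Biostrings::pattern(pa))
  lapply(seq_along(sequences), function(i) {
    if (gapless[i]) {
      # no gaps: the aligned read region maps 1:1 onto the germline
      qa <- substr(sequences[i], p_start[i], p_end[i])
      ga <- germline$sequence_nt
    } else {
      qa <- as.character(Biostrings::alignedPattern(pa[i]))
      ga <- as.character(Biostrings::alignedSubject(pa[i]))
    }
    structure(
      list(aligned_query = qa, aligned_germline = ga,
           identity = ident[i], allele_name = germline$allele_name),
      class = "v_alignment"
    )
  })
}

#' Call somatic mutations from a V alignment
#'
#' Emits one `Mutation` per mismatch column. Silent versus replacement is
#' decided by translating the full observed codon (all three positions, so
#' multi-hit codons are handled correctly). Codons disrupted by deletions
#' yield no per-site calls; any gap sets `has_indel`. Mismatch sites whose
#' observed codon contains an ambiguous base are skipped and tallied in
#' `n_ambiguous`.
#'
#' @param alignment A `v_alignment` from [align_to_germline()].
#' @param germline The `germline_reference` used for the alignment.
#' @return A `mutation_profile`: mutation table, replacement/silent counts,
#'   indel and ambiguity flags.
#' @export
call_mutations <- function(alignment, germline) {
  q <- strsplit(alignment$aligned_query, "")[[1]]
  g <- strsplit(alignment$aligned_germline, "")[[1]]
  L <- nchar(germline$sequence_nt)
  germ_cols <- which(g != "-")
  stopifnot(length(germ_cols) == L)
  obs <- q[germ_cols]                      # observed base per germline position
  has_insertion <- length(q) > L
  has_deletion <- any(obs == "-")
  has_indel <- has_insertion || has_deletion

  germ <- strsplit(germline$sequence_nt, "")[[1]]
  mismatch <- obs != germ & obs != "-"
  n_ambiguous <- 0L
  rows <- list()
  if (any(mismatch)) {
    codon_idx <- ceiling(which(mismatch) / 3)
    for (p in which(mismatch)) {
      ci <- ceiling(p / 3)
      cod_pos <- (3L * ci - 2L):(3L * ci)
      obs_codon <- obs[cod_pos]
      if (any(obs_codon == "-")) next          # deletion-disrupted codon
      if (any(!obs_codon %in% DNA_BASES)) {    # ambiguous base in codon
        n_ambiguous <- n_ambiguous + 1L
        next
      }
      germ_aa <- substr(germline$sequence_aa, ci, ci)
      obs_aa <- codon_to_aa(paste(obs_codon, collapse = ""))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        nt_position = p,
        germline_nt = germ[p],
        observed_nt = obs[p],
        aa_position = ci,
        germline_aa = germ_aa,
        observed_aa = obs_aa,
        is_silent = identical(germ_aa, obs_aa),
        region = region_of(germline, ci)
      )
    }
  }
  mutations <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    nt_position = integer(), germline_nt = character(),
    observed_nt = character(), aa_position = integer(),
    germline_aa = character(), observed_aa = character(),
    is_silent = logical(), region = character()
  )
  structure(
    list(
      mutations = mutations,
      n_replacement = sum(!mutations$is_silent),
      n_silent = sum(mutations$is_silent),
      n_ambiguous = n_ambiguous,
      has_indel = has_indel,
      identity = alignment$identity,
      allele_name = alignment$allele_name
    ),
    class = "mutation_profile"
  )
}

#' Classify a mutation profile into an idiotope category
#'
#' Precedence classification over the hotspot scheme: AVY if any replacement
#' falls at an AVY position (plus the auxiliary Q6/W7 pair when
#' `include_aux_in_avy`); else NHS; else KLS; else OTHER_REPLACEMENT if any
#' replacement remains; else SILENT_ONLY if only silent changes; else
#' GERMLINE. Profiles with indels are UNCLASSIFIABLE. Junction/CDR3
#' mutations never reach this classification — profiling covers only the
#' germline V region.
#'
#' @param profile A `mutation_profile`.
#' @param scheme A `hotspot_scheme`.
#' @return One of GERMLINE, AVY, NHS, KLS, OTHER_REPLACEMENT, SILENT_ONLY,
#'   UNCLASSIFIABLE.
#' @export
classify_idiotope <- function(profile, scheme = hotspot_scheme()) {
  if (isTRUE(profile$has_indel)) return("UNCLASSIFIABLE")
  m <- profile$mutations
  repl <- m$aa_position[!m$is_silent]
  avy_set <- if (scheme$include_aux_in_avy) c(scheme$avy, scheme$aux) else scheme$avy
  if (any(repl %in% avy_set)) return("AVY")
  if (any(repl %in% scheme$nhs)) return("NHS")
  if (any(repl %in% scheme$kls)) return("KLS")
  if (length(repl) > 0L) return("OTHER_REPLACEMENT")
  if (profile$n_silent > 0L) return("SILENT_ONLY")
  "GERMLINE"
}

#' Profile a rearrangement set against germline references
#'
#' Batch wrapper: aligns every record whose V gene has a germline reference,
#' calls mutations and classifies each record. Appends extension columns
#' `idiotope_category`, `n_replacement`, `n_silent`, `n_ambiguous`,
#' `has_indel`, `v_identity` and the multi-label hotspot flags `hits_avy`,
#' `hits_nhs`, `hits_kls` (so any alternative precedence can be re-derived).
#' Records whose alignment identity falls below `identity_floor` are marked
#' UNCLASSIFIABLE.
#'
#' @param set Rearrangement set.
#' @param germlines Named list of `germline_reference` objects keyed by gene.
#' @param scheme A `hotspot_scheme`.
#' @param identity_floor Minimum alignment identity (default 0.7).
#' @return The set with profiling columns appended.
#' @export
profile_repertoire <- function(set, germlines, scheme = hotspot_scheme(),
                               identity_floor = 0.7) {
  df <- tibble::as_tibble(set)
  n <- nrow(df)
  cat_v <- rep(NA_character_, n)
  n_repl <- rep(NA_integer_, n)
  n_sil <- rep(NA_integer_, n)
  n_amb <- rep(NA_integer_, n)
  indel <- rep(NA, n)
  ident <- rep(NA_real_, n)
  hit <- matrix(NA, n, 3, dimnames = list(NULL, c("avy", "nhs", "kls")))
  genes <- gene_from_call(df$v_call)
  for (gname in intersect(unique(genes), names(germlines))) {
    germ <- germlines[[gname]]
    check_scheme_span(scheme, germ)
    idx <- which(genes == gname)
    als <- align_many(df$sequence[idx], germ)
    for (k in seq_along(idx)) {
      i <- idx[k]
      al <- als[[k]]
      ident[i] <- al$identity
      if (al$identity < identity_floor) {
        cat_v[i] <- "UNCLASSIFIABLE"
        next
      }
      prof <- call_mutations(al, germ)
      cat_v[i] <- classify_idiotope(prof, scheme)
      n_repl[i] <- prof$n_replacement
      n_sil[i] <- prof$n_silent
      n_amb[i] <- prof$n_ambiguous
      indel[i] <- prof$has_indel
      repl <- prof$mutations$aa_position[!prof$mutations$is_silent]
      avy_set <- if (scheme$include_aux_in_avy) c(scheme$avy, scheme$aux) else scheme$avy
      hit[i, ] <- c(any(repl %in% avy_set), any(repl %in% scheme$nhs),
                    any(repl %in% scheme$kls))
    }
  }
  df$idiotope_category <- cat_v
  df$n_replacement <- n_repl
  df$n_silent <- n_sil
  df$n_ambiguous <- n_amb
  df$has_indel <- indel
  df$v_identity <- ident
  df$hits_avy <- hit[, "avy"]
  df$hits_nhs <- hit[, "nhs"]
  df$hits_kls <- hit[, "kls"]
  out <- new_rearrangement_set(df, attr(set, "provenance"))
  append_provenance(out, paste0("profile_repertoire: ",
                                sum(!is.na(cat_v)), "/", n,
                                " records profiled"))
}

#' Summarize idiotope categories per group
#'
#' Per-group counts and fractions over the seven categories, in fixed
#' category order. Fractions sum to 1 within each group.
#'
#' @param df Data frame with a grouping column and a category column
#'   (e.g. the output of [profile_repertoire()]).
#' @param group_col Grouping column name (default `subject_id`).
#' @param category_col Category column name (default `idiotope_category`).
#' @return Tibble with columns group, category, count, fraction, n_total.
#' @export
summarize_categories <- function(df, group_col = "subject_id",
                                 category_col = "idiotope_category") {
  df <- tibble::as_tibble(df)
  keep <- !is.na(df[[category_col]])
  if (any(!keep)) {
    warning(sum(!keep), " record(s) without a category omitted")
  }
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) {
    warning("no classified records; empty category table")
    return(tibble::tibble(group = character(), category = character(),
                          count = integer(), fraction = double(),
                          n_total = integer()))
  }
  groups <- as.character(df[[group_col]])
  cats <- factor(df[[category_col]], levels = CLONE_CATEGORIES)
  tab <- table(groups, cats)
  out <- lapply(rownames(tab), function(gr) {
    counts <- as.integer(tab[gr, ])
    tibble::tibble(
      group = gr,
      category = CLONE_CATEGORIES,
      count = counts,
      fraction = counts / sum(counts),
      n_total = sum(counts)
    )
  })
  dplyr::bind_rows(out)
}
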