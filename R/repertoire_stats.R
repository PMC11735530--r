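# Repertoire-level skew statistics: Chao1 richness, V-J pairing usage,
# CDR3 length by J gene, CDR3 physicochemistry, and distal-JH usage —
# the signatures by which an impaired-recombination repertoire departs
# from a healthy one.

#' Chao1 richness estimate
#'
#' Nonparametric richness estimator from an abundance vector: observed
#' richness corrected for unseen species using singleton (f1) and doubleton
#' (f2) counts. The classic form is `S_obs + f1^2 / (2 f2)`; the
#' bias-corrected form (default) is `S_obs + f1 (f1 - 1) / (2 (f2 + 1))`.
#' When f2 = 0 the classic form is undefined and falls back to the
#' bias-corrected form.
#'
#' @param abundances Positive integer vector, one entry per observed species
#'   (e.g. records per unique CDR3).
#' @param variant "bias_corrected" (default) or "classic".
#' @return A `diversity_estimate`: s_obs, f1, f2, chao1, variant.
#' @export
chao1_estimate <- function(abundances,
                           variant = c("bias_corrected", "classic")) {
  variant <- match.arg(variant)
  if (length(abundances) == 0L) {
    stop("Chao1 is undefined for an empty abundance vector")
  }
  if (any(is.na(abundances)) || any(abundances < 1)) {
    stop("abundances must all be >= 1")
  }
  s_obs <- length(abundances)
  f1 <- sum(abundances == 1)
  f2 <- sum(abundances == 2)
  chao1 <- if (variant == "classic" && f2 > 0) {
    s_obs + f1^2 / (2 * f2)
  } else {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  }
  structure(
    list(s_obs = s_obs, f1 = f1, f2 = f2, chao1 = chao1, variant = variant),
    class = "diversity_estimate"
  )
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("Chao1 (%s): %.2f  [S_obs=%d, f1=%d, f2=%d]\n",
              x$variant, x$chao1, x$s_obs, x$f1, x$f2))
  invisible(x)
}

# Abundance vector over unique CDR3s for one set of records.
cdr3_abundances <- function(df, level = c("nt", "aa"),
                            weight = c("clone", "duplicate")) {
  level <- match.arg(level)
  weight <- match.arg(weight)
  key <- if (level == "nt") df$junction else df$junction_aa
  ok <- !is.na(key) & nchar(key) > 0L
  key <- key[ok]
  if (length(key) == 0L) stop("no usable CDR3 sequences")
  if (weight == "clone") {
    as.integer(table(key))
  } else {
    as.integer(tapply(df$duplicate_count[ok], key, sum))
  }
}

#' Per-subject CDR3 diversity
#'
#' Chao1 per grouping level over unique CDR3 sequences (nucleotide by
#' default). Clone weighting counts each unique rearrangement record once;
#' duplicate weighting sums `duplicate_count`.
#'
#' @param set Rearrangement set.
#' @param by Grouping column (default `subject_id`).
#' @param level CDR3 identity level: "nt" (default) or "aa".
#' @param weight "clone" (default) or "duplicate".
#' @param variant Chao1 variant, see [chao1_estimate()].
#' @return Tibble: group, s_obs, f1, f2, chao1, variant.
#' @export
repertoire_diversity <- function(set, by = "subject_id",
                                 level = c("nt", "aa"),
                                 weight = c("clone", "duplicate"),
                                 variant = c("bias_corrected", "classic")) {
  df <- tibble::as_tibble(set)
  variant <- match.arg(variant)
  groups <- if (by %in% names(df)) as.character(df[[by]]) else rep("all", nrow(df))
  groups[is.na(groups)] <- "<NA>"
  out <- lapply(sort(unique(groups)), function(gr) {
    est <- chao1_estimate(
      cdr3_abundances(df[groups == gr, , drop = FALSE], level, weight),
      variant
    )
    tibble::tibble(group = gr, s_obs = est$s_obs, f1 = est$f1, f2 = est$f2,
                   chao1 = est$chao1, variant = est$variant)
  })
  dplyr::bind_rows(out)
}

#' V-J pairing usage matrix
#'
#' Percentage of total V-J pairs per (V gene, J gene) cell. Clone-weighted
#' by default (each record counts once); duplicate weighting sums
#' `duplicate_count`. Non-productive rearrangements are included by default,
#' since usage skew in the pre-selection repertoire is visible only when
#' they are retained.
#'
#' @param set Rearrangement set.
#' @param include_nonproductive Keep non-productive records (default TRUE).
#' @param weight "clone" (default) or "duplicate".
#' @return Matrix (V genes x J genes) of percentages summing to 100, with
#'   attribute `include_nonproductive`.
#' @export
vj_usage_matrix <- function(set, include_nonproductive = TRUE,
                            weight = c("clone", "duplicate")) {
  weight <- match.arg(weight)
  df <- tibble::as_tibble(set)
  if (!include_nonproductive) {
    df <- df[!is.na(df$productive) & df$productive, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no records available for V-J usage")
  v <- gene_from_call(df$v_call)
  j <- gene_from_call(df$j_call)
  w <- if (weight == "clone") rep(1, nrow(df)) else df$duplicate_count
  counts <- tapply(w, list(v, j), sum, default = 0)
  pct <- 100 * counts / sum(counts)
  pct <- pct[order(rownames(pct)), order(colnames(pct)), drop = FALSE]
  attr(pct, "include_nonproductive") <- include_nonproductive
  pct
}

#' Long-format export of a V-J usage matrix
#'
#' @param mat Matrix from [vj_usage_matrix()].
#' @return Tibble: v_gene, j_gene, percent.
#' @export
vj_usage_long <- function(mat) {
  tibble::tibble(
    v_gene = rep(rownames(mat), times = ncol(mat)),
    j_gene = rep(colnames(mat), each = nrow(mat)),
    percent = as.vector(mat)
  )
}

trim_cdr3 <- function(junction_aa, trim_anchors = TRUE) {
  if (!trim_anchors) return(junction_aa)
  len <- nchar(junction_aa)
  out <- rep(NA_character_, length(junction_aa))
  ok <- !is.na(junction_aa) & len > 2L
  out[ok] <- substr(junction_aa[ok], 2L, len[ok] - 1L)
  out
}

#' CDR3 amino-acid length distribution per J gene
#'
#' CDR3 length is the junction length minus the two conserved anchor
#' residues (Cys-104 and Trp/Phe-118) by default; disable `trim_anchors`
#' to count full junction lengths. Records without a usable junction (or
#' shorter than the anchors) are excluded and tallied.
#'
#' @param set Rearrangement set.
#' @param trim_anchors Trim the two anchors (default TRUE).
#' @return Tibble: j_gene, cdr3_length, n; excluded-record count in the
#'   `n_excluded` attribute.
#' @export
cdr3_length_by_j <- function(set, trim_anchors = TRUE) {
  df <- tibble::as_tibble(set)
  cdr3 <- trim_cdr3(df$junction_aa, trim_anchors)
  ok <- !is.na(cdr3) & nchar(cdr3) > 0L
  out <- tibble::tibble(
    j_gene = gene_from_call(df$j_call[ok]),
    cdr3_length = nchar(cdr3[ok])
  ) |>
    dplyr::count(.data$j_gene, .data$cdr3_length, name = "n") |>
    dplyr::arrange(.data$j_gene, .data$cdr3_length)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' CDR3 physicochemistry: hydrophobicity and cysteine content
#'
#' Per-record mean residue hydrophobicity of the (anchor-trimmed) CDR3 under
#' a named scale (Kyte-Doolittle by default) and the cysteine count within
#' the CDR3; per-subject aggregates report the mean index and the fraction
#' of CDR3s containing at least one cysteine. Records with unknown residue
#' letters are flagged and excluded from the means.
#'
#' @param set Rearrangement set.
#' @param scale Scale name or named numeric vector, see
#'   [hydrophobicity_scale()].
#' @param trim_anchors Trim the two anchor residues (default TRUE).
#' @param by Grouping column for aggregates (default `subject_id`).
#' @return List with `per_record` (sequence_id, cdr3_aa, cdr3_length,
#'   mean_hydrophobicity, n_cys, flagged) and `per_group` (group,
#'   mean_hydrophobicity, frac_with_cys, n) tibbles.
#' @export
cdr3_physicochemistry <- function(set, scale = "kyte_doolittle",
                                  trim_anchors = TRUE, by = "subject_id") {
  sc <- hydrophobicity_scale(scale)
  df <- tibble::as_tibble(set)
  cdr3 <- trim_cdr3(df$junction_aa, trim_anchors)
  ok <- !is.na(cdr3) & nchar(cdr3) > 0L
  res <- lapply(cdr3[ok], function(s) {
    aa <- strsplit(s, "")[[1]]
    known <- aa %in% names(sc)
    list(
      mean_h = if (all(known)) mean(sc[aa]) else NA_real_,
      n_cys = sum(aa == "C"),
      flagged = !all(known)
    )
  })
  per_record <- tibble::tibble(
    sequence_id = df$sequence_id[ok],
    cdr3_aa = cdr3[ok],
    cdr3_length = nchar(cdr3[ok]),
    mean_hydrophobicity = vapply(res, `[[`, 0, "mean_h"),
    n_cys = vapply(res, `[[`, 0L, "n_cys"),
    flagged = vapply(res, `[[`, FALSE, "flagged")
  )
  groups <- if (by %in% names(df)) as.character(df[[by]][ok]) else
    rep("all", sum(ok))
  groups[is.na(groups)] <- "<NA>"
  clean <- !per_record$flagged
  per_group <- tibble::tibble(group = groups[clean],
                              h = per_record$mean_hydrophobicity[clean],
                              cys = per_record$n_cys[clean] > 0L) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      mean_hydrophobicity = mean(.data$h),
      frac_with_cys = mean(.data$cys),
      n = dplyr::n(),
      .groups = "drop"
    )
  list(per_record = per_record, per_group = per_group)
}

#' Distal J-gene usage fraction
#'
#' Fraction of records (clone-weighted by default) whose J call resolves to
#' a distal J gene (JH5/JH6 by default — the segments whose loss marks
#' impaired recombination), plus the full per-J usage vector.
#'
#' @param set Rearrangement set.
#' @param distal_genes Distal gene names (default IGHJ5, IGHJ6).
#' @param weight "clone" (default) or "duplicate".
#' @return List: `fraction` (scalar), `usage` (named vector summing to 1).
#' @export
distal_j_fraction <- function(set, distal_genes = c("IGHJ5", "IGHJ6"),
                              weight = c("clone", "duplicate")) {
  weight <- match.arg(weight)
  df <- tibble::as_tibble(set)
  if (nrow(df) == 0L) stop("empty rearrangement set")
  j <- gene_from_call(df$j_call)
  w <- if (weight == "clone") rep(1, nrow(df)) else df$duplicate_count
  usage <- tapply(w, j, sum, default = 0)
  usage <- usage / sum(usage)
  usage <- usage[order(names(usage))]
  list(
    fraction = sum(usage[names(usage) %in% distal_genes]),
    usage = usage
  )
}
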