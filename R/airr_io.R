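# AIRR-C rearrangement table I/O: read/write, transcript collapsing and
# filtering. Column names follow the AIRR Rearrangement schema; unknown
# columns are carried through untouched.

AIRR_REQUIRED <- c("sequence_id", "v_call", "j_call", "junction")
KNOWN_ISOTYPES <- c("IGHM", "IGHD", "IGHG", "IGHA", "IGHE")

new_rearrangement_set <- function(df, provenance = list()) {
  df <- tibble::as_tibble(df)
  attr(df, "provenance") <- provenance
  class(df) <- c("rearrangement_set", class(df))
  df
}

#' Provenance log of a rearrangement set
#'
#' @param set A rearrangement set.
#' @return List with the source path and the filter/transform log.
#' @export
provenance <- function(set) attr(set, "provenance")

append_provenance <- function(set, entry) {
  p <- attr(set, "provenance")
  p$log <- c(p$log, entry)
  attr(set, "provenance") <- p
  set
}

parse_airr_logical <- function(x) {
  up <- toupper(trimws(x))
  out <- rep(NA, length(x))
  out[up %in% c("T", "TRUE", "1")] <- TRUE
  out[up %in% c("F", "FALSE", "0")] <- FALSE
  out
}

infer_productive <- function(junction) {
  ok <- !is.na(junction) & nchar(junction) > 0L
  out <- rep(NA, length(junction))
  inframe <- ok & nchar(junction) %% 3L == 0L
  out[ok & !inframe] <- FALSE
  if (any(inframe)) {
    aa <- translate_nt(junction[inframe])
    out[inframe] <- !grepl("*", aa, fixed = TRUE)
  }
  out
}

#' Read an AIRR rearrangement TSV
#'
#' Reads a tab-separated rearrangement table with at least `sequence_id`,
#' `v_call`, `j_call`, `junction` and one of `sequence` /
#' `sequence_alignment`. Missing optional columns receive documented
#' defaults: `duplicate_count` 1; `productive` inferred from the junction
#' (in frame and stop-free); `locus` inferred from the `v_call` prefix.
#' Multi-assignment `v_call`/`j_call` values keep the first allele and are
#' flagged in `v_call_multi` / `j_call_multi`. Unknown columns are carried
#' through untouched.
#'
#' @param path TSV path.
#' @param strict If TRUE, duplicated `sequence_id` values and locus/gene
#'   prefix inconsistencies are errors rather than warnings.
#' @return A rearrangement set (tibble with a provenance attribute).
#' @export
read_rearrangements <- function(path, strict = FALSE) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE, na = character())
  df[df == ""] <- NA
  missing_cols <- setdiff(AIRR_REQUIRED, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column: ", paste(missing_cols, collapse = ", "))
  }
  if (!any(c("sequence", "sequence_alignment") %in% names(df))) {
    stop("missing required column: sequence (or sequence_alignment)")
  }
  if (!"sequence" %in% names(df)) {
    df$sequence <- gsub("[.\\-]", "", df$sequence_alignment)
  }
  if (anyDuplicated(df$sequence_id)) {
    msg <- "duplicate sequence_id values in input"
    if (strict) stop(msg) else warning(msg)
  }
  for (col in c("v_call", "j_call")) {
    multi <- grepl(",", df[[col]], fixed = TRUE)
    df[[paste0(col, "_multi")]] <- multi
    df[[col]] <- sub(",.*$", "", df[[col]])
  }
  if (!"c_call" %in% names(df)) df$c_call <- NA_character_
  if (!"junction_aa" %in% names(df)) {
    df$junction_aa <- NA_character_
    inframe <- !is.na(df$junction) & nchar(df$junction) %% 3L == 0L &
      nchar(df$junction) > 0L
    if (any(inframe)) df$junction_aa[inframe] <- translate_nt(df$junction[inframe])
  }
  df$duplicate_count <- if ("duplicate_count" %in% names(df)) {
    n <- suppressWarnings(as.integer(df$duplicate_count))
    n[is.na(n)] <- 1L
    n
  } else rep(1L, nrow(df))
  if (any(df$duplicate_count < 1L)) stop("duplicate_count must be >= 1")
  df$productive <- if ("productive" %in% names(df)) {
    p <- parse_airr_logical(df$productive)
    p[is.na(p)] <- infer_productive(df$junction[is.na(p)])
    p
  } else infer_productive(df$junction)
  if (!"locus" %in% names(df)) {
    df$locus <- ifelse(grepl("^TRB", df$v_call), "TRB", "IGH")
  }
  bad_locus <- !is.na(df$v_call) &
    substr(df$v_call, 1, 3) != substr(df$locus, 1, 3)
  if (any(bad_locus)) {
    msg <- paste0("v_call prefix inconsistent with locus for ",
                  sum(bad_locus), " record(s)")
    if (strict) stop(msg) else warning(msg)
  }
  if (!"subject_id" %in% names(df)) df$subject_id <- NA_character_
  if (!"subset_label" %in% names(df)) df$subset_label <- NA_character_
  new_rearrangement_set(df, provenance = list(source = path, log = character()))
}

#' Write a rearrangement set as an AIRR TSV
#'
#' Logical `productive` is serialised as `T`/`F` per AIRR convention.
#'
#' @param set Rearrangement set (or plain data frame with AIRR columns).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_rearrangements <- function(set, path) {
  df <- as.data.frame(set)
  for (col in names(df)) {
    if (is.logical(df[[col]])) {
      df[[col]] <- ifelse(is.na(df[[col]]), NA_character_,
                          ifelse(df[[col]], "T", "F"))
    }
  }
  readr::write_tsv(tibble::as_tibble(df), path, na = "", progress = FALSE)
  invisible(path)
}

#' Collapse transcripts to unique rearrangements
#'
#' Records identical on the collapse keys are merged into one record whose
#' `duplicate_count` is the sum of the merged counts; the first-seen record
#' supplies all other fields (including `sequence_id`). This controls for
#' expression and amplification bias while keeping isotypes distinct
#' (`c_call` is in the default keys).
#'
#' @param set Rearrangement set.
#' @param keys Collapse-key columns (defaults keep isotype and
#'   subject/subset separate).
#' @return Collapsed rearrangement set; total `duplicate_count` conserved.
#' @export
collapse_transcripts <- function(set,
                                 keys = c("sequence", "c_call",
                                          "subject_id", "subset_label")) {
  df <- tibble::as_tibble(set)
  if (nrow(df) == 0L) return(set)
  keys <- intersect(keys, names(df))
  key_id <- do.call(paste, c(lapply(keys, function(k) {
    x <- as.character(df[[k]])
    ifelse(is.na(x), "\r<NA>", x)
  }), sep = "\r"))
  first_idx <- !duplicated(key_id)
  sums <- tapply(df$duplicate_count, key_id, sum)
  out <- df[first_idx, , drop = FALSE]
  out$duplicate_count <- as.integer(sums[key_id[first_idx]])
  out <- new_rearrangement_set(out, attr(set, "provenance"))
  append_provenance(out, paste0("collapse_transcripts(keys=",
                                paste(keys, collapse = ","), "): ",
                                nrow(df), " -> ", nrow(out), " records"))
}

#' Filter rearrangements by V gene, isotype and productivity
#'
#' All supplied predicates must hold. V-gene matching is at the gene level
#' (allele suffixes ignored), e.g. `v_gene = "IGHV4-34"` keeps every
#' `IGHV4-34*xx` record.
#'
#' @param set Rearrangement set.
#' @param v_gene Optional gene-level V name.
#' @param isotype Optional constant-region token (IGHM, IGHD, IGHG, IGHA,
#'   IGHE); unknown tokens are an error.
#' @param productive_only If TRUE, keep only productive records.
#' @return Filtered rearrangement set with updated provenance.
#' @export
filter_rearrangements <- function(set, v_gene = NULL, isotype = NULL,
                                  productive_only = FALSE) {
  df <- tibble::as_tibble(set)
  keep <- rep(TRUE, nrow(df))
  desc <- character()
  if (!is.null(v_gene)) {
    keep <- keep & !is.na(df$v_call) & gene_from_call(df$v_call) == v_gene
    desc <- c(desc, paste0("v_gene=", v_gene))
  }
  if (!is.null(isotype)) {
    if (!isotype %in% KNOWN_ISOTYPES) {
      stop("unknown isotype token: ", isotype)
    }
    keep <- keep & !is.na(df$c_call) & gene_from_call(df$c_call) == isotype
    desc <- c(desc, paste0("isotype=", isotype))
  }
  if (isTRUE(productive_only)) {
    keep <- keep & !is.na(df$productive) & df$productive
    desc <- c(desc, "productive_only")
  }
  if (length(desc) == 0L) return(set)
  out <- new_rearrangement_set(df[keep, , drop = FALSE],
                               attr(set, "provenance"))
  append_provenance(out, paste0("filter_rearrangements(",
                                paste(desc, collapse = ", "), "): ",
                                nrow(df), " -> ", sum(keep), " records"))
}
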