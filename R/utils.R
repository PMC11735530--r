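#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

# Kyte-Doolittle hydropathy index, the conventional default for CDR3
# hydrophobicity summaries.
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Hydrophobicity scales available to [cdr3_physicochemistry()]
#'
#' Returns the named per-residue table for a scale. Only the
#' Kyte-Doolittle scale ships with the package; user scales can be passed
#' directly as a named numeric vector over the 20 amino acids.
#'
#' @param scale Scale name ("kyte_doolittle") or a named numeric vector.
#' @return Named numeric vector of per-residue values.
#' @export
hydrophobicity_scale <- function(scale = "kyte_doolittle") {
  if (is.numeric(scale)) {
    if (is.null(names(scale)) || !all(nchar(names(scale)) == 1L)) {
      stop("a custom hydrophobicity scale must be a named vector over residues")
    }
    return(scale)
  }
  switch(scale,
    kyte_doolittle = KYTE_DOOLITTLE,
    stop("unknown hydrophobicity scale: ", scale)
  )
}

# The seven mutually exclusive idiotope categories, in precedence order for
# classification and in fixed output order for category tables.
CLONE_CATEGORIES <- c(
  "GERMLINE", "AVY", "NHS", "KLS",
  "OTHER_REPLACEMENT", "SILENT_ONLY", "UNCLASSIFIABLE"
)

#' Translate nucleotide strings in frame 1
#'
#' @param nt Character vector of nucleotide sequences (length a multiple of 3).
#' @return Character vector of amino-acid sequences ("*" marks stops,
#'   "X" marks codons containing ambiguous bases).
#' @export
translate_nt <- function(nt) {
  if (length(nt) == 0L) return(character(0))
  as.character(Biostrings::translate(
    Biostrings::DNAStringSet(nt),
    if.fuzzy.codon = "X"
  ))
}

# Single-codon translation via the standard genetic code; NA for codons with
# non-ACGT characters.
codon_to_aa <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa
}

#' Resolve a V/J/C call to its gene-level name
#'
#' Strips the allele suffix (`*01`) and, for multi-assignment calls,
#' keeps only the first listed allele — the analyses here operate at the
#' gene level.
#'
#' @param call Character vector of IMGT-style calls, e.g. `"IGHV4-34*01"`.
#' @return Character vector of gene names, e.g. `"IGHV4-34"`.
#' @export
gene_from_call <- function(call) {
  first <- sub(",.*$", "", call)
  sub("\\*.*$", "", first)
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming distance requires equal lengths")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# All-pairs Hamming distance matrix for equal-length strings.
# O(n^2 L) but vectorised row-wise; partitions in clonal grouping are small.
hamming_matrix <- function(strings) {
  n <- length(strings)
  m <- matrix(unlist(strsplit(strings, "", fixed = TRUE)),
              nrow = n, byrow = TRUE)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    d[i, ] <- as.integer(rowSums(m != rep(m[i, ], each = n)))
  }
  d
}

DNA_BASES <- c("A", "C", "G", "T")

# Uniformly substitute each base with one of the three alternatives.
substitute_bases <- function(bases) {
  vapply(bases, function(b) {
    sample(setdiff(DNA_BASES, b), 1L)
  }, character(1), USE.NAMES = FALSE)
}
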