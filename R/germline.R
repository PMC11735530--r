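# Germline V-gene references: construction of the synthetic reference family,
# FASTA + region-bounds I/O, and validation.

# One representative codon per amino acid. Every codon used for scaffold
# construction (M and W excluded from filler residues) has at least one
# synonymous single-nucleotide neighbour, so silent mutations can be
# implanted at any non-hotspot filler codon.
PREFERRED_CODON <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
  Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
  L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
  S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT"
)

# Filler residues for scaffold positions not fixed by the hotspot layout.
# M and W are excluded so every filler codon admits a synonymous edit.
GERMLINE_FILLER <- strsplit("EVGLSTPDKARFYNIHQ", "")[[1]]

# V-region length (amino acids) of the synthetic references: FR1 through FR3.
V_REGION_AA_LEN <- 98L

# Default region bounds (1-based inclusive amino-acid intervals). Chosen so
# that the hydrophobic-patch triplet A24-V25-Y26 (with auxiliary Q6-W7) falls
# in FR1, the N-glycosylation triplet N57-H58-S59 in CDR2, and K90-L91-S92 in
# FR3 — the regions in which these self-reactivity hotspots reside.
DEFAULT_REGION_BOUNDS <- list(
  FR1  = c(1L, 30L),
  CDR1 = c(31L, 35L),
  FR2  = c(36L, 49L),
  CDR2 = c(50L, 66L),
  FR3  = c(67L, 98L)
)

# Residues fixed in the IGHV4-34-like scaffold: the three hotspot triplets
# plus the auxiliary hydrophobic-patch pair.
VH4_34_FIXED <- c(
  `6` = "Q", `7` = "W",
  `24` = "A", `25` = "V", `26` = "Y",
  `57` = "N", `58` = "H", `59` = "S",
  `90` = "K", `91` = "L", `92` = "S"
)

# Gene registry for the synthetic family. Each gene gets a distinct scaffold
# by shifting the filler cycle; only IGHV4-34 carries the fixed hotspot
# residues.
SYNTHETIC_V_GENES <- c(
  "IGHV4-34", "IGHV1-2", "IGHV1-69", "IGHV3-23",
  "IGHV3-30", "IGHV4-39", "IGHV5-51"
)

synthetic_germline_aa <- function(gene) {
  offset <- match(gene, SYNTHETIC_V_GENES)
  if (is.na(offset)) offset <- 1L + (sum(utf8ToInt(gene)) %% 17L)
  idx <- ((seq_len(V_REGION_AA_LEN) - 1L + (offset - 1L) * 3L) %%
            length(GERMLINE_FILLER)) + 1L
  aa <- GERMLINE_FILLER[idx]
  if (gene == "IGHV4-34") {
    aa[as.integer(names(VH4_34_FIXED))] <- unname(VH4_34_FIXED)
  }
  paste(aa, collapse = "")
}

#' Construct a germline reference object
#'
#' @param allele_name Allele name, e.g. `"IGHV4-34*01"`.
#' @param sequence_nt V-region nucleotide sequence (frame 1, FR1..FR3).
#' @param region_bounds Named list of 1-based inclusive amino-acid intervals
#'   for FR1, CDR1, FR2, CDR2, FR3.
#' @return A `germline_reference` object.
#' @export
germline_reference <- function(allele_name, sequence_nt,
                               region_bounds = DEFAULT_REGION_BOUNDS) {
  sequence_nt <- toupper(sequence_nt)
  if (nchar(sequence_nt) %% 3L != 0L) {
    stop("germline V-region length must be a multiple of 3")
  }
  sequence_aa <- translate_nt(sequence_nt)
  if (grepl("\\*", sequence_aa)) {
    stop("germline V-region translation contains a stop codon")
  }
  validate_region_bounds(region_bounds, nchar(sequence_aa))
  structure(
    list(
      allele_name = allele_name,
      gene = gene_from_call(allele_name),
      sequence_nt = sequence_nt,
      sequence_aa = sequence_aa,
      region_bounds = region_bounds
    ),
    class = "germline_reference"
  )
}

validate_region_bounds <- function(bounds, aa_len) {
  required <- c("FR1", "CDR1", "FR2", "CDR2", "FR3")
  if (!all(required %in% names(bounds))) {
    stop("region bounds must name FR1, CDR1, FR2, CDR2, FR3")
  }
  iv <- do.call(rbind, bounds[required])
  if (any(iv[, 1] > iv[, 2])) stop("region interval start exceeds end")
  if (any(iv < 1L)) stop("region intervals must be 1-based positive")
  if (any(iv[, 2] > aa_len)) {
    stop("region interval exceeds germline protein length (", aa_len, " aa)")
  }
  # ordered and disjoint: each region must start after the previous ends
  if (any(iv[-1, 1] <= iv[-nrow(iv), 2])) {
    stop("region intervals must be disjoint and ordered FR1 < ... < FR3")
  }
  invisible(TRUE)
}

#' Region containing an amino-acid position
#'
#' @param germline A `germline_reference`.
#' @param aa_position 1-based amino-acid positions.
#' @return Character vector of region names (NA outside all regions).
#' @export
region_of <- function(germline, aa_position) {
  out <- rep(NA_character_, length(aa_position))
  for (rg in names(germline$region_bounds)) {
    b <- germline$region_bounds[[rg]]
    out[aa_position >= b[1] & aa_position <= b[2]] <- rg
  }
  out
}

#' Synthetic germline V-gene family
#'
#' Builds the packaged synthetic reference family. The IGHV4-34-like member
#' carries the self-reactivity hotspot residues at their canonical linear
#' positions (Q6, W7; A24, V25, Y26; N57, H58, S59; K90, L91, S92); the other
#' members are distinct scaffolds used only as simulation backgrounds. These
#' are constructed sequences, not database alleles.
#'
#' @param genes Gene names to build (default: the full registry).
#' @return Named list of `germline_reference` objects (names are gene names).
#' @export
synthetic_germline_set <- function(genes = SYNTHETIC_V_GENES) {
  refs <- lapply(genes, function(g) {
    aa <- strsplit(synthetic_germline_aa(g), "")[[1]]
    nt <- paste(PREFERRED_CODON[aa], collapse = "")
    germline_reference(paste0(g, "*01"), nt)
  })
  names(refs) <- genes
  refs
}

#' Write a germline family as FASTA plus a region-bounds JSON sidecar
#'
#' @param refs Named list of `germline_reference` objects.
#' @param fasta_path Output FASTA path.
#' @param bounds_path Output JSON path (1-based inclusive intervals).
#' @return Invisibly, the two paths.
#' @export
write_germline_reference <- function(refs, fasta_path, bounds_path) {
  seqs <- Biostrings::DNAStringSet(vapply(refs, `[[`, "", "sequence_nt"))
  names(seqs) <- vapply(refs, `[[`, "", "allele_name")
  Biostrings::writeXStringSet(seqs, fasta_path)
  bounds <- lapply(refs, function(r) lapply(r$region_bounds, as.integer))
  names(bounds) <- vapply(refs, `[[`, "", "allele_name")
  jsonlite::write_json(bounds, bounds_path, auto_unbox = FALSE)
  invisible(c(fasta = fasta_path, bounds = bounds_path))
}

#' Read germline references from FASTA plus region-bounds JSON
#'
#' FASTA headers carry allele names; the JSON sidecar maps each allele name
#' to its FR1/CDR1/FR2/CDR2/FR3 amino-acid intervals (1-based inclusive).
#' Each record is validated: intervals must be disjoint, ordered and within
#' the translated protein, and the sequence must translate without stops.
#'
#' @param fasta_path FASTA of V-region nucleotide sequences.
#' @param bounds_path JSON sidecar of region bounds.
#' @return Named list of `germline_reference` objects keyed by gene name.
#' @export
read_germline_reference <- function(fasta_path, bounds_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  bounds_all <- jsonlite::read_json(bounds_path)
  refs <- lapply(seq_along(seqs), function(i) {
    allele <- names(seqs)[i]
    b <- bounds_all[[allele]]
    if (is.null(b)) stop("no region bounds supplied for allele ", allele)
    b <- lapply(b, function(x) as.integer(unlist(x)))
    germline_reference(allele, as.character(seqs[[i]]), b)
  })
  names(refs) <- gene_from_call(names(seqs))
  refs
}

#' @export
print.germline_reference <- function(x, ...) {
  cat("Germline reference", x$allele_name, "\n")
  cat(" ", nchar(x$sequence_nt), "nt /", nchar(x$sequence_aa), "aa\n")
  for (rg in names(x$region_bounds)) {
    b <- x$region_bounds[[rg]]
    cat(sprintf("  %-4s %3d..%d\n", rg, b[1], b[2]))
  }
  invisible(x)
}
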