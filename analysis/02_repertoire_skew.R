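#!/usr/bin/env Rscript
# Repertoire-skew statistics on the simulated HD and IIe repertoires:
# Chao1 CDR3 diversity, V-J pairing usage, CDR3 length by J gene, CDR3
# physicochemistry and distal-JH usage. The expectation, mirroring the
# contrast between healthy and RAG-deficient repertoires, is lower
# diversity, a dominant IGHV4-34/IGHJ4 cell and reduced JH5/JH6 usage in
# the IIe-like repertoire.

suppressPackageStartupMessages(library(vh4rep))

outdir <- "results/tables"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

sets <- lapply(c(hd = "hd", iie = "iie"), function(p) {
  collapse_transcripts(
    read_rearrangements(file.path("results/sim", paste0(p, "_airr.tsv"))))
})

div <- dplyr::bind_rows(lapply(sets, repertoire_diversity))
readr::write_tsv(div, file.path(outdir, "diversity.tsv"))
message("Chao1 (unique CDR3nt): ",
        paste(sprintf("%s=%.0f", div$group, div$chao1), collapse = ", "))

for (p in names(sets)) {
  m <- vj_usage_matrix(sets[[p]])
  readr::write_tsv(vj_usage_long(m),
                   file.path(outdir, paste0(p, "_vj_usage.tsv")))
  message(sprintf("%-3s IGHV4-34 x IGHJ4 usage: %.1f%% of V-J pairs",
                  toupper(p), m["IGHV4-34", "IGHJ4"]))
  readr::write_tsv(cdr3_length_by_j(sets[[p]]),
                   file.path(outdir, paste0(p, "_cdr3_lengths.tsv")))
  pc <- cdr3_physicochemistry(sets[[p]])
  readr::write_tsv(pc$per_group,
                   file.path(outdir, paste0(p, "_physchem.tsv")))
  dj <- distal_j_fraction(sets[[p]])
  readr::write_tsv(
    tibble::tibble(j_gene = names(dj$usage), usage = as.numeric(dj$usage)),
    file.path(outdir, paste0(p, "_j_usage.tsv")))
  message(sprintf("%-3s distal JH5+JH6 usage: %.3f", toupper(p), dj$fraction))
}
message("wrote ", outdir)
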