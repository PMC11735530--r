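#!/usr/bin/env Rscript
# VH4-34 hotspot mutation analysis: filter each repertoire to IGHV4-34 IgM
# receptors, align to the germline V gene, call somatic mutations and
# classify every clone by the self-reactivity hotspot scheme (AVY / NHS /
# KLS / other / silent-only / germline); then enumerate the top 10 heavy
# chains by the number of distinct CDR3s carrying them.

suppressPackageStartupMessages(library(vh4rep))

outdir <- "results/tables"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
refs <- synthetic_germline_set()

tabs <- list()
for (p in c("hd", "iie")) {
  col <- collapse_transcripts(
    read_rearrangements(file.path("results/sim", paste0(p, "_airr.tsv"))))
  f <- filter_rearrangements(col, v_gene = "IGHV4-34", isotype = "IGHM")
  prof <- profile_repertoire(f, refs)
  write_rearrangements(prof, file.path(outdir, paste0(p, "_profiled.tsv")))
  tab <- summarize_categories(prof)
  tabs[[p]] <- tab
  shown <- tab[tab$count > 0, ]
  message(sprintf("%-3s (%d IGHV4-34 IgM receptors): %s", toupper(p),
                  shown$n_total[1],
                  paste(sprintf("%s %.1f%%", shown$category,
                                100 * shown$fraction), collapse = ", ")))
  top <- enumerate_top_clones(prof, 10)
  readr::write_tsv(top, file.path(outdir, paste0(p, "_top_clones.tsv")))
}
readr::write_tsv(dplyr::bind_rows(tabs), file.path(outdir, "category_table.tsv"))
message("wrote ", outdir)
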