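#!/usr/bin/env Rscript
# Clonal connectivity: group the profiled IGHV4-34 IgM receptors into
# clones by junction relatedness (normalized Hamming <= 0.15, single
# linkage), draw a reproducible sample of up to 200 clone groups and export
# the connectivity graph (nodes annotated with hotspot category, isotype
# and expression count; edges between same-clone members with junctions
# <= 1 nt apart).

suppressPackageStartupMessages(library(vh4rep))

outdir <- "results/networks"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

for (p in c("hd", "iie")) {
  prof <- read_rearrangements(file.path("results/tables",
                                        paste0(p, "_profiled.tsv")))
  groups <- group_clones(prof, distance_threshold = 0.15, linkage = "single")
  sampled <- sample_groups(groups, 200, seed = 200)
  graph <- build_connectivity_graph(sampled, prof, edge_rule = 1L)
  export_graph(graph,
               file.path(outdir, paste0(p, "_connectivity.graphml")),
               file.path(outdir, paste0(p, "_edges.tsv")))
  readr::write_tsv(attr(groups, "assignments"),
                   file.path(outdir, paste0(p, "_clone_assignments.tsv")))
  sizes <- sort(groups$size, decreasing = TRUE)
  message(sprintf(
    "%-3s: %d clones from %d receptors; sampled %d groups; top clone sizes %s",
    toupper(p), nrow(groups), sum(groups$size), nrow(sampled),
    paste(utils::head(sizes, 5), collapse = "/")))
}
message("wrote ", outdir)
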