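# End-to-end orchestration: ingest -> collapse -> repertoire statistics ->
# V-gene/isotype filter -> mutation profiling -> clonal inference -> exports,
# driven by a single configuration list, with deterministic outputs and a
# run manifest.

#' Pipeline configuration
#'
#' @param input Path to an AIRR rearrangement TSV (ignored if `set` is
#'   passed to [run_pipeline()] directly).
#' @param germline_fasta,region_bounds Germline FASTA and region-bounds JSON
#'   (default: the packaged synthetic family written on the fly).
#' @param v_gene,isotype,productive_only Filter applied before profiling
#'   (defaults: IGHV4-34, IGHM, keep non-productive).
#' @param scheme A `hotspot_scheme`.
#' @param distance_threshold,linkage Clonal grouping parameters.
#' @param edge_rule Maximum junction distance (nt) for graph edges.
#' @param sample_n,seed Clone-group subsample size and RNG seed.
#' @param top_n Rows in the top-clone table.
#' @param chao1_variant,weight,cdr3_level,trim_anchors,scale Statistics
#'   options (see the respective functions).
#' @param outdir Output directory (created if needed).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL,
                            germline_fasta = NULL,
                            region_bounds = NULL,
                            v_gene = "IGHV4-34",
                            isotype = "IGHM",
                            productive_only = FALSE,
                            scheme = hotspot_scheme(),
                            distance_threshold = 0.15,
                            linkage = "single",
                            edge_rule = 1L,
                            sample_n = 200L,
                            seed = 1L,
                            top_n = 10L,
                            chao1_variant = "bias_corrected",
                            weight = "clone",
                            cdr3_level = "nt",
                            trim_anchors = TRUE,
                            scale = "kyte_doolittle",
                            outdir = tempfile("vh4rep_run_")) {
  structure(
    list(input = input, germline_fasta = germline_fasta,
         region_bounds = region_bounds, v_gene = v_gene, isotype = isotype,
         productive_only = productive_only, scheme = scheme,
         distance_threshold = distance_threshold, linkage = linkage,
         edge_rule = edge_rule, sample_n = sample_n, seed = seed,
         top_n = top_n, chao1_variant = chao1_variant, weight = weight,
         cdr3_level = cdr3_level, trim_anchors = trim_anchors,
         scale = scale, outdir = outdir),
    class = "pipeline_config"
  )
}

load_pipeline_germlines <- function(config) {
  if (is.null(config$germline_fasta)) {
    synthetic_germline_set()
  } else {
    read_germline_reference(config$germline_fasta, config$region_bounds)
  }
}

#' Run the full repertoire analysis pipeline
#'
#' Executes the stages in fixed order and writes every table to
#' `config$outdir`: repertoire diversity, V-J usage (long format), CDR3
#' length histograms, CDR3 physicochemistry, the per-record profiled AIRR
#' table, the idiotope category table, clone assignments, the sampled-group
#' connectivity graph (GraphML + edge TSV), the top-clone table and a JSON
#' manifest with per-stage record counts and output checksums. Identical
#' configuration and inputs give identical outputs (manifest timestamp
#' aside).
#'
#' @param config A `pipeline_config`.
#' @param set Optional in-memory rearrangement set (overrides
#'   `config$input`).
#' @return A report bundle: list with every computed table, the graph, the
#'   manifest, and `outdir`.
#' @export
run_pipeline <- function(config, set = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  raw <- stage("ingest", {
    if (!is.null(set)) set else read_rearrangements(config$input)
  })
  counts$ingest <- nrow(raw)

  collapsed <- stage("collapse", collapse_transcripts(raw))
  counts$collapse <- nrow(collapsed)

  stats_out <- stage("repertoire_stats", {
    list(
      diversity = repertoire_diversity(collapsed, level = config$cdr3_level,
                                       weight = config$weight,
                                       variant = config$chao1_variant),
      vj_usage = vj_usage_long(vj_usage_matrix(collapsed,
                                               include_nonproductive = TRUE,
                                               weight = config$weight)),
      cdr3_lengths = cdr3_length_by_j(collapsed, config$trim_anchors),
      physchem = cdr3_physicochemistry(collapsed, config$scale,
                                       config$trim_anchors),
      distal_j = distal_j_fraction(collapsed, weight = config$weight)
    )
  })

  filtered <- stage("filter", {
    filter_rearrangements(collapsed, v_gene = config$v_gene,
                          isotype = config$isotype,
                          productive_only = config$productive_only)
  })
  counts$filter <- nrow(filtered)

  germlines <- stage("germline", load_pipeline_germlines(config))
  profiled <- stage("profile", {
    profile_repertoire(filtered, germlines, config$scheme)
  })
  category_table <- stage("categories", summarize_categories(profiled))

  groups <- stage("clone", {
    group_clones(profiled, config$distance_threshold, config$linkage)
  })
  counts$clones <- nrow(groups)
  sampled <- stage("sample", {
    sample_groups(groups, config$sample_n, config$seed)
  })
  graph <- stage("graph", {
    build_connectivity_graph(sampled, profiled, config$edge_rule)
  })
  top_clones <- stage("topclones", {
    if (nrow(profiled) > 0L) enumerate_top_clones(profiled, config$top_n)
    else NULL
  })

  # --- write outputs ---
  w <- function(df, name) {
    path <- file.path(outdir, name)
    readr::write_tsv(tibble::as_tibble(df), path, na = "", progress = FALSE)
    path
  }
  files <- c(
    w(stats_out$diversity, "diversity.tsv"),
    w(stats_out$vj_usage, "vj_usage.tsv"),
    w(stats_out$cdr3_lengths, "cdr3_lengths.tsv"),
    w(stats_out$physchem$per_record, "physchem_per_record.tsv"),
    w(stats_out$physchem$per_group, "physchem_per_subject.tsv"),
    w(tibble::tibble(j_gene = names(stats_out$distal_j$usage),
                     usage = as.numeric(stats_out$distal_j$usage)),
      "j_usage.tsv"),
    w(category_table, "category_table.tsv"),
    w(attr(groups, "assignments"), "clone_assignments.tsv"),
    w(dplyr::select(sampled, -"member_ids"), "sampled_groups.tsv")
  )
  files <- c(files, file.path(outdir, "profiled.tsv"))
  write_rearrangements(profiled, file.path(outdir, "profiled.tsv"))
  if (!is.null(top_clones)) files <- c(files, w(top_clones, "top_clones.tsv"))
  gml <- file.path(outdir, "connectivity.graphml")
  etsv <- file.path(outdir, "graph_edges.tsv")
  export_graph(graph, gml, etsv)
  files <- c(files, gml, etsv)

  manifest <- list(
    config = config[setdiff(names(config), "scheme")],
    scheme = unclass(config$scheme),
    stage_counts = counts,
    distal_j_fraction = stats_out$distal_j$fraction,
    n_excluded_clonal = attr(groups, "n_excluded"),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)

  list(
    collapsed = collapsed,
    filtered = filtered,
    profiled = profiled,
    category_table = category_table,
    clone_groups = groups,
    sampled_groups = sampled,
    graph = graph,
    top_clones = top_clones,
    stats = stats_out,
    manifest = manifest,
    outdir = outdir
  )
}
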