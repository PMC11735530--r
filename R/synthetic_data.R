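# Synthetic AIRR repertoire generator with ground truth. Emulates the two
# repertoire regimes the analyses contrast: a polyclonal healthy-donor-like
# repertoire (singleton-dominated clone sizes, ~5-10% IGHV4-34, intact
# distal-J usage, hotspot-mutated memory clones) and an affected-sibling-like
# repertoire (oligoclonal expansion, ~50% IGHV4-34, depleted distal JH5/JH6,
# germline/KLS/silent-dominated hotspot profile).

SYNTHETIC_J_GENES <- c("IGHJ1", "IGHJ2", "IGHJ3", "IGHJ4", "IGHJ5", "IGHJ6")

# Short in-frame J-segment remnant appended downstream of the junction.
J_STUBS <- c(
  IGHJ1 = "GGTCAAGGTACT", IGHJ2 = "GGTCAAGGTACC",
  IGHJ3 = "GGTCAAGGAACT", IGHJ4 = "GGTCAAGGAACC",
  IGHJ5 = "GGTCAAGGCACT", IGHJ6 = "GGTCAAGGCACC"
)

STOP_CODONS <- c("TAA", "TAG", "TGA")

default_v_usage <- function(ighv4_34_fraction) {
  others <- setdiff(SYNTHETIC_V_GENES, "IGHV4-34")
  c(
    stats::setNames(ighv4_34_fraction, "IGHV4-34"),
    stats::setNames(rep((1 - ighv4_34_fraction) / length(others),
                        length(others)), others)
  )
}

# Baseline J usage: IGHJ4-dominant with a distal (JH5 + JH6) mass of 0.30.
DEFAULT_J_USAGE <- c(IGHJ1 = 0.05, IGHJ2 = 0.05, IGHJ3 = 0.15,
                     IGHJ4 = 0.45, IGHJ5 = 0.12, IGHJ6 = 0.18)

default_junction_length_law <- function() {
  lengths <- 9:22                       # junction length in amino acids
  p <- stats::dnorm(lengths, mean = 15, sd = 2.2)
  stats::setNames(p / sum(p), lengths)
}

#' Simulation configuration
#'
#' Resolves and validates all generator knobs. The distal-J depletion factor
#' multiplies the baseline mass of the distal genes; the removed mass is
#' redistributed over the non-distal genes, so the realised distal mass is
#' exactly `baseline * factor`.
#'
#' @param n_sequences Number of sequences to emit.
#' @param ighv4_34_fraction Probability a clone uses IGHV4-34 (ignored if
#'   `v_usage` is supplied).
#' @param v_usage Optional named probability vector over V genes.
#' @param j_usage Named probability vector over J genes.
#' @param distal_j_depletion Multiplicative factor on the distal-J mass.
#' @param distal_genes Distal J genes (default IGHJ5, IGHJ6).
#' @param clone_size_law List: `law` ("zipf" or "negative_binomial") plus
#'   parameters (`alpha`, `max_size` for zipf; `mu`, `size` for nbinom).
#' @param shm_rate Background per-nucleotide substitution probability over
#'   the V region.
#' @param hotspot_multipliers Optional list of `list(positions, factor)`
#'   entries boosting the background rate at amino-acid position sets.
#' @param category_mix Optional named probabilities over implanted clone
#'   categories (GERMLINE, AVY, NHS, KLS, OTHER_REPLACEMENT, SILENT_ONLY).
#' @param isotype_probs Named probabilities over constant-region calls.
#' @param nonproductive_fraction Probability a member is frameshifted.
#' @param junction_length_law Named probabilities over junction aa lengths.
#' @param subject_id,subset_label Labels stamped on every record.
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_sequences = 1000L,
                              ighv4_34_fraction = 0.07,
                              v_usage = NULL,
                              j_usage = DEFAULT_J_USAGE,
                              distal_j_depletion = 1,
                              distal_genes = c("IGHJ5", "IGHJ6"),
                              clone_size_law = list(law = "zipf",
                                                    alpha = 1.5,
                                                    max_size = 1000L),
                              shm_rate = 0,
                              hotspot_multipliers = NULL,
                              category_mix = NULL,
                              isotype_probs = c(IGHM = 0.55, IGHD = 0.20,
                                                IGHG = 0.15, IGHA = 0.10),
                              nonproductive_fraction = 0.05,
                              junction_length_law = NULL,
                              subject_id = "sim",
                              subset_label = "CD27+IgM+",
                              seed = 1L) {
  if (n_sequences < 1L) stop("n_sequences must be >= 1")
  if (is.null(v_usage)) v_usage <- default_v_usage(ighv4_34_fraction)
  if (is.null(junction_length_law)) {
    junction_length_law <- default_junction_length_law()
  }
  check_probs <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-9) stop(what, " probabilities must sum to 1")
    if (any(p < 0)) stop(what, " probabilities must be non-negative")
  }
  check_probs(v_usage, "v_usage")
  check_probs(j_usage, "j_usage")
  check_probs(isotype_probs, "isotype_probs")
  check_probs(junction_length_law, "junction_length_law")
  if (!is.null(category_mix)) {
    check_probs(category_mix, "category_mix")
    bad <- setdiff(names(category_mix),
                   setdiff(CLONE_CATEGORIES, "UNCLASSIFIABLE"))
    if (length(bad)) stop("unknown categories in category_mix: ",
                          paste(bad, collapse = ", "))
  }
  if (distal_j_depletion < 0) stop("distal_j_depletion must be >= 0")
  if (shm_rate < 0 || shm_rate >= 1) stop("shm_rate must be in [0, 1)")
  # apply distal depletion: distal mass becomes baseline * factor exactly
  distal <- intersect(names(j_usage), distal_genes)
  if (distal_j_depletion != 1 && length(distal)) {
    j_eff <- j_usage
    j_eff[distal] <- j_usage[distal] * distal_j_depletion
    nond <- setdiff(names(j_usage), distal)
    j_eff[nond] <- j_usage[nond] * (1 - sum(j_eff[distal])) / sum(j_usage[nond])
    j_usage_effective <- j_eff
  } else {
    j_usage_effective <- j_usage
  }
  structure(
    list(
      n_sequences = as.integer(n_sequences),
      v_usage = v_usage,
      j_usage = j_usage,
      j_usage_effective = j_usage_effective,
      distal_j_depletion = distal_j_depletion,
      distal_genes = distal_genes,
      clone_size_law = clone_size_law,
      shm_rate = shm_rate,
      hotspot_multipliers = hotspot_multipliers,
      category_mix = category_mix,
      isotype_probs = isotype_probs,
      nonproductive_fraction = nonproductive_fraction,
      junction_length_law = junction_length_law,
      subject_id = subject_id,
      subset_label = subset_label,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Preset simulation configurations
#'
#' `"hd"` emulates a healthy-donor CD27+IgM+ repertoire: ~7% IGHV4-34,
#' intact distal-J usage, singleton-dominated clone sizes (Zipf alpha 3),
#' and a hotspot mix dominated by AVY/NHS-mutated plus ~25% germline clones.
#' `"iie"` emulates the affected-sibling regime: ~50% IGHV4-34, distal-J
#' mass halved, oligoclonal expansion (Zipf alpha 1.5), and a mix with rare
#' AVY but elevated germline, KLS, scattered-other and silent-only clones.
#'
#' @param preset "hd" or "iie".
#' @param n_sequences Number of sequences.
#' @param seed Integer seed.
#' @return A `simulation_config`.
#' @export
preset_config <- function(preset = c("hd", "iie"), n_sequences = 10000L,
                          seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "hd") {
    simulation_config(
      n_sequences = n_sequences,
      ighv4_34_fraction = 0.07,
      distal_j_depletion = 1,
      clone_size_law = list(law = "zipf", alpha = 3, max_size = 1000L),
      shm_rate = 0.002,
      category_mix = c(GERMLINE = 0.25, AVY = 0.25, NHS = 0.20,
                       KLS = 0.10, OTHER_REPLACEMENT = 0.12,
                       SILENT_ONLY = 0.08),
      isotype_probs = c(IGHM = 0.60, IGHD = 0.25, IGHG = 0.10, IGHA = 0.05),
      subject_id = "HD_sim",
      seed = seed
    )
  } else {
    simulation_config(
      n_sequences = n_sequences,
      ighv4_34_fraction = 0.50,
      distal_j_depletion = 0.5,
      clone_size_law = list(law = "zipf", alpha = 1.5, max_size = 1000L),
      shm_rate = 0.002,
      category_mix = c(GERMLINE = 0.45, AVY = 0.02, NHS = 0.08,
                       KLS = 0.20, OTHER_REPLACEMENT = 0.15,
                       SILENT_ONLY = 0.10),
      isotype_probs = c(IGHM = 0.90, IGHD = 0.05, IGHG = 0.04, IGHA = 0.01),
      subject_id = "IIe_sim",
      seed = seed
    )
  }
}

all_scheme_positions <- function(scheme) {
  unique(c(scheme$avy, scheme$aux, scheme$nhs, scheme$kls))
}

codon_at <- function(sequence_nt, aa_pos) {
  substr(sequence_nt, 3L * aa_pos - 2L, 3L * aa_pos)
}

single_nt_variants <- function(codon) {
  bases <- strsplit(codon, "")[[1]]
  out <- list()
  for (i in 1:3) {
    for (b in setdiff(DNA_BASES, bases[i])) {
      v <- bases
      v[i] <- b
      out[[length(out) + 1L]] <- list(codon = paste(v, collapse = ""),
                                      offset = i, base = b)
    }
  }
  out
}

apply_codon_edit <- function(sequence_nt, aa_pos, variant) {
  nt_pos <- 3L * aa_pos - 3L + variant$offset
  ref <- substr(sequence_nt, nt_pos, nt_pos)
  substr(sequence_nt, nt_pos, nt_pos) <- variant$base
  list(sequence = sequence_nt, nt_position = nt_pos, ref = ref,
       alt = variant$base)
}

#' Implant a category-defining mutation
#'
#' Implants the minimal edit guaranteeing the requested idiotope category
#' under the classifier's precedence: one non-synonymous single-nucleotide
#' change at a position of the category's hotspot set (AVY/NHS/KLS), one
#' non-synonymous change outside every hotspot set (OTHER_REPLACEMENT), or
#' one synonymous change outside every hotspot set (SILENT_ONLY). Stop
#' codons are never created.
#'
#' @param sequence_nt Germline V-region nucleotide sequence.
#' @param category Target category (AVY, NHS, KLS, OTHER_REPLACEMENT or
#'   SILENT_ONLY).
#' @param scheme A `hotspot_scheme`.
#' @param seed Optional integer seed; NULL draws from the current RNG
#'   stream.
#' @return List: `sequence` (mutated), `mutations` (tibble of implanted
#'   edits with nt/aa coordinates and silent flag).
#' @export
inject_hotspot_mutations <- function(sequence_nt, category,
                                     scheme = hotspot_scheme(),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  valid <- c("AVY", "NHS", "KLS", "OTHER_REPLACEMENT", "SILENT_ONLY")
  if (!category %in% valid) {
    stop("category must be one of: ", paste(valid, collapse = ", "))
  }
  n_aa <- nchar(sequence_nt) %/% 3L
  avy_set <- if (scheme$include_aux_in_avy) c(scheme$avy, scheme$aux) else scheme$avy
  candidates <- switch(category,
    AVY = avy_set,
    NHS = scheme$nhs,
    KLS = scheme$kls,
    setdiff(seq_len(n_aa), all_scheme_positions(scheme))
  )
  want_silent <- category == "SILENT_ONLY"
  for (aa_pos in candidates[sample.int(length(candidates))]) {
    codon <- codon_at(sequence_nt, aa_pos)
    ref_aa <- codon_to_aa(codon)
    variants <- single_nt_variants(codon)
    keep <- vapply(variants, function(v) {
      aa <- codon_to_aa(v$codon)
      if (aa == "*") return(FALSE)
      if (want_silent) aa == ref_aa else aa != ref_aa
    }, logical(1))
    variants <- variants[keep]
    if (length(variants) == 0L) next
    v <- variants[[sample.int(length(variants), 1L)]]
    ed <- apply_codon_edit(sequence_nt, aa_pos, v)
    mut <- tibble::tibble(
      nt_position = ed$nt_position,
      germline_nt = ed$ref,
      observed_nt = ed$alt,
      aa_position = aa_pos,
      germline_aa = ref_aa,
      observed_aa = codon_to_aa(v$codon),
      is_silent = want_silent
    )
    return(list(sequence = ed$sequence, mutations = mut))
  }
  stop("no eligible edit found for category ", category,
       " (generation error)")
}

#' Apply background somatic hypermutation
#'
#' Site-independent substitution: each nucleotide mutates with probability
#' `rate` times the factor of any covering position-set multiplier, the
#' substituted base uniform over the three alternatives. This is a neutral
#' background process, not an AID motif model; category control is achieved
#' by explicit injection.
#'
#' @param sequence_nt Nucleotide sequence.
#' @param rate Per-site substitution probability in `[0, 1]`.
#' @param multipliers Optional list of `list(positions = <aa positions>,
#'   factor = <relative rate>)`.
#' @param seed Optional integer seed; NULL draws from the current stream.
#' @return List: `sequence`, `mutations` (tibble nt_position/ref/alt).
#' @export
apply_shm <- function(sequence_nt, rate, multipliers = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  core <- shm_core(sequence_nt, shm_site_rates(rate, nchar(sequence_nt),
                                               multipliers))
  list(
    sequence = core$sequence,
    mutations = tibble::tibble(nt_position = core$hits,
                               germline_nt = core$ref,
                               observed_nt = core$alt)
  )
}

shm_site_rates <- function(rate, L, multipliers = NULL) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  p <- rep(rate, L)
  for (m in multipliers) {
    nt_sites <- as.vector(vapply(m$positions,
                                 function(a) (3L * a - 2L):(3L * a),
                                 integer(3)))
    nt_sites <- nt_sites[nt_sites <= L]
    p[nt_sites] <- pmin(rate * m$factor, 1)
  }
  p
}

# Lean substitution core shared by apply_shm and the simulator loop.
shm_core <- function(sequence_nt, p) {
  L <- nchar(sequence_nt)
  hits <- which(stats::runif(L) < p)
  if (length(hits) == 0L) {
    return(list(sequence = sequence_nt, hits = integer(0),
                ref = character(0), alt = character(0)))
  }
  bases <- strsplit(sequence_nt, "")[[1]]
  ref <- bases[hits]
  alt <- substitute_bases(ref)
  bases[hits] <- alt
  list(sequence = paste(bases, collapse = ""), hits = hits,
       ref = ref, alt = alt)
}

random_junction <- function(aa_len) {
  # junction = conserved Cys anchor + random non-stop interior + Trp anchor
  interior <- aa_len - 2L
  codons <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  paste0("TGT",
         paste(sample(codons, interior, replace = TRUE), collapse = ""),
         "TGG")
}

draw_clone_sizes <- function(n_sequences, law) {
  sizes <- integer(0)
  total <- 0L
  draw <- switch(law$law,
    zipf = {
      k <- seq_len(law$max_size)
      p <- k^(-law$alpha)
      function(m) sample.int(law$max_size, m, replace = TRUE, prob = p)
    },
    negative_binomial = function(m) {
      1L + stats::rnbinom(m, mu = law$mu, size = law$size)
    },
    stop("unknown clone_size_law: ", law$law)
  )
  while (total < n_sequences) {
    batch <- draw(max(16L, ceiling((n_sequences - total) / 2)))
    sizes <- c(sizes, batch)
    total <- total + sum(batch)
  }
  cum <- cumsum(sizes)
  n_clones <- which(cum >= n_sequences)[1]
  sizes <- sizes[seq_len(n_clones)]
  sizes[n_clones] <- sizes[n_clones] - (cum[n_clones] - n_sequences)
  sizes[sizes > 0L]
}

#' Simulate an AIRR repertoire with ground truth
#'
#' Draws clones with sizes from the configured clone-size law; each clone
#' receives a V gene, J gene, a random in-frame junction flanked by the
#' conserved anchors, an optional implanted hotspot mutation defining its
#' idiotope category, and members that accumulate background SHM over the V
#' region and draw an isotype. Non-productive members are generated by
#' frameshifting the junction. The same seed yields byte-identical output.
#'
#' @param config A `simulation_config`.
#' @param germlines Named list of `germline_reference` objects covering all
#'   V genes in the usage map (default: the packaged synthetic family).
#' @param scheme Hotspot scheme used for category injection.
#' @return List: `set` (rearrangement set), `truth` (per-sequence tibble
#'   with true clone_id, category, implanted mutations, isotype,
#'   productive flag), `config` (the resolved configuration).
#' @export
simulate_repertoire <- function(config,
                                germlines = synthetic_germline_set(),
                                scheme = hotspot_scheme()) {
  stopifnot(inherits(config, "simulation_config"))
  missing_germ <- setdiff(names(config$v_usage), names(germlines))
  if (length(missing_germ)) {
    stop("v_usage references genes without a germline reference: ",
         paste(missing_germ, collapse = ", "))
  }
  set.seed(config$seed, kind = "Mersenne-Twister", sample.kind = "Rejection")

  sizes <- draw_clone_sizes(config$n_sequences, config$clone_size_law)
  n_clones <- length(sizes)
  v_genes <- sample(names(config$v_usage), n_clones, replace = TRUE,
                    prob = config$v_usage)
  j_genes <- sample(names(config$j_usage_effective), n_clones, replace = TRUE,
                    prob = config$j_usage_effective)
  jlens <- as.integer(sample(names(config$junction_length_law), n_clones,
                             replace = TRUE,
                             prob = config$junction_length_law))
  categories <- if (is.null(config$category_mix)) {
    rep("GERMLINE", n_clones)
  } else {
    sample(names(config$category_mix), n_clones, replace = TRUE,
           prob = config$category_mix)
  }

  total_n <- sum(sizes)
  seq_v <- character(total_n)
  junc_v <- character(total_n)
  jaa_v <- rep(NA_character_, total_n)
  prod_v <- logical(total_n)
  iso_v <- character(total_n)
  vcall_v <- character(total_n)
  jcall_v <- character(total_n)
  clone_v <- character(total_n)
  cat_v <- character(total_n)
  vgene_v <- character(total_n)
  jgene_v <- character(total_n)
  impl_v <- character(total_n)
  nshm_v <- integer(total_n)
  pos <- 0L
  for (cl in seq_len(n_clones)) {
    germ <- germlines[[v_genes[cl]]]
    v_nt <- germ$sequence_nt
    impl_str <- ""
    if (categories[cl] != "GERMLINE") {
      inj <- inject_hotspot_mutations(v_nt, categories[cl], scheme)
      v_nt <- inj$sequence
      impl_str <- paste(sprintf("%d:%s>%s", inj$mutations$nt_position,
                                inj$mutations$germline_nt,
                                inj$mutations$observed_nt),
                        collapse = ";")
    }
    junction <- random_junction(jlens[cl])
    stub <- J_STUBS[[j_genes[cl]]]
    size <- sizes[cl]
    idx <- pos + seq_len(size)
    pos <- pos + size
    iso_v[idx] <- sample(names(config$isotype_probs), size, replace = TRUE,
                         prob = config$isotype_probs)
    nonprod <- stats::runif(size) < config$nonproductive_fraction
    p_site <- shm_site_rates(config$shm_rate, nchar(v_nt),
                             config$hotspot_multipliers)
    for (i in seq_len(size)) {
      core <- shm_core(v_nt, p_site)
      nshm_v[idx[i]] <- length(core$hits)
      if (nonprod[i]) {
        extra <- sample(DNA_BASES, 1L)
        jx <- paste0(substr(junction, 1, 3), extra,
                     substr(junction, 4, nchar(junction)))
      } else {
        jx <- junction
      }
      junc_v[idx[i]] <- jx
      seq_v[idx[i]] <- paste0(core$sequence, jx, stub)
    }
    prod_v[idx] <- !nonprod
    vcall_v[idx] <- germ$allele_name
    jcall_v[idx] <- paste0(j_genes[cl], "*01")
    clone_v[idx] <- sprintf("true_clone%05d", cl)
    cat_v[idx] <- categories[cl]
    vgene_v[idx] <- v_genes[cl]
    jgene_v[idx] <- j_genes[cl]
    impl_v[idx] <- impl_str
  }
  if (any(prod_v)) jaa_v[prod_v] <- translate_nt(junc_v[prod_v])
  ids <- sprintf("%s_seq%06d", config$subject_id, seq_len(total_n))
  set <- new_rearrangement_set(
    tibble::tibble(
      sequence_id = ids,
      sequence = seq_v,
      locus = "IGH",
      v_call = vcall_v,
      j_call = jcall_v,
      c_call = iso_v,
      junction = junc_v,
      junction_aa = jaa_v,
      productive = prod_v,
      duplicate_count = 1L,
      subject_id = config$subject_id,
      subset_label = config$subset_label
    ),
    provenance = list(source = sprintf("simulate_repertoire(seed=%d)",
                                       config$seed),
                      log = character())
  )
  truth <- tibble::tibble(
    sequence_id = ids,
    clone_id = clone_v,
    category = cat_v,
    v_gene = vgene_v,
    j_gene = jgene_v,
    isotype = iso_v,
    productive = prod_v,
    implanted_mutations = impl_v,
    n_shm = nshm_v
  )
  list(set = set, truth = truth, config = config)
}
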