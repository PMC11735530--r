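---
title: "Methods: VH4-34 repertoire skew and idiotope hotspot analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VH4-34 repertoire skew and idiotope hotspot analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vh4rep)
```

## The scientific problem

The germline-encoded IGHV4-34 heavy chain is intrinsically self-reactive: it
binds the I/i blood-group glycans displayed on red cells and B cells. Its
self-reactivity is carried not by the CDR3 but by a framework-1 "hydrophobic
patch" — the A24-V25-Y26 triplet assisted by Q6/W7 — which also forms the
epitope of the 9G4 anti-idiotype antibody. Two further sites modulate
avidity: the CDR2 N-glycosylation sequon N57-H58-S59 and the framework-3
K90-L91-S92 triplet. In healthy donors, IGHV4-34 B cells that survive into
memory usually carry replacement mutations at these hotspots; a memory
repertoire in which IGHV4-34 clones remain germline at the patch is a
signature of disturbed tolerance, as reported in hypomorphic RAG deficiency.

`vh4rep` implements the complete analysis chain used to quantify this
signature from AIRR rearrangement tables, plus the repertoire-level skew
statistics that accompany it (Chao1 richness, V-J pairing usage, CDR3
length and physicochemistry, distal-JH usage), and a synthetic-repertoire
generator with ground truth so every stage is testable without access to
patient sequence data.

## Mutation profiling and idiotope classification

Each transcript is aligned to its germline V gene with a Needleman-Wunsch
alignment that is global in the germline and local in the read
(`Biostrings::pairwiseAlignment`, `type = "local-global"`), so the junction
and downstream constant-region sequence never distort the V alignment.
Mismatch columns map one-to-one onto 1-based germline coordinates. Silent
versus replacement status is decided by translating the *whole* observed
codon, so double-hit codons are called correctly. Codons disrupted by
deletions yield no per-site calls; any indel marks the profile and routes
it to `UNCLASSIFIABLE`. Ambiguous bases (N) at mismatch sites are skipped
and tallied rather than guessed. Alignments below a configurable identity
floor (default 70%) are treated as gene misassignments.

Classification is a precedence rule over the hotspot scheme:

AVY > NHS > KLS > OTHER_REPLACEMENT > SILENT_ONLY > GERMLINE

A replacement anywhere in A24-V25-Y26 dominates, then the N-glycosylation
site, then K90-L91-S92; remaining replacements give `OTHER_REPLACEMENT`,
silent-only profiles `SILENT_ONLY`, untouched sequences `GERMLINE`. The
precedence order mirrors the biological salience of the sites (patch
ablation removes 9G4 reactivity outright); because the order is a design
choice, the profiler also emits independent `hits_avy` / `hits_nhs` /
`hits_kls` flags from which any alternative precedence can be re-derived.
Q6/W7 is excluded from the AVY trigger by default and folded in via
`include_aux_in_avy = TRUE`.

Hotspot positions are 1-based indices in the translated mature V region,
taken as linear numbering; any alternative numbering can be supplied
through `hotspot_scheme()`. Classification is per unique clone: transcript
collapsing (identical on sequence, isotype, subject and subset; counts
summed) precedes profiling, which both removes amplification bias and keeps
isotypes distinct.

### The synthetic germline family

The packaged references are constructed sequences, not database alleles:
a 98-residue V-region scaffold whose IGHV4-34-like member carries Q6, W7,
A24-V25-Y26, N57-H58-S59 and K90-L91-S92 at exactly those linear positions,
with region bounds placing AVY in FR1, NHS in CDR2 and KLS in FR3. Filler
residues exclude Met and Trp so every non-hotspot codon admits a synonymous
single-nucleotide edit, which the generator exploits when implanting
`SILENT_ONLY` clones. Six further scaffolds with shifted filler cycles act
as background V genes. Using a constructed family keeps the package
self-contained and the hotspot coordinates exact; analyses of real data
should supply the IMGT germline set through `read_germline_reference()`.

## Clonal inference

Rearrangements are partitioned by (V gene, J gene, junction length);
within a partition, clones are clusters under normalized junction Hamming
distance at a threshold (default 0.15, the conventional junction-identity
cutoff for heavy chains). Single linkage — the default — is defined as the
connected components of the graph with edges at distance ≤ threshold;
complete linkage cuts a complete-linkage dendrogram at the same height.
Hamming rather than edit distance is used because equal-length partitions
make alignment unnecessary and this is the standard convention for clonal
grouping. Clone identifiers are deterministic (clones ordered by partition
key and smallest member id), sampling of clone groups uses R's
Mersenne-Twister under an explicit seed, and all tie-breaks are
lexicographic, so outputs are byte-stable across runs and platforms.

Connectivity graphs carry one node per member sequence (annotated with
clone, category, isotype and duplicate count) and edges between same-clone
members whose junctions differ by at most `edge_rule` nucleotides
(default 1). Published clonal-network displays differ in whether they
connect sequences by junction distance or by shared V mutations, so the
edge rule is exposed as a parameter rather than fixed.

Top-clone enumeration ranks unique heavy-chain V-region amino-acid
sequences by the number of distinct CDR3s observed with them — recurrent
germline heavy chains with many private CDR3s indicate selection of the
unmutated receptor — with per-isotype counts of distinct (CDR3, isotype)
pairs.

## Repertoire statistics

* **Chao1.** `chao1_estimate()` implements both the classic form
  `S_obs + f1²/(2 f2)` and the bias-corrected form
  `S_obs + f1(f1−1)/(2(f2+1))`; bias-corrected is the default and classic
  falls back to it when `f2 = 0`, where the classic form is undefined.
  Diversity is computed over unique CDR3 sequences, nucleotide-level by
  default (`level = "aa"` switches), with each collapsed record counting
  once ("clone" weighting) or by `duplicate_count` ("duplicate").
* **V-J usage.** Percent of total V-J pairs per gene-level cell, summing
  to 100; non-productive rearrangements are included by default because
  pre-selection skew is visible only when they are retained.
* **CDR3 length and physicochemistry.** CDR3 is the junction minus the
  two conserved anchors (Cys-104, Trp/Phe-118); trimming is toggleable.
  Hydrophobicity uses the Kyte–Doolittle index by default; any named
  per-residue vector drops in.
* **Distal-J usage.** Fraction of records using JH5/JH6, whose loss marks
  impaired recombination.

## The generator and what it emulates

`simulate_repertoire()` draws clones with sizes from a Zipf law (exponent
`alpha`, truncated at `max_size`), assigns each clone a V gene, J gene,
random in-frame junction flanked by the conserved anchor codons, an
idiotope category implanted as a minimal single-nucleotide edit, and
members that accumulate background SHM (site-independent substitution with
optional position-set multipliers) and draw an isotype. Non-productive
members are produced by frameshifting the junction. Every sequence has a
ground-truth record, and a fixed seed gives byte-identical output.

Two presets encode the contrast the analyses are designed to detect, with
parameters fixed at the values the study context reports or, where
unreported, at conventional values chosen once:

| knob | HD-like | IIe-like | basis |
|---|---|---|---|
| IGHV4-34 fraction | 0.07 | 0.50 | healthy naive ~5–10%; affected sibling ~half the repertoire |
| distal-J depletion | 1.0 | 0.5 | reduced JH5/JH6 in affected siblings (baseline distal mass 0.30) |
| Zipf exponent | 3.0 | 1.5 | singleton-dominated vs oligoclonal expansion |
| category mix | 25% germline, 45% AVY/NHS | 45% germline, 2% AVY, elevated KLS/other/silent | ~25% unmutated in HD; KLS/other/silent-dominated, AVY-poor in the affected sibling |
| isotypes | IgM 0.60 | IgM 0.90 | expanded population is overwhelmingly IgM |
| background SHM | 0.002/nt | 0.002/nt | low memory-compartment load |

The depletion factor multiplies the distal-J mass and redistributes the
removed mass over non-distal genes, so the realised distal fraction is
exactly `baseline × factor` (0.15 for the IIe preset).

Deliberate simplifications: junctions are random in-frame sequences, not
TdT/exonuclease-modelled VDJ joints — sufficient for distance-based clonal
logic but without real junction microhomology structure; SHM is
site-independent, not an AID WRC/GYW motif model — category control is by
explicit injection, and with nonzero background SHM the *implanted*
category is a lower bound, since background replacements can promote a
clone up the precedence (this is visible, and correct, in collapsed
category tables where SHM variants of large germline clones surface as
`OTHER_REPLACEMENT`/`SILENT_ONLY`); within a clone the junction is held
fixed and SHM applies to the V region only, so clone recovery against
truth is exact at zero noise. Passing tests on these simulations therefore
validates the *computational* contracts — coordinates, precedence,
partitions, estimators, determinism — not biological realism of mutation
spectra.

Parameter-recovery checks (gene fractions, distal-J mass) use
singleton-clone configurations (`max_size = 1`) so the observed fraction
is an exact binomial draw and "within 3 binomial standard errors" is the
correct yardstick; under heavy-tailed clone sizes the record-level
fraction is not binomial in n.

## Numerical and procedural choices

* Alignment scoring: match +1, mismatch −2, gap open 6, extend 2 — favours
  substitution calls over spurious gaps at SHM-like divergence. Gapless
  alignments take a fast path that maps the read substring directly onto
  germline coordinates; gapped ones reconstruct the full gapped strings.
* Distance comparisons use `≤ threshold` on `k/L`; implementation and the
  brute-force test oracle compute the ratio identically, so boundary cases
  (e.g. 3 mismatches in a 20-nt junction at threshold 0.15) agree exactly.
* Degenerate inputs: empty abundance vectors, empty sets after filtering,
  junctions shorter than the anchors and unknown residues raise errors or
  are excluded-and-tallied, never silently dropped.
* Problem sizes: property tests run at hundreds of records, recovery and
  preset contrasts at 10,000 sequences, the clonal-grouping oracle at 100
  instances of ≤200 sequences — sizes at which every binomial tolerance
  above is meaningful and the full suite stays comfortably interactive.

## Known limitations

Profiling covers FR1–FR3 of the V region only; junction/CDR3 mutations
never influence idiotope category (by design — self-reactivity resides in
the framework patch). Published hotspot-category fractions are sometimes
clone-weighted and sometimes transcript-weighted; this package fixes
clone-weighting (collapse first) and documents it. Real-data
comparisons additionally require IMGT germlines and an upstream V/J
annotator (e.g. an IgBLAST-style tool); raw-read processing, UMI consensus,
light chains and lineage-tree inference are out of scope.
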