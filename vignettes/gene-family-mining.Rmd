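---
title: "Mining gene families in fish genomes: models, thresholds and design choices"
author: "gobymine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining gene families in fish genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gobymine)
```

# Scope

`gobymine` packages the bespoke computational procedures that large
gene-family studies of teleost genomes tend to re-invent ad hoc: turning
translated-homology searches into gene models, classifying genes by motif
and domain content, calling lineage-specific expansions on phylogenies,
predicting opsin spectral sensitivity from key sites, and screening RAD-seq
data for sex-determining regions. The package consumes the *outputs* of
standard external tools (BLAST tabular hit tables, domain-scanner tables,
Newick trees, Stacks-style count matrices); it never runs an aligner or
tree builder itself. A seeded simulator family generates inputs with known
ground truth so that every procedure is testable offline.

# From hit table to gene model

A tblastn search of a protein family against a genome yields high-scoring
segment pairs (HSPs). The reconstruction proceeds in four deterministic
steps.

**E-value gate and per-locus deduplication.** Hits with e-value above
`max_evalue` (default `1e-50`; the informal spelling "10e-50" in methods
sections is read as \(1\times10^{-50}\)) are discarded. Then, wherever
several surviving HSPs overlap on the genomic subject (same contig, either
strand), only the highest-bit-score HSP is kept. We resolve greedily from
the highest score downward; ties break by lower e-value, then query id,
then genomic start, making the output invariant to input order. This
operationalizes "one hit per genomic position": after deduplication no two
surviving subject intervals overlap, so downstream chaining is
strand-unambiguous.

**Exon chaining.** Within each (contig, strand, query) group, HSPs sorted
into transcription order are joined into one multi-exon model when every
consecutive pair satisfies both rules:

* query coordinates advance (`q_start` strictly increasing) with an
  inclusive overlap `prev_q_end - next_q_start + 1` of at most
  `max_query_overlap_aa` (default 15 aa; we read "maximum overlap of 15"
  as inclusive, so 15 joins and 16 does not);
* the genomic gap between adjacent subject intervals is non-negative and
  strictly below `max_genomic_gap_bp` (default 10 000 bp, an exclusive
  bound: a 9 999 bp intron joins, 10 000 does not).

Each maximal joinable run becomes one model; singletons become single-exon
models. Chaining is per query protein: because deduplication precedes it,
models from different queries can never share genomic positions, and we do
not merge across queries. For small inputs the greedy 5'-to-3' chaining is
provably identical to an exhaustive search over run partitions, and the
test suite checks exactly that equivalence on hundreds of random cases.

**Translation.** The concatenated exon sequence (reverse-complemented for
minus-strand models) is translated by a deterministic longest-ORF rule:
the longest ATG-initiated open reading frame across the three forward
frames of the CDS, falling back to the longest stop-free stretch of the
frame-0 translation (flagged `no_start`) when no ATG exists. This replaces
an external ORF caller with something reproducible; models additionally
carry `internal_stop` and `no_stop` flags so users can treat putative
pseudogenes differently. We deliberately do not model splice sites or
repair frameshifts - the exon boundaries are evidence-driven (they come
from the HSPs), and adjusting them would blur what the homology evidence
actually supports.

**Length filter.** Models translating to fewer than `min_protein_len_aa`
residues (default 250 aa - roughly the central transmembrane core of an
olfactory receptor) are removed; 250 aa is retained, 249 aa is not.

For homolog screens that accept or reject whole hits rather than building
models (e.g. osmoregulatory families), `filter_orthologs()` applies
inclusive coverage (>= 70% of the query) and identity (>= 40%) bounds with
a strict e-value bound (< 1e-20), matching the usual phrasing "at least
70% ... at least 40% ... e-value < 1e-20".

# Motif and domain classification

**PROSITE matcher.** Patterns support literals, `x` wildcards, `[..]`
alternatives, `{..}` exclusions, `e(n)`/`e(n,m)` repetitions and `<`/`>`
anchors, plus - as an extension needed by published Walker A motif
tables - parenthesized alternations of residue strings like `(IP/TA)`.
Matching is a direct backtracking interpreter with greedy repetition and
leftmost non-overlapping semantics, so results coincide with what a greedy
regular-expression engine reports; the test suite verifies this agreement
against an independently written regex translation on 1 000 random
pattern/sequence pairs. Building the matcher directly (rather than
translating to a regex internally) keeps that cross-check meaningful.

**CYP completeness.** Cytochrome P450 genes are classified from four
conserved motifs (I-helix, K-helix, meander coil, heme-binding loop):
missing any motif means `fragment`; with all motifs present, a gene is
`complete` when its length is within `full_length_aa +/- tolerance_aa`
(default 500 +/- 50 aa - the "~500 aa" of the literature demands an
explicit band), starts with methionine, terminated at a stop codon, and
matched the family profile HMM; otherwise it is `partial` (intact
motif-bearing ~120 aa core, clearly less than full length). One edge the
verbal definition leaves open: a full-length gene with all motifs but
missing start/stop/HMM evidence is neither literally complete nor
literally "clearly less than full length"; we classify it `partial` as the
conservative downgrade, which also keeps the call monotone - removing
evidence can never move a gene toward `complete`. The shipped motif
patterns are surrogate consensus shapes (the original accessions are not
public); they are defaults in `cyp_motif_patterns()` and every analysis
accepts replacements. Profile-HMM scoring is out of scope by design:
`has_hmm_match` is an input, so the decision rule stays testable without
re-implementing HMMER.

**NLR-C groups.** The six fish NLR-C groups are identified by conserved
Walker A motifs plus whether members may carry an N-terminal PYD and/or
C-terminal B30.2 domain (groups 1, 2 and 5 may carry both; 3 only B30.2;
4 and 6 neither). `classify_nlr_group()` returns the unique group whose
motif matches and whose domain allowances are consistent with the
protein's observed domains - a present-but-disallowed domain vetoes a
group, absence never does. Ambiguity or no match yields `"unassigned"`
rather than a guess. The test suite cross-classifies one exemplar motif
per group against all six patterns (6 x 6) to guarantee the patterns are
mutually exclusive on their own exemplars.

**ASC adaptors.** The inflammasome adaptor architecture is a PYD domain
immediately followed by a CARD. "Immediately" means no other annotated
domain in between - a positional criterion, not a residue-distance one
(an optional `max_gap_aa` exists but defaults to unlimited). The screen
depends only on domain order and adjacency, never on scores.

# Lineage-specific expansions

On a gene tree whose leaves are labelled with species, an expansion is a
maximal monophyletic clade whose leaves all belong to one species (or one
merged species group) with at least `min_size = 5` gene copies - "five or
more genes of the same species"; four is not an expansion. Maximality
means the parent clade is not monospecific, so the returned clades
(including singletons) always partition the leaf set - a convenient
invariant that the tests assert and that a brute-force scan over all
clades confirms on hundreds of random trees.

Species merges (`apply_species_equivalence()`) let a sister species with a
poor assembly count toward the focal lineage, reproducing the common
"allow species B inside species A's expansions" adjustment; merging can
only coarsen the partition, never shrink a clade. Unrooted input trees are
midpoint-rooted when branch lengths exist (a neutral stand-in for the
original outgroup rooting; re-root externally to reproduce a specific
outgroup choice). Near-monospecific clades with one stray leaf are
strictly non-monospecific: we report no fuzzy rescue, because any such
tolerance would need a justification the source procedures do not supply.
Bootstrap values do not gate calls.

# Opsin spectral tuning

LWS opsin sensitivity is predicted by the additive five-sites rule: key
residues at bovine-rhodopsin positions 164/181/261/269/292 determine
lambda-max relative to an ancestral pigment (`SHYTA`, 560 nm). The shipped
substitution table carries the classical entries S164A (-7), H181Y (-28),
Y261F (-10), T269A (-15) and A292S (-27 nm); only the Y261F entry is
exercised by the goby LWS1/LWS2 comparison (560 vs 550 nm, a 10 nm
predicted shift), and the others are clearly literature defaults that can
be overridden or replaced wholesale. Key sites are located either by
explicit query-numbering positions or through a gapped pairwise alignment
against a bovine-numbered reference; a deletion over a key site becomes
`-` with a warning at extraction and a hard error at prediction, because
silently imputing a residue would fabricate a phenotype. Unknown
substitutions contribute 0 nm but are recorded in the prediction's
`notes` attribute - the model is a lookup table, not a regression, and
pretending otherwise would overstate it. Predictions are site-order
invariant and translation-equivariant in the baseline by construction;
both properties are tested.

# RAD-seq sex screen

Samples must exceed 150 000 reads (strictly: a sample at exactly the
threshold is dropped). A locus is sex-specific when it is present (count
>= 1 by default) in at least one individual of the focal sex and in at
most `max_other_sex_presence` individuals of the other sex; the default 0
is the strict "present exclusively" reading, and the tolerance knob exists
only because real RAD data has dropout. Interpretation is tiered: zero
sex-specific loci means nothing detected; one or more indicates a
contiguous sex-determining region at least as large as the expected
marker spacing; on the order of hundreds (default threshold 100) indicates
a sex chromosome.

The expected-density arithmetic divides genome size by locus count and
locus count by chromosome number, rounding half away from zero. With a
1 Gb genome, 21 877 loci and 23 chromosomes this yields one locus per
45 710 bp and 951 markers per chromosome (2 140 markers with the
49 220-locus call set) - the published worked example, recomputed by the
acceptance tests. The published companion figure "20316" appears to be a
truncation rather than a rounding of 1e9/49 220 = 20 316.9; we do not
chase it with a second rounding rule.

# What the simulators emulate - and what they do not

All generators are pure functions of a spec plus a seed (byte-identical
reruns), and each returns machine-readable truth.

* `simulate_genome_with_families()` implants ATG-initiated multi-exon
  ORFs into random background sequence at a configurable GC content
  (default 0.416, a typical teleost value). Exons are codon-aligned, so
  hit tables derived from the truth carry clean protein coordinates, and
  the truth's exon intervals are CDS spans in the GFF3 sense (stop codon
  inside the last exon). Introns default to 200-2 000 bp, safely below
  the 10 kb chaining bound; ranges above 10 kb exist to exercise the
  negative case.
* `emit_truth_hsps()` emits one HSP per implanted exon, optionally
  splitting exon hits into still-chainable pieces (<= 15 aa overlap) and
  adding spurious background hits whose bit scores sit strictly below
  true scores and whose e-values sit above the default gate. This
  emulates the *decision structure* of a real tblastn result - a hard
  e-value gate separating signal from noise - not its score
  distributions. Recovery under this noise is a construction property,
  not a statistical claim.
* `simulate_expansion_tree()` grafts monospecific subtrees onto a random
  background gene tree (graft points are background leaf edges, so
  planted clades stay monophyletic). There is no sequence evolution and
  no tree-inference error; a green recovery test establishes that the
  clade logic is right, not that expansions survive phylogenetic
  uncertainty.
* `simulate_rad_matrix()` defaults mirror a 47-male/45-female,
  ~21 877-locus design with per-sample totals comfortably above the read
  filter. Background loci are present everywhere (shifted-Poisson counts)
  with independent dropout (default rate 0.05; the recovery tests use 0,
  the stated zero-noise condition); planted sex-linked loci are
  structurally absent from the other sex and never subject to dropout.
  Real RAD dropout is locus- and depth-correlated; this generator's
  dropout is i.i.d. and exists to exercise thresholds, not to model
  library chemistry.

# Numerical and interface choices

* Internal genomic coordinates are 0-based half-open on the forward
  strand; BLAST tabular and GFF3 conventions (1-based inclusive,
  minus-strand encoded by swapped subject coordinates) are converted at
  I/O boundaries only.
* All greedy resolutions and orderings have total, documented tie-breaks
  (bit score desc, e-value asc, query id asc, genomic start asc), so every
  result is reproducible regardless of input order.
* Newick serialization orders children by smallest descendant leaf name,
  giving canonical output (isomorphic trees serialize identically).
* Configuration files for the command-line front end are JSON rather than
  YAML (no YAML parser is part of the package's dependency footprint);
  the R API takes plain argument lists.
* The command-line interface (`inst/cli/gobymine.R`) is a thin veneer
  over the exported functions; the functions themselves are the primary
  interface.

# Limitations

* Exon boundaries are homology-driven; no splice-site model corrects
  them, so terminal exons can be truncated where homology decays.
* The CYP motif defaults are surrogates; curated patterns should replace
  them for publication-grade CYP inventories.
* The tuning model covers LWS only; RH1/RH2/SWS tables can be supplied
  via `tuning_model()` but are not shipped.
* The expansion caller trusts the input topology; it performs no
  reconciliation or duplication dating.
* The RAD screen detects presence/absence signal only; it is blind to
  sex-linked loci that are present in both sexes at different depths.
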