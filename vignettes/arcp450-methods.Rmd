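---
title: "Annotating archaeal P450s and their redox partners with arcp450"
author: "arcp450 authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating archaeal P450s and their redox partners with arcp450}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcp450)
```

## What the package computes

Cytochrome P450 monooxygenases (CYPs/P450s) form a heme-thiolate enzyme
superfamily with a standardised nomenclature: `CYP` + family numeral +
subfamily letter + member numeral, where proteins above 40% pairwise
identity share a family and proteins above 55% share a subfamily.
Prokaryotic P450s depend on small iron–sulfur electron carriers
(ferredoxins) and on ferredoxin reductases such as the two-subunit
2-oxoacid:ferredoxin oxidoreductase (OFOR). Comparative questions about
these proteins — which families are expanded, which co-occur in the same
species, how members split between chromosomes and plasmids, whether redox
partners are co-transcribed with P450s — all reduce to a reproducible
annotation pipeline over proteomes, gene coordinates and replicon
metadata. `arcp450` implements that pipeline end to end:

1. **Motif screen** (`screen_proteome`): P450 candidates must carry the
   K-helix EXXR tetrad and the heme-ligating CXG tripeptide; candidates
   shorter than 350 aa (or missing a motif) are fragments and are excluded
   from classification.
2. **Identity engine** (`global_align`, `identity_matrix`): affine-gap
   global alignment and percent identity — the quantitative basis of the
   nomenclature thresholds.
3. **Nomenclature** (`assign_families`): placement against a named
   reference set, de-novo single-linkage family/subfamily clustering, and
   label finalisation.
4. **Ferredoxin typing** (`classify_ferredoxins`, `annotate_subtypes`):
   Fe–S cluster types from declarative cysteine-spacing grammars, plus a
   persistent subtype registry; OFOR subunits by annotation keywords and
   gene adjacency (`find_ofor`).
5. **Genome context** (`predict_operons`, `p450_operon_context`,
   `copresence_counts`, `replicon_family_comparison`,
   `family_saturation`): operons and replicon-aware comparative tables.
6. **Phylogeny stage** (`identity_to_distance`, `nj_tree`,
   `write_newick`): a neighbor-joining tree over identity distances.
7. **Synthetic studies** (`generate_study`): seed-deterministic data with
   complete ground truth, used to validate every stage.

`run_pipeline()` wires the stages together and writes one TSV per result
plus a JSON manifest, so a run is fully self-describing.

## The alignment model and why it is fixed the way it is

Percent identity is only meaningful relative to an alignment model, and
published family assignments rarely state one. The package fixes a single
default, applied everywhere and recorded in the manifest:

| parameter | default | rationale |
|---|---|---|
| substitution table | BLOSUM62 | the de-facto standard for protein identity work |
| gap open / extend | 10 / 0.5 | EMBOSS-needle-style costs; a gap of length L costs `open + L·ext` |
| terminal gaps | free | domain-sized length differences should not be penalised |
| identity denominator | scored columns | columns between the first and last residue-pair column; terminal overhangs excluded |

Every choice is a knob on `align_params()`, so alternative conventions
(shorter-sequence or full-alignment-length denominators, strict global
alignment) can be reproduced. Threshold comparisons downstream are
*inclusive* (≥ 40, ≥ 55): the nomenclature convention's prose ("more than
40%", "less than 40%") leaves exactly-at-threshold undefined, and the
inclusive reading is applied uniformly.

The aligner itself is a three-state Gotoh dynamic program (compiled code)
with deterministic tie-breaking: residue columns are preferred over gaps,
and gaps in the first sequence over gaps in the second. Its scores are
verified in the test suite against two independent routes — an exponential
brute-force enumeration of all alignments on short sequences, and
`Biostrings::pairwiseAlignment` on strict-global problems.

Empirically, under this model unrelated random 450-aa proteins score
~13–22% identity, comfortably below the 40% family threshold; this is what
makes identity-threshold clustering workable at all.

## Nomenclature decisions

* **Single linkage** realises the pairwise rule ("above 40% → same
  family") transitively, which is how the convention is applied in
  practice. Chaining is a real risk of single linkage, so any component
  whose *minimum* internal identity falls below the threshold is reported
  with a warning rather than silently accepted.
* **Conflicts**: when references from two different families both clear
  the family threshold, the best hit wins and the assignment is flagged
  `conflict = TRUE`; the underlying identities are reported so such cases
  stay auditable.
* **Novel families** receive a neutral `CYPN1`, `CYPN2`, … prefix in
  component order (smallest member id first). Official CYP numbers are
  allocated by the nomenclature committee and are deliberately not
  guessed; a collision between a generated label and a reference family
  label is an error, not a silent rename.
* **New subfamilies** inside a known family continue the reference
  lettering (A, B, …, Z, AA, …), and member numbering continues after the
  largest reference member number.

## Ferredoxin grammars

Ferredoxin types are defined by the cysteines that ligate the Fe–S
cluster; subtypes by the exact residue spacing between them. The scanner
consumes a *declarative* rule set — per cluster class, the cysteine count
and an allowed range for each inter-cysteine gap:

| class | cysteines | spacing ranges |
|---|---|---|
| 4Fe-4S (bacterial type) | 4 | (2, 2, 3–40) |
| 2Fe-2S (plant/adrenodoxin type) | 4 | (4–6, 2, 20–40) |
| 3Fe-4S | 3 | (2–8, 3–40) |

Classes are tried in the order above, 4-cysteine classes first, so a
3-cysteine rule can never shadow a longer motif; within a flexible range
the nearest conforming cysteine is taken; accepted motifs never overlap
(greedy left-to-right). Composite types resolve before single-motif types:
two 4Fe-4S motifs give `2[4Fe-4S]`, one 3Fe-4S plus one 4Fe-4S give
7Fe-8S. The Alvin-type `2[4Fe-4S]Alv` — distinguished in the literature by
a long insertion before the terminal cysteine of the second cluster — is
split from the clostridial form when that final spacing reaches
`alv_min_last_spacing` (default 8). The primary literature defers exact
subtype-defining spacings to earlier ferredoxin surveys we do not ship;
the defaults above encode the canonical motif forms, and everything
downstream keys on *signatures* (e.g. `C-2-C-2-C-3-C`), which are
convention-free. Legacy subtype *numbers* can be injected through a
registry TSV; otherwise signatures are numbered sequentially per type.

## Operons and comparative statistics

Operon prediction is a deliberately transparent heuristic: maximal runs of
same-strand genes on one replicon with intergenic gaps ≤ 150 bp (1-based
inclusive coordinates; overlapping same-strand genes count as gap 0 with a
warning). This stands in for external transcription-unit predictors; the
pipeline's question — are ferredoxins or OFOR subunits co-transcribed with
P450s? — is qualitative, and the threshold is a parameter. Species
identity comes from the replicon metadata table, so multi-replicon species
aggregate correctly in co-presence counts and saturation curves. The
saturation curve is a permutation-averaged family-accumulation curve;
orderings are Monte-Carlo (seeded, default 100) with an exhaustive mode
that enumerates all N! orderings for N ≤ 8, used by the tests to pin the
estimator to exact values.

## The phylogeny stage

The tree stage is a stand-in for multiple-alignment plus model-based
inference, which are outside this package's scope: pairwise identity is
converted to distance (`d = 1 − identity/100`) and a classical
neighbor-joining tree is built (via `ape::nj`), with negative branch
estimates clamped to zero. NJ is exact on additive matrices — the test
suite verifies topology recovery on simulated trees — but identity
distances from real sequences are not additive, so resulting topologies
are illustrative context, not inference.

## What the synthetic generator emulates — and what it does not

`generate_study()` produces multi-species, multi-replicon studies with
planted P450 families (identity bands enforced by *measurement* through
the package's own identity engine, not by mutation-rate formulas),
truncated fragments, ferredoxins built from stated signatures, adjacent
OFOR gene pairs, decoys and operon-structured gene layouts. Choices a real
dataset would not give you:

* P450 seeds are 450 aa with `EALR` at 35% and `CIG` at 88% of the length;
  members are substitution-only variants (no indels), so within-family
  alignments are gapless and bands converge quickly.
* Non-P450 proteins are drawn from a reduced alphabet without R and G (and
  without C outside planted Fe–S motifs), so no signature motif can arise
  by chance and planted composition is recovered *exactly*. Real
  proteomes are noisier in both directions: real decoys can carry
  EXXR/CXG-like tripeptides, and real P450 fragments contain cysteines
  that can mimic Fe–S spacings (for this reason the pipeline's ferredoxin
  stage skips anything the P450 screen claimed).
* Within-family identity bands default to 62–70% pairwise, achieved by
  mutating members to `(100+band)/2` identity to a common seed; every new
  member is additionally verified against all previously generated
  families' members to stay below a cross-family ceiling (35% by default).
* Operon structure is a two-regime gap model (20–120 bp within, 300–900 bp
  between), far cleaner than real intergenic-distance distributions.

A green test on synthetic data therefore establishes that the *rules are
implemented correctly*, not that the rules are optimal for real archaeal
proteomes — motif-only screening without a domain-model pre-filter, in
particular, would be more permissive on real data than on these decoys.

## Numerical and degenerate-input conventions

* Percent identities are reported to 0.1; an alignment whose scored span
  is empty (pure cross-gap alignments) raises an error rather than
  returning 0/0.
* Nonstandard residues B/Z/U/O/J are mapped to X on input with a warning;
  `*` stop codons are stripped.
* Coordinates are 1-based inclusive on disk (GFF3 authority) and 0-based
  half-open internally; converters are exported and tested both ways.
* All stochastic steps (generator, saturation permutations) take explicit
  integer seeds; the same seed reproduces outputs byte for byte.
* Singleton inputs: a single unplaced query founds its own family; a
  singleton family is subfamily A; a lone gene is a singleton operon.

## Known limitations

* Family assignment quality is bounded by the reference set; with no
  references everything is de novo and labels are not comparable across
  runs on different inputs.
* The motif screen deliberately replaces profile/domain-model detection;
  on real data it should be fed a candidate list from such a tool when
  available (`screen_proteome(..., candidates = )`).
* Ferredoxin subtype *numbers* are registry-relative; only signatures are
  portable across studies.
* Identity-distance NJ trees are not phylogenetic inference (see above).

## A worked micro-example

```{r example, eval = FALSE}
study <- generate_study(default_study_spec(seed = 17))
res <- run_pipeline(run_config(seed = 17), out_dir = tempfile("arcp450_"),
                    records = study$records, features = study$features,
                    meta = study$meta)
res$screen          # 38 proteins: 14 full-length, 2 fragments, 22 not P450
count_families(res$assignments)  # CYPN1..CYPN4 with 5/4/3/2 members
head(res$fdx)       # ferredoxin types, signatures, subtype ids
res$saturation      # family accumulation over species permutations
```
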