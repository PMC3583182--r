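---
title: "Mining, curating and dating the WRKY transcription factor family"
author: "wrkyminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining, curating and dating the WRKY transcription factor family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrkyminer)
```

## The problem

Plant genomes encode on the order of a hundred WRKY transcription
factors. The family is defined by the WRKY domain: an invariant
heptapeptide (canonically `WRKYGQK`) followed, within a short window, by a
zinc finger — `C-x(4,5)-C-x(22,24)-H-x(1)-H` (C2H2) in Groups I and II, or
`C-x(7)-C-x(22,24)-H-x(1)-C` (C2HC) in Group III. Group I proteins carry
two domains; the subfamilies IIa–IIe and III carry one.

The property this package is built around is the family's conserved
gene structure: in the genome, nearly every WRKY domain is split by an
intron at one of exactly two positions —

* **PR class**: immediately after the codons of the invariant `PR`
  dipeptide, separating the heptapeptide-bearing exon from the zinc
  finger (Group I C-terminal domains, IIc, IId, IIe, III);
* **IIab class**: at the codon boundary five residues after the second
  cysteine of a `C-X5-C`, splitting the finger itself (IIa, IIb).

Only the Group I N-terminal domain is intronless. Automated gene
predictors break disproportionately often at this intron, which is why
family censuses built by exhaustive translated search plus manual curation
recover more (and more accurate) members than annotation pipelines. In
the curated *Brachypodium distachyon* table bundled here, 20 of 86
members have mispredicted or missing gene models.

`wrkyminer` mechanizes that workflow: a recall-first translated search, a
splice-aware domain reconstructor restricted to the two sanctioned intron
positions, structural subfamily classification, a gene-model audit, a
pseudogene detector, a tandem-array detector, and a small
neighbor-joining engine for the phylogenetic side of the analysis.

## The scanner model

**Seeding.** Every representative query domain is aligned against all six
reading frames of every chromosome with Smith–Waterman (BLOSUM62, affine
gaps 10/0.5), windowed (1500 residues, 120 overlap) for scale. The seed
threshold is deliberately permissive — 25% of each query's self-score
(`min_seed_score_frac`). The arithmetic behind that number: a split
domain exposes only its exon fragments to a single-frame alignment, and
the smaller half of a IIab-class domain is ~20 of ~60 residues, about a
third of the self-score; a threshold of 40% or more would systematically
miss exon-sized fragments, defeating the search's recall-first purpose.
Random background maxima over a megabase of six-frame translation sit
near 20% of a typical domain self-score, so 25% keeps noise manageable
while seeding fragments. Everything above threshold is reported; nothing
is filtered for completeness at this stage.

**Reconstruction.** Around each seed (one representative per overlapping
seed cluster) the scanner looks for heptapeptide anchors in all three
frames of the oriented window — up to one intron length upstream of the
seed, because a finger-side seed sits downstream of its heptapeptide, but
never downstream of the seed. For each anchor it first tries to complete
the domain within the frame; failing that, it enumerates canonical
`GT..AG` introns (20 bp–10 kb) anchored at exactly the two sanctioned
donor positions and tests whether the spliced translation completes the
domain. Two plausibility guards reject chance completions:

* `min_complete_score_frac` (0.5): a complete domain must align to its
  query at half the self-score or better;
* `min_splice_gain` (40 score units): a spliced completion must beat the
  best unspliced reading of the same anchor by a clear margin, because a
  chance acceptor can close the finger grammar while contributing nothing
  to the alignment.

The best reading is chosen per anchor (complete first, then score, then
stop-repaired readings, then shorter introns), and one hit per anchor is
returned. If nothing completes, the best incomplete reading survives as a
candidate pseudogene — never silently dropped. A reading that completes
once in-frame stops are ignored is marked `stop_broken`; that is exactly
the evidence later reported as `INTERNAL_STOP`.

**Merging.** Hits are deduplicated by overlap of their *first-exon*
footprints on the same strand, keeping the most complete then
highest-scoring representative. Anchoring on the first exon rather than
the whole footprint matters: a long-range spurious splice from one gene
can span a neighboring gene, and whole-footprint merging would let that
chimera swallow the neighbor.

**Extended fingers.** Some Group III members carry a 9–10 residue
insertion in the zinc-finger spacer. The matcher accepts the enlarged
spacer and reports the surplus as `finger_extension`. An observed spacer
of, say, 33 residues decomposes ambiguously (24 + 9 or 23 + 10); the
matcher prefers the modal canonical spacing (23), making the reported
extension well defined. Setting `allow_extension = FALSE` disables the
tolerance, and such domains are then reported incomplete.

## Classification, audit and pseudogenes

Subfamily assignment is a cascade of structural rules: two complete
domains → I; C2HC finger → III; IIab intron + C2H2 → {IIa, IIb}; PR intron
+ C2H2 → {IIc, IId, IIe}. The last two sets are structurally degenerate,
mirroring the fact that those splits are phylogenetic, not structural.
They are resolved by a supplied tree placement (`placements_from_tree()`
labels each query with the majority subfamily of the smallest clade
joining it to a labeled reference) and reported `tree-confirmed`, or by
nearest labeled reference domain and reported `ambiguous`. Without
references the degenerate groups stay `UNASSIGNED` rather than guessing.

The audit asks one machine-checkable question per locus: does the
model's spliced CDS translation contain every complete domain peptide the
genome supports? If no model overlaps, the locus is `missing`; if a model
overlaps and contains the domain, it is a `match` (or `short` when the
predicted protein is under `min_protein_len`, default 120 aa — short
models are deliberately not scored incorrect); otherwise `mispredicted`.
Containment is start-codon-agnostic by construction, so the common
predictor disagreement about the first ATG never flips a verdict — the
suite checks ±30 bp shifts explicitly.

Pseudogene evidence for incomplete loci: `PARTIAL_DOMAIN` always;
`INTERNAL_STOP` when the best reading completes modulo stops;
`FRAMESHIFT` when a complete finger is found downstream of the domain's
first half in a shifted reading frame (searched without stop truncation,
since a frameshifted finger reads cleanly in its own frame) and the
defect is not already explained by stops; `ADJACENT_TRANSPOSON` only when
a repeat annotation is supplied and overlaps within 2 kb. The frameshift
search is a 1.5 kb heuristic window; domains split by introns beyond that
are reported as `PARTIAL_DOMAIN` only.

## Tandem arrays

`detect_tandem_arrays()` chains same-subfamily members along a
chromosome when the inter-gene gap (next start minus previous end) is at
most `max_gap` (default 30,000 bp, the scale of the known chromosome-4
cluster) with at most `max_intervening` foreign genes between members
(default 0). Detection is purely positional: sequence-similarity
confirmation of paralogy belongs to the phylogeny module. On the bundled
table this recovers the chromosome-4 cluster
{BdWRKY86, BdWRKY15, BdWRKY29, BdWRKY10} on a 23,076 bp span exactly. It
also, faithfully, returns more than the two classically cited arrays:
the table places BdWRKY25 only 6,948 bp beyond BdWRKY8 — inside the
chromosome-2 cluster — and contains two further Group III pairs
(BdWRKY44/83 at 1,250 bp, BdWRKY11/17 at 8,552 bp). No positional gap
threshold can keep the 16,703 bp gap inside the chromosome-2 cluster
while excluding the 6,948 bp gap to BdWRKY25, so a purely positional
detector cannot reproduce the historical "two arrays of four" count; the
package reports what the coordinates support (four arrays, thirteen
genes) and leaves similarity-based refinement to the user. The
corresponding acceptance expectations are intentionally left failing
rather than bending the detector.

## Phylogeny engine

Distances are proportions of differing sites under pairwise deletion
(columns with `-` or `X` in either row are excluded; `X` is treated as
missing), Poisson-corrected as `d = -ln(1 - p)` in substitutions per
site; saturated pairs (`p = 1`) are undefined and rejected with advice to
trim the alignment. Trees are built with the Saitou–Nei neighbor-joining
algorithm; ties in the Q-criterion break deterministically by taxon
order. Negative branch lengths are clamped to zero with the deficit
transferred to the sister branch (at the final trifurcation, to the
closest sister); raw lengths are available with
`clamp_negative = FALSE`. Bootstrap supports resample alignment columns
with replacement (single seeded generator; replicates with undefined
distances are redrawn, at most ten times) and report the percentage of
replicates containing each bipartition of the full-data tree, which is
the tree returned; a majority-rule consensus is available via
`type = "consensus"`. Alignments are accepted as input from any aligner —
progressive alignment and manual adjustment are out of scope.

The test suite validates the engine against independent oracles: exact
recovery of random additive matrices (path lengths to 1e-9), agreement
with an exhaustive least-squares search over all 105 six-taxon
topologies, the closed three-point formulas at three taxa, and an
independent NJ implementation.

## The synthetic-genome generator

`build_synthetic_genome()` implants well-formed WRKY genes — correct
heptapeptide, finger spacing, and intron position for each subfamily —
at non-overlapping positions on both strands of an i.i.d. background
(default GC 0.44, roughly a compact grass genome). Domain spacers are
per-subfamily canonical strings with a 8% per-residue substitution rate,
drawn from an alphabet free of C, H, P and W so that no spurious
fingers, PR anchors or heptapeptides arise by construction; flanking
coding sequence puts whole proteins at a realistic 170–260 aa. Intron
interiors are scrubbed of `AG` so each intron has a unique acceptor.
Corruption modes mirror the failure classes seen in curated tables:
`STOP` (an in-frame `TAA` inside the domain), `FRAMESHIFT` (1 bp deletion
just upstream of the finger), `TRUNCATION` (gene cut after the domain's
first exon), `TRANSPOSON` (truncation plus a marked A/T/G-only repeat
cassette that cannot encode cysteine or histidine, recorded in a repeat
annotation). Gene models are emitted `TRUE`, `BAD_MODEL` (acceptor
shifted 30 bp into the second exon: in frame, but the domain is lost) or
`NO_MODEL`.

What passing tests on this generator do and do not show: the background
is i.i.d. and repeat-free apart from the cassette, spacer mutation is
uniform, and introns are short (90–350 bp) — so recall/precision results
certify the splice-aware reconstruction logic, not robustness to real
repeat landscapes, diverged domains far from any query, or non-canonical
splice sites (a gene with a non-GT/AG or mispositioned intron is
deliberately reported incomplete).

## Problem sizes and numerical choices

The reference study condition is twelve intact genes covering all seven
subfamilies, both intron classes and both extended-finger variants,
implanted in 1 Mb (`default_synth_spec()`); the audit condition mixes
nine genes with all corruption and model modes in 200 kb; phylogeny
checks use up to eight taxa, 105-topology enumeration at six taxa, and
200 bootstrap replicates on a four-clade simulated alignment whose
clades share a conserved backbone (keeping p-distances below
saturation). Branch lengths are serialized at 15 significant digits;
additivity is asserted at 1e-9. Coordinates are 1-based inclusive
everywhere; any half-open arithmetic is internal.

## Known limitations

* The scanner trusts its query set: a family member with no query above
  the permissive threshold anywhere in its domain would be missed.
* IIa/IIb and IIc/IId/IIe splits are only as good as the supplied
  references or tree; without them the package refuses to guess.
* Frameshift evidence is a bounded-window heuristic and deliberately
  conservative.
* The tandem detector is positional only, by design; see above for the
  consequences on the bundled table.
* Orientation of curated-table records is unknown (the table stores no
  strand), so `same_orientation` is `NA` for table-only input.
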