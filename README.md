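# wrkyminer

Genome mining, curation and phylogenetics for the WRKY transcription
factor family.

WRKY proteins are one of the largest families of plant transcriptional
regulators. Each carries one or two ~60-residue WRKY domains: an invariant
heptapeptide (canonically `WRKYGQK`, with variants such as `WKKYGQK`)
followed by a zinc finger, either `C-x(4,5)-C-x(22,24)-H-x(1)-H` (C2H2;
Groups I and II) or `C-x(7)-C-x(22,24)-H-x(1)-C` (C2HC; Group III). In the
genome, almost every WRKY domain is interrupted by an intron at one of two
strictly conserved positions: immediately after the invariant `PR`
dipeptide (Group I C-terminal domains, IIc, IId, IIe, III), or at the codon
boundary five residues after the second cysteine of the `C-X5-C` (IIa,
IIb). Automated gene predictions frequently break at exactly this intron,
so genome annotations miss or mangle a substantial fraction of the family —
in the curated *Brachypodium distachyon* family bundled with this package,
20 of 86 members (23.3%) have mispredicted or missing gene models.

`wrkyminer` turns the manual curation workflow behind such family
censuses into an automated, testable pipeline:

- **scan** — exhaustive, recall-first discovery of WRKY-domain-encoding
  loci: Smith–Waterman seeding of representative domains against all six
  reading frames (BLOSUM62, permissive threshold), followed by splice-aware
  domain reconstruction that completes split domains only across a
  canonical `GT..AG` intron at one of the two sanctioned positions.
  Extended Group III fingers (a 9–10 residue insertion in the zinc-finger
  spacer) are recognized and reported.
- **classify** — subfamily assignment from domain structure (two domains →
  I; C2HC → III; intron class + references/tree placement for the
  structure-degenerate groups), with explicit evidence and confidence.
- **audit** — per-locus comparison of GFF3 gene models against the domain
  evidence (`match` / `mispredicted` / `missing` / `short`), tolerant of
  shifted start-codon predictions, plus pseudogene flagging (partial
  domains, in-frame stops, frameshifts, adjacent transposons).
- **tandem** — positional detection of tandem arrays of family members.
- **phylo** — p-distances under pairwise deletion, Poisson correction
  `d = -ln(1 - p)`, Saitou–Nei neighbor-joining and bootstrap supports.
- **synth** — a synthetic-genome generator with a complete truth table, so
  the entire pipeline is testable at desk scale without downloads.

The curated 86-member BdWRKY family table ships with the package
(`load_table1_fixture()`).

## Worked example

```r
library(wrkyminer)

# the curated Brachypodium family table
fam <- load_table1_fixture()
summarize_family(fam)
#> WRKY family summary
#>   total loci:         86
#>   per subfamily:      I=15 IIa=3 IIb=6 IIc=21 IId=6 IIe=10 III=23 UNASSIGNED=2
#>   mispredicted:       10
#>   missing model:      10
#>   flagged (either):   20
#>   pseudogenes:        3
#>   short models:       2

# tandem arrays of Group III genes (30 kb default gap)
arr <- detect_tandem_arrays(fam, subfamily = "III")
arr[arr$chrom == "Bd4", c("members", "n_members")]
#>                               members n_members
#> 4 BdWRKY86,BdWRKY15,BdWRKY29,BdWRKY10         4
array_span(arr[arr$chrom == "Bd4", ])
#> [1] 23076

# a synthetic genome with known truth, scanned end to end
syn  <- build_synthetic_genome(default_synth_spec(), background_len = 1e6,
                               seed = 1)
hits <- scan_genome(syn$genome, syn$queries)
loci <- pair_group1_domains(hits)
loci <- assign_subfamily(loci, references = syn$queries)
loci <- flag_pseudogene(loci, syn$genome, repeats = syn$repeats)
audit <- audit_gene_models(loci, syn$models, syn$genome)
table(audit$status)
#> match
#>    12
```

The summary above reads: 86 family members, of which ten have gene models
that fail to encode the genome-supported domain, ten have no usable gene
model at all (together 23.3% of the family), three are likely pseudogenes,
and two models predict suspiciously short proteins. `array_span` confirms
the four chromosome-4 Group III genes sit on a 23 kb fragment — a tandem
duplication cluster.

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "wrkyminer.R", package = "wrkyminer")` with
subcommands `scan`, `audit`, `report`, `tandem`, `tree` and `synth`.

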