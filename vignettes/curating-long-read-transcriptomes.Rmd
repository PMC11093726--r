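---
title: "Curating long-read transcriptomes: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating long-read transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Long-read RNA sequencing recovers full-length transcript molecules, but
the resulting transcript models are contaminated by reproducible artifact
classes: 5ʹ-degraded fragments that masquerade as alternative starts,
oligo-dT intrapriming on genomic A-tracts that fabricates 3ʹ ends,
reverse-transcriptase template switching at direct repeats that fabricates
junctions, and mapping or reconstruction errors that shuffle splice
chains. `isocurate` treats curation as a three-stage decision problem —
classify, filter, rescue — with every decision grounded in attributes a
reviewer can recompute.

# Structural classification

Transcripts are compared to the reference by their **splice-junction
chain** (the ordered introns). The category logic, in priority order for
multi-exonic queries:

* **FSM** — the chain equals a reference chain. Ties between references
  with the same chain are broken by the smallest
  `|diff_to_TSS| + |diff_to_TTS|`, then lexicographic transcript id, so
  output is independent of input order.
* **ISM** — the chain is a non-empty *contiguous* sublist of a same-gene
  reference chain. The associated reference is chosen by closest ends
  among the chains that contain the query chain.
* **fusion** — the chain overlaps two or more same-strand gene loci that
  do not overlap each other. This test runs *before* the novelty tests:
  a chain concatenating known junctions of two disjoint loci would
  otherwise satisfy the "all junctions known" test and be mislabelled
  NIC. Overlapping loci (nested or bidirectional genes) never trigger
  fusion.
* **NIC / NNC** — evaluated against the junction, donor and acceptor
  catalogs of the same-strand genes the query overlaps (not the global
  catalogs: a donor annotated on another chromosome is not evidence
  here). One novel donor or acceptor makes NNC; all sites known makes
  NIC, split into *combination of known junctions* versus *combination
  of known splice sites* depending on whether every junction (as
  opposed to every site) is annotated.
* **genic_genomic / antisense / intergenic** — by locus overlap; a
  spliced query entirely inside an annotated intron is genic_genomic.

Mono-exonic queries cannot be chain-matched: overlap with a mono-exonic
reference gives FSM, containment within one exon of a multi-exonic
reference gives ISM, other exon overlap gives NIC (with the
*mono-exon by intron retention* subcategory when the exon spans a whole
annotated intron), and the locus rules cover the rest.

## The 22-label space

The admissible (category, subcategory) pairs number exactly 22:
FSM and ISM carry five subcategories each (reference match /
alternative 5ʹ / alternative 3ʹ / alternative both / mono-exon, and
3ʹ fragment / 5ʹ fragment / internal fragment / intron retention /
mono-exon respectively), NIC carries four (known-junction combinations,
known-splice-site combinations, mono-exon, mono-exon by intron
retention), NNC one, fusion one (always multi-exonic), and antisense,
genic_genomic and intergenic two each (mono- versus multi-exonic). This
is the only partition of the space we found in which every label is
realizable — a mono-exonic NNC, for instance, cannot exist because a
transcript without junctions has no splice sites to be novel — and the
fixture generator constructs one exemplar of each label as a standing
test of exhaustiveness and exclusivity.

## Conventions

* Coordinates are 0-based half-open internally; GTF/GFF3 I/O converts at
  the boundary. One internal convention removes a whole class of
  off-by-one bugs; BED, bedGraph and the STAR junction dialect are
  consumed natively.
* End distances are signed, positive when the query end lies downstream
  of the reference end *in transcription direction*, on both strands.
* The reference-match window (50 bp) is inclusive: a 50 bp offset is
  still a reference match, 51 bp is alternative. All boundary constants
  in the package are inclusive on the flagged side and boundary-tested.
* `min_ref_len` (default 200 bp, settable to 0) applies to the
  *spliced* length of reference transcripts: the threshold exists to
  suppress spurious matches to annotated fragments, and a fragment's
  deceptive length is its exonic length, not its genomic span.

# QC attributes

| Attribute | Default | Meaning |
|---|---|---|
| TSS ratio window | 100 bp | coverage windows inside/outside the first exon |
| TSS ratio aggregation | max | across short-read replicates |
| pseudocount | 0.01 | on both coverage means |
| intrapriming window | 20 bp | genomic window downstream of the TTS |
| intrapriming threshold | 60 % A | inclusive |
| polyA motif window | 50 bp | terminal transcript window; a motif qualifies when its **end** is within 50 nt of the 3ʹ end |
| canonical splice motifs | GT-AG, GC-AG, AT-AC | strand-corrected donor–acceptor dinucleotides |
| RTS repeat length | 8 nt | exact direct repeat between donor and acceptor boundary windows (window = repeat length each side); exposed as a parameter |
| junction support | ≥ 3 unique reads | used by the default rules |

Window coverage is reduced by the *mean* depth; bedGraph gaps count as
zero. Peak support measures the signed distance from a transcript end to
the *midpoint* of the nearest eligible peak; only peaks upstream of a
TSS or downstream of a TTS are eligible, except that a peak containing
the end always is. Upstream distances are negative. Strand-undefined
junction rows in `SJ.out.tab` (STAR code 0) match queries on either
strand, because dropping them would silently discard support.

# Filtering

**Rules mode** evaluates a JSON document mapping categories (or a
`rest` block for all unkeyed categories) to rules; requisites inside a
rule combine as AND, rules for one category as OR. Numeric requisites
are closed intervals or lower bounds; logical columns match as the
levels `TRUE`/`FALSE`; missing values fail every requisite
(conservative: an attribute that could not be measured cannot vouch for
a transcript). An optional switch drops all mono-exonic transcripts,
off by default.

**ML mode** trains a 500-tree random forest. Automatic training sets
take reference-match transcripts as true positives and
noncanonical-junction NNC as true negatives; because those definitions
lean on junction type and end distances, the corresponding columns are
withheld from training along with identifiers, genome-structure columns
and the categories themselves. Sets are balanced by downsampling to the
smaller, capped by `max_size`, and refused below 250 per class.
Missing numeric features are imputed with the training median (rank
structure is preserved); missing categorical values become an explicit
`"NA"` level. Held-out accuracy is reported from a stratified 80/20
split, then the shipped model is refitted on all labeled rows; all
sampling and fitting runs under one seed, so probabilities are
bit-reproducible. Multi-exonic transcripts are kept at probability
≥ 0.7 (inclusive); mono-exonic transcripts are not scored — they lack
the junction attributes the forest leans on — and pass through unless
explicitly dropped.

# Rescue

Automatic rescue restores the reference transcript of every removed FSM
unless a surviving FSM already represents it, each reference at most
once. Removed multi-exonic ISM/NIC/NNC transcripts become mapping
candidates (ISM only when no FSM in the dataset shares its reference —
the automatic step covers that case). The internal mapper scores a
candidate/target pair as the fraction of candidate junctions present in
the target plus the exonic Jaccard index, keeps at most 7 hits per
candidate (primary plus six secondary, mirroring a spliced aligner's
default), and externally computed alignments can be fed in using the same
hit shape. Reference targets must pass the *same* filter configuration,
evaluated by running QC on the reference against itself with
`min_ref_len = 0` (so short annotated transcripts are judged rather than
silently dropped; self-classification yields FSM reference matches at
distance 0, a standing invariant test). In ML mode the surviving target
with the highest isoform probability wins, ties broken by mapping score
then id — the tie-break is a convention, surfaced in the output, since
no principled ordering exists between equally probable targets. In
rules mode all surviving reference targets are considered. Additions
are deduplicated and redundancy-checked against the curated set, so the
final transcriptome never contains a rescued duplicate and the gene set
can only grow.

# Spike-in benchmarking

`build_scenario()` reproduces the two corruption modes of spike-in
experiments: removing true transcripts from the annotation while they
remain in the RNA mix, and adding fabricated isoforms absent from the
mix. Fabrications are internal-exon-skip variants (falling back to
100–300 bp end shifts when a gene has no skippable exon), with
duplicate chains rejected. Detections are classified against both
annotations; reference-match hits to true models are known or novel
true positives, hits to fabricated models are over-annotation false
positives, FSMs with an end off by more than the 50 bp window are
partial true positives, and NIC/NNC against both annotations are false
positives. Matched classes are de-duplicated by matched model so that a
transcript detected twice — or re-added by rescue — counts once and
sensitivity is bounded by 1; false positives count detections. The six
metrics follow the standard definitions (F-score is the harmonic mean of
sensitivity and precision; FDR adds partial and over-annotation classes;
ODR and NDR isolate over-annotation and novelty).

# Feature transfer

Functional features transfer by genomic coordinate matching from donor
transcripts of the same gene (or the same id, outside novel mode). UTR
features must stay exonic and avoid the acceptor CDS; coding-region
features must also sit inside the CDS and, when they cross exon
boundaries, those boundaries must be shared junctions; protein features
transfer wholesale on identical CDS exon sets and otherwise only inside
the shared CDS region, where "partial match" means ≥ 1 bp of CDS-exon
overlap; gene-level terms follow gene identity. Feature identity for
de-duplication is (level, label, genomic span), which also makes
transfer idempotent. The GFF3 dialect used is deliberately minimal
(structural rows in genomic coordinates, feature rows in spliced
transcript coordinates keyed by level) and round-trip-tested; protein
features are carried in transcript nucleotide coordinates rather than
residue coordinates to keep one coordinate system per transcript.

# What the fixture generator emulates — and what it does not

The generator lays out genes with canonical GT-AG introns on a uniform
random genome, plants a polyA motif ending 17 nt before every true TTS
(inside the empirically enriched 16–18 nt band), places 5ʹ and 3ʹ peaks
at the true ends, encodes short-read coverage as exact plateaus over
gene bodies so that window means are analytic (a true TSS sees
inside/outside ≈ 10/0, ratio 1001; a degraded end sees 10/10, ratio
exactly 1), and supports true junctions with fixed read counts. Each
artifact construct plants its own signal: A-rich downstream windows
(80 % A), unsupported noncanonical novel donors, shared 8-mers at
junction boundaries, degraded 5ʹ starts inside covered regions.

Because plateaus are exact and plants are deterministic given the seed,
planted attributes are recovered *exactly* and truth labels agree with
the classifier at 100 % under zero jitter. Real data differ in ways the
generator deliberately omits: ragged coverage, soft peak boundaries,
sequencing error, ambiguous gene models, overlapping loci, expression-
dependent evidence depth. Passing tests therefore demonstrate the
correctness of the *decision logic* at its operating points, not
field performance on tissue data.

# Problem sizes and numerical choices

The test suite runs oracle-equivalence sweeps on 200 random fixtures of
up to 10 genes against an independently written brute-force classifier,
and the end-to-end curation property (precision rises after filtering,
sensitivity recovers after rescue, F-score never degrades) on five
seeds of a 90-gene, ~700-transcript study with 39 fabricated and 26
removed annotation entries — sizes chosen to exercise every code path
with comfortable statistical margins while keeping a full run on a
laptop in the low minutes. Degenerate inputs are defined, not special-
cased: empty reference indexes answer every lookup with "no hit",
coverage queries outside tracks return 0, zero-length clipped windows
count as zero coverage, empty junction sets make `min_cov` missing, and
zero denominators in benchmark metrics yield `NA` rather than 0.

# Known limitations

* ORF/coding-status prediction and expression quantification are out of
  scope; the QC attribute set is the subset used by the default filters
  and rescue.
* The internal rescue mapper scores structural compatibility, not
  sequence alignment; for sequence-level fidelity substitute an external
  aligner's hits.
* Fusion calls require non-overlapping partner loci; read-through
  transcription between overlapping genes is not distinguished from a
  multi-isoform locus.
* The RT-switching test is an exact-repeat screen with an 8 nt default;
  it is a flag for review, not a mechanistic classifier.
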