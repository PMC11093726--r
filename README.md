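# isocurate

Quality control and curation of transcriptomes built from long-read RNA
sequencing (PacBio / ONT). Long-read transcript collections are rich in
artifacts — 5ʹ-degraded fragments, intrapriming products, junctions
fabricated by reverse-transcriptase template switching, misassembled
splice chains — and `isocurate` provides the full curation loop:

1. **Classify** every query transcript model against a reference
   annotation by splice-junction chain matching, into 8 structural
   categories (FSM, ISM, NIC, NNC, antisense, fusion, genic_genomic,
   intergenic) and their subcategories — 22 admissible
   (category, subcategory) labels in total. An FSM whose two ends lie
   within 50 bp of the matched reference ends is a *reference match*.
2. **Measure** transcript- and junction-level QC attributes from
   orthogonal evidence: CAGE-like 5ʹ peaks and polyA 3ʹ peaks (BED),
   polyA motifs in the final 50 bp of the transcript, the adenine
   fraction of the 20 bp genomic window downstream of the TTS
   (intrapriming, flagged at ≥ 60 %), short-read splice-junction counts
   (STAR `SJ.out.tab`), direct-repeat RT-switching flags, and the
   **TSS ratio**

   ```
   TSS ratio = (coverage inside + 0.01) / (coverage outside + 0.01)
   ```

   comparing mean short-read coverage over the 100 bp inside versus
   outside the first exon (per replicate; the maximum is kept by
   default). A genuine TSS depletes upstream coverage (ratio ≫ 1); a
   degradation product does not (ratio ≈ 1).
3. **Filter** artifacts either with JSON-defined rules (requisites AND
   within a rule, rules OR within a category; the default removes FSM
   solely on intrapriming and requires other categories to be free of
   intrapriming and RT switching and to have every junction supported by
   ≥ 3 short reads or all-canonical junctions) or with a random-forest
   classifier trained on reference-match true positives versus
   noncanonical-NNC true negatives (≥ 250 transcripts per class,
   balanced; isoforms kept at probability ≥ 0.7).
4. **Rescue** discarded signal: references of removed FSMs are restored
   automatically; removed ISM/NIC/NNC transcripts are mapped to
   same-gene long-read and reference targets, targets are themselves
   validated with the same QC + filter configuration, and the best
   surviving target is re-incorporated without redundancy.
5. **Benchmark** with spike-in-style ground truth: corrupt an annotation
   (fabricated isoforms added, true isoforms removed), tally detections
   into known/novel/partial true positives and over-annotation/other
   false positives, and compute sensitivity, precision, F-score, FDR,
   over-annotation detection rate (ODR) and novel detection rate (NDR).
6. **Transfer** functional features (UTR, CDS, protein, gene level) onto
   curated transcripts by genomic coordinate matching, emitting a
   tappAS-style GFF3.

A deterministic fixture generator (`generate_fixture()`) builds synthetic
genomes, annotations, query sets with planted truth labels, and all the
orthogonal evidence tracks, so the whole pipeline is testable offline.

## Worked example

```r
library(isocurate)

spec <- fixture_spec(n_genes = 6, isoforms_per_gene = 2,
  mix = c(reference_match = 6, ism_3prime_fragment = 3,
          nnc_noncanonical = 3, intrapriming = 2))
bundle <- generate_fixture(spec, seed = 1)

index <- build_reference_index(bundle$reference)
qc <- compute_qc_tables(bundle$query, index, genome = bundle$genome,
  cage_peaks = bundle$cage_peaks, polya_peaks = bundle$polya_peaks,
  polya_motifs = bundle$motifs, coverage = bundle$coverage, sj = bundle$sj)
table(qc$classification$structural_category, qc$classification$subcategory)
#>       3prime_fragment alternative_3end at_least_one_novel_splicesite reference_match
#>   FSM               0                2                             0               6
#>   ISM               3                0                             0               0
#>   NNC               0                0                             3               0
```

The six faithful copies are FSM reference matches; the degraded
fragments are ISM 3ʹ fragments; the corrupted-junction models are NNC;
the two intrapriming products are FSM with an alternative 3ʹ end and an
A-rich downstream window:

```r
qc$classification[qc$classification$intrapriming,
  c("isoform", "subcategory", "perc_A_downstream_TTS", "ratio_TSS")]
#>    isoform      subcategory perc_A_downstream_TTS ratio_TSS
#> 13   Q0013 alternative_3end                   0.8      1001
#> 14   Q0014 alternative_3end                   0.8      1001
```

Filtering with the default rules removes the intrapriming FSMs and the
unsupported noncanonical NNCs (the ISM fragments carry supported,
canonical junctions and survive a junction-based rule set):

```r
decisions <- apply_rules(qc$classification, default_rules())
table(decisions$verdict)
#> artifact  isoform
#>        5        9
```

Rescue validates the reference annotation under the same rules and
re-incorporates the best surviving same-gene targets for the removed
NNC artifacts:

```r
refv <- validate_reference_targets(bundle$reference, mode = "rules",
  rules = default_rules(), genome = bundle$genome,
  cage_peaks = bundle$cage_peaks, polya_peaks = bundle$polya_peaks,
  polya_motifs = bundle$motifs, coverage = bundle$coverage, sj = bundle$sj)
rescue <- run_rescue_stage(qc$classification, decisions, bundle$query,
                           index, refv, mode = "rules")
rescue$outcomes
#>   artifact_id            action chosen_target
#> 1       Q0010 rescued_reference        G001.2
#> 2       Q0011 rescued_reference        G002.2
#> 3       Q0012 rescued_reference        G003.2
```

The curated transcriptome keeps 9 query models and adds 3 reference
models whose signal would otherwise have been lost.

File-based runs use the staged pipeline (`run_config()`, `run_qc()`,
`run_filter()`, `run_rescue()`, `summarize_run()`) or the thin CLI at
`inst/cli/isocurate.R` with subcommands `qc`, `filter`, `rescue`,
`report`, `simulate` and `eval`.

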