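# End-to-end spike-in curation run: noisy detection set against a corrupted
# annotation (39 fabricated models added, 26 true models removed), ML filter
# with automatic training sets, then rescue. Returns the six metrics before
# filtering, after filtering, and after rescue.
sirv_curation_run <- function(seed, n_genes = 90, n_false = 39,
                              n_removed = 26) {
  spec <- fixture_spec(
    n_genes = n_genes, isoforms_per_gene = 3,
    mix = c(reference_match = 3 * n_genes, ism_3prime_fragment = n_genes,
            nnc_noncanonical = 3 * n_genes, intrapriming = 20))
  b <- generate_fixture(spec, seed)
  scenario <- build_scenario(b$reference, n_false, n_removed, seed + 1)

  # ten genes are observed only through degraded 5' fragments: their full
  # models are absent from the detection set and recoverable only by rescue
  frag_only <- sprintf("G%03d", (n_genes - 9):n_genes)
  drop <- b$truth$isoform[b$truth$type == "reference_match" &
                            b$truth$source_gene %in% frag_only]
  b$query <- b$query[setdiff(names(b$query), drop)]

  # detections matching the fabricated (over-annotated) models
  fabq <- list()
  for (i in seq_along(scenario$fabricated_ids)) {
    tm <- scenario$modified[[scenario$fabricated_ids[i]]]
    id <- sprintf("QF%03d", i)
    fabq[[id]] <- transcript_model(id, gene_id = id, chrom = tm$chrom,
                                   strand = tm$strand, exons = tm$exons)
  }
  detections <- c(b$query, fabq)

  # the corrupted annotation is the reference available to the pipeline
  idx <- build_reference_index(scenario$modified, min_ref_len = 0)
  qc <- compute_qc_tables(detections, idx, genome = b$genome,
                          cage_peaks = b$cage_peaks,
                          polya_peaks = b$polya_peaks,
                          polya_motifs = b$motifs, coverage = b$coverage,
                          sj = b$sj)

  m_unfiltered <- compute_metrics(tally_detections(detections, scenario))

  sp <- ml_training_spec(seed = seed)
  sets <- auto_training_sets(qc$classification, sp)
  sp$excluded_columns <- union(sp$excluded_columns,
                               sets$auto_excluded_columns)
  model <- train_ml_filter(qc$classification, sets$tp_ids, sets$tn_ids, sp)
  dec <- score_and_filter(qc$classification, model, sp)
  kept <- dec$isoform[dec$verdict == "isoform"]
  m_filtered <- compute_metrics(tally_detections(detections[kept], scenario))

  refv <- validate_reference_targets(scenario$modified, mode = "ml",
                                     ml_model = model, ml_spec = sp,
                                     genome = b$genome,
                                     cage_peaks = b$cage_peaks,
                                     polya_peaks = b$polya_peaks,
                                     polya_motifs = b$motifs,
                                     coverage = b$coverage, sj = b$sj)
  res <- run_rescue_stage(qc$classification, dec, detections, idx, refv,
                          mode = "ml")
  final <- c(detections[res$curated_ids],
             scenario$modified[intersect(res$additions,
                                         names(scenario$modified))])
  m_rescued <- compute_metrics(tally_detections(final, scenario))

  list(unfiltered = m_unfiltered, filtered = m_filtered,
       rescued = m_rescued, n_kept = length(kept),
       n_added = length(res$additions))
}
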