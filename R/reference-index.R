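#' Build the reference index
#'
#' Collects a reference transcript set into the queryable index used by the
#' classifier and the rescue module: transcripts by id, genes and their
#' genomic loci, and catalogs of junctions, donor sites, acceptor sites and
#' annotated TSS/TTS. All catalogs are pure functions of the input set
#' (insertion order does not matter). Transcripts shorter than the
#' `min_ref_len` already applied at load time are simply absent from the
#' input, so every catalog entry traces back to at least one indexed
#' transcript.
#'
#' @param transcripts Named list of `transcript_model` objects.
#' @param min_ref_len The spliced-length threshold the set was loaded with
#'   (recorded for provenance; default 200).
#' @return An object of class `reference_index`.
#' @export
build_reference_index <- function(transcripts, min_ref_len = 200) {
  if (length(transcripts) > 0L)
    transcripts <- transcripts[order(names(transcripts))]
  gene_ids <- vapply(transcripts, `[[`, character(1), "gene_id")
  genes <- split(as.character(names(transcripts)), gene_ids)

  gene_table <- if (length(genes) > 0L) {
    do.call(rbind, lapply(names(genes), function(g) {
      tms <- transcripts[genes[[g]]]
      data.frame(gene_id = g,
                 chrom = tms[[1L]]$chrom,
                 strand = tms[[1L]]$strand,
                 start = min(vapply(tms, tm_start, numeric(1))),
                 end = max(vapply(tms, tm_end, numeric(1))),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(gene_id = character(0), chrom = character(0),
               strand = character(0), start = numeric(0), end = numeric(0))
  }

  per_gene <- lapply(genes, function(ids) {
    tms <- transcripts[ids]
    list(junctions = unique(unlist(lapply(tms, junction_keys))),
         donors = unique(unlist(lapply(tms, donor_keys))),
         acceptors = unique(unlist(lapply(tms, acceptor_keys))),
         tss = unique(vapply(tms, tm_tss, numeric(1))),
         tts = unique(vapply(tms, tm_tts, numeric(1))))
  })

  chains <- vapply(transcripts, chain_key, character(1))
  by_chain <- split(as.character(names(transcripts)), chains)

  structure(list(
    transcripts = transcripts,
    genes = genes,
    gene_table = gene_table,
    per_gene = per_gene,
    junctions = unique(unlist(lapply(per_gene, `[[`, "junctions"))),
    donors = unique(unlist(lapply(per_gene, `[[`, "donors"))),
    acceptors = unique(unlist(lapply(per_gene, `[[`, "acceptors"))),
    by_chain = by_chain,
    min_ref_len = min_ref_len
  ), class = "reference_index")
}

#' @export
print.reference_index <- function(x, ...) {
  cat(sprintf("<reference_index> %d transcripts, %d genes, %d junctions, min_ref_len=%g\n",
              length(x$transcripts), length(x$genes), length(x$junctions),
              x$min_ref_len))
  invisible(x)
}

# Gene ids whose locus overlaps [start, end) on chrom; strand "+"/"-" to
# restrict, or NULL for both.
overlapping_genes <- function(index, chrom, start, end, strand = NULL) {
  gt <- index$gene_table
  hit <- gt$chrom == chrom & gt$start < end & gt$end > start
  if (!is.null(strand)) hit <- hit & gt$strand == strand
  gt$gene_id[hit]
}
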