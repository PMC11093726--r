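# Hand-built micro-fixtures shared across test files.

mk_tm <- function(id, exons, strand = "+", chrom = "chr1", gene = id,
                  cds = NULL) {
  transcript_model(id, gene_id = gene, chrom = chrom, strand = strand,
                   exons = exons, cds = cds)
}

# One gene on the plus strand: 4 exons, full isoform A.1 plus exon-2-skip
# isoform A.2, and a mono-exonic gene M on the same chromosome.
tiny_reference <- function() {
  ex <- rbind(c(100, 200), c(500, 650), c(1000, 1150), c(1500, 1700))
  list(
    A.1 = mk_tm("A.1", ex, gene = "A"),
    A.2 = mk_tm("A.2", ex[-2L, ], gene = "A"),
    M.1 = mk_tm("M.1", cbind(5000, 5400), gene = "M")
  )
}

tiny_index <- function() build_reference_index(tiny_reference())

# A genome string with planted content, as a named character vector
# (accepted everywhere a DNAStringSet is).
flat_genome <- function(len = 10000, chrom = "chr1", base = "C") {
  stats::setNames(strrep(base, len), chrom)
}

# Deterministic non-repetitive random genome (a single base would trivially
# contain shared k-mers everywhere).
rnd_genome <- function(len = 10000, chrom = "chr1", seed = 99) {
  withr::with_seed(seed, stats::setNames(
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    chrom))
}

plant_str <- function(genome, chrom, start0, seq) {
  g <- genome[[chrom]]
  substr(g, start0 + 1, start0 + nchar(seq)) <- seq
  genome[[chrom]] <- g
  genome
}

# Mirror a transcript set through reverse-complementing the genome:
# coordinates flip around the chromosome length, strands invert.
flip_tm <- function(tm, chrom_len) {
  ex <- cbind(chrom_len - tm$exons[, 2L], chrom_len - tm$exons[, 1L])
  mk_tm(tm$transcript_id, ex[order(ex[, 1L]), , drop = FALSE],
        strand = if (tm$strand == "+") "-" else "+", chrom = tm$chrom,
        gene = tm$gene_id)
}

flip_genome <- function(genome) {
  out <- vapply(genome, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "",
                       fixed = TRUE)[[1L]]), collapse = "")
  }, character(1))
  out
}

# Minimal classification records for filter tests.
stub_records <- function(n, category = "NNC", subcategory = "at_least_one_novel_splicesite",
                         exons = 3, min_cov = 10, all_canonical = TRUE,
                         intrapriming = FALSE, RTS_stage = FALSE,
                         ratio_TSS = 2, perc_A = 0.2, prefix = "T") {
  data.frame(
    isoform = sprintf("%s%04d", prefix, seq_len(n)),
    chrom = "chr1", strand = "+", length = 1000, exons = exons,
    structural_category = category, subcategory = subcategory,
    associated_gene = "G", associated_transcript = "G.1",
    diff_to_TSS = 0, diff_to_TTS = 0, diff_to_gene_TSS = 0,
    diff_to_gene_TTS = 0, ratio_TSS = ratio_TSS,
    perc_A_downstream_TTS = perc_A, intrapriming = intrapriming,
    polyA_motif = "AATAAA", polyA_dist = 17, polyA_motif_found = TRUE,
    within_CAGE_peak = TRUE, dist_to_CAGE_peak = 0,
    within_polyA_site = TRUE, dist_to_polyA_site = 0,
    all_canonical = all_canonical, min_cov = min_cov, RTS_stage = RTS_stage,
    stringsAsFactors = FALSE)
}
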