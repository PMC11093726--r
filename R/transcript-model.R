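#' Transcript model
#'
#' A `transcript_model` is the unit object of the package: one transcript on
#' one chromosome and strand, described by its ordered exons and, optionally,
#' a CDS interval. All coordinates are 0-based half-open; GTF/GFF3 I/O
#' converts at the boundary.
#'
#' @param transcript_id Transcript identifier (unique within a set).
#' @param gene_id Gene identifier; defaults to `transcript_id` when absent.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column numeric matrix (or data.frame) of exon
#'   `start`/`end` coordinates, 0-based half-open. Overlapping or book-ended
#'   exons are merged; rows are sorted by start.
#' @param cds Optional genomic `c(start, end)` interval (0-based half-open)
#'   delimiting the coding region, or `NULL`.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id = transcript_id, chrom,
                             strand, exons, cds = NULL) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            strand %in% c("+", "-"))
  exons <- as.matrix(exons)
  storage.mode(exons) <- "double"
  if (ncol(exons) != 2L || nrow(exons) < 1L)
    stop("exons must be a matrix with >= 1 row and 2 columns")
  if (any(exons[, 1L] >= exons[, 2L]))
    stop("exon start must be < exon end (0-based half-open)")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  exons <- merge_blocks(exons)
  dimnames(exons) <- list(NULL, c("start", "end"))
  if (!is.null(cds)) {
    cds <- as.numeric(cds)
    stopifnot(length(cds) == 2L, cds[1L] < cds[2L])
  }
  structure(list(transcript_id = transcript_id,
                 gene_id = gene_id,
                 chrom = chrom, strand = strand,
                 exons = exons, cds = cds),
            class = "transcript_model")
}

# Merge overlapping/adjacent sorted blocks into disjoint blocks.
merge_blocks <- function(blocks) {
  if (nrow(blocks) <= 1L) return(blocks)
  out <- blocks[1L, , drop = FALSE]
  for (i in 2L:nrow(blocks)) {
    k <- nrow(out)
    if (blocks[i, 1L] <= out[k, 2L]) {
      out[k, 2L] <- max(out[k, 2L], blocks[i, 2L])
    } else {
      out <- rbind(out, blocks[i, , drop = FALSE])
    }
  }
  out
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s %d exon(s), span %d-%d\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), tm_start(x), tm_end(x)))
  invisible(x)
}

#' Accessors for transcript models
#'
#' Small helpers used throughout the package: genomic span, exon count,
#' spliced length, strand-aware transcript ends and the intron (junction)
#' chain.
#'
#' `tm_tss()`/`tm_tts()` return the 0-based coordinate of the first/last
#' transcribed base (strand aware). `tm_junctions()` returns a matrix of
#' intron intervals (`start` 0-based inclusive, `end` exclusive) in genomic
#' order; a mono-exonic transcript yields zero rows.
#'
#' @param tm A `transcript_model`.
#' @name tm-accessors
NULL

#' @rdname tm-accessors
#' @export
tm_start <- function(tm) tm$exons[1L, 1L]

#' @rdname tm-accessors
#' @export
tm_end <- function(tm) tm$exons[nrow(tm$exons), 2L]

#' @rdname tm-accessors
#' @export
tm_n_exons <- function(tm) nrow(tm$exons)

#' @rdname tm-accessors
#' @export
tm_spliced_length <- function(tm) sum(tm$exons[, 2L] - tm$exons[, 1L])

#' @rdname tm-accessors
#' @export
tm_tss <- function(tm) if (tm$strand == "+") tm_start(tm) else tm_end(tm) - 1

#' @rdname tm-accessors
#' @export
tm_tts <- function(tm) if (tm$strand == "+") tm_end(tm) - 1 else tm_start(tm)

#' @rdname tm-accessors
#' @export
tm_junctions <- function(tm) {
  n <- nrow(tm$exons)
  if (n < 2L) {
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = tm$exons[-n, 2L], end = tm$exons[-1L, 1L])
}

# String keys used by the catalogs. Junction keys are strand-aware;
# donor/acceptor keys encode the strand-aware splice-site position.
junction_keys <- function(tm) {
  j <- tm_junctions(tm)
  if (nrow(j) == 0L) return(character(0))
  sprintf("%s:%s:%d-%d", tm$chrom, tm$strand, as.integer(j[, 1L]), as.integer(j[, 2L]))
}

chain_key <- function(tm) {
  k <- junction_keys(tm)
  if (length(k) == 0L) return(NA_character_)
  paste(k, collapse = ";")
}

# Donor = 5' splice site of the intron, acceptor = 3' site (strand aware).
donor_keys <- function(tm) {
  j <- tm_junctions(tm)
  if (nrow(j) == 0L) return(character(0))
  pos <- if (tm$strand == "+") j[, 1L] else j[, 2L]
  sprintf("%s:%s:%d", tm$chrom, tm$strand, as.integer(pos))
}

acceptor_keys <- function(tm) {
  j <- tm_junctions(tm)
  if (nrow(j) == 0L) return(character(0))
  pos <- if (tm$strand == "+") j[, 2L] else j[, 1L]
  sprintf("%s:%s:%d", tm$chrom, tm$strand, as.integer(pos))
}

# Signed distance between a query end and a reference end, positive when the
# query end lies downstream (in transcription direction) of the reference end.
signed_end_diff <- function(query_pos, ref_pos, strand) {
  if (strand == "+") query_pos - ref_pos else ref_pos - query_pos
}

# Total number of genomic bases shared by the exons of two transcripts.
exon_overlap_bp <- function(a, b) {
  tot <- 0
  for (i in seq_len(nrow(a$exons))) {
    s <- pmin(a$exons[i, 2L], b$exons[, 2L]) - pmax(a$exons[i, 1L], b$exons[, 1L])
    tot <- tot + sum(s[s > 0])
  }
  tot
}

# Jaccard index of the exonic base sets of two transcripts.
exon_jaccard <- function(a, b) {
  ov <- exon_overlap_bp(a, b)
  un <- tm_spliced_length(a) + tm_spliced_length(b) - ov
  if (un <= 0) 0 else ov / un
}

#' Spliced, strand-corrected transcript sequence
#'
#' Concatenates the exon sequences and reverse-complements on the minus
#' strand, so that the returned sequence reads 5' to 3'.
#'
#' @param tm A `transcript_model`.
#' @param genome A named [Biostrings::DNAStringSet] of chromosome sequences,
#'   or the named uppercase character vector from [genome_chars()].
#' @return A character scalar (uppercase DNA).
#' @export
tm_sequence <- function(tm, genome) {
  genome <- genome_chars(genome)
  chr <- genome[[tm$chrom]]
  parts <- substring(chr, tm$exons[, 1L] + 1L, tm$exons[, 2L])
  s <- paste(parts, collapse = "")
  if (tm$strand == "-") s <- revcomp_chr(s)
  s
}

#' Genome as plain character strings
#'
#' The sequence-based QC attributes slice the genome heavily; converting a
#' [Biostrings::DNAStringSet] once to a named uppercase character vector
#' makes those lookups cheap. Character input passes through.
#'
#' @param genome Named `DNAStringSet` or named character vector.
#' @return Named uppercase character vector of chromosome sequences.
#' @export
genome_chars <- function(genome) {
  if (is.character(genome)) return(genome)
  stats::setNames(toupper(as.character(genome)), names(genome))
}

# Reverse complement of a plain character DNA string.
revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# Genomic slice [start, end) clipped to the chromosome; returns "" when the
# clipped window is empty.
genome_slice <- function(genome, chrom, start, end) {
  chr <- genome[[chrom]]
  start <- max(0, start)
  end <- min(nchar(chr, type = "bytes"), end)
  if (end <= start) return("")
  substr(chr, start + 1L, end)
}
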