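#' Read a GTF file into transcript models
#'
#' Parses exon (and CDS) features of a GENCODE-dialect GTF into a list of
#' [transcript_model()] objects. GTF 1-based inclusive coordinates are
#' converted to the package's internal 0-based half-open convention.
#' Reference transcripts whose spliced (exonic) length is below `min_len`
#' are dropped; set `min_len = 0` to keep everything, e.g. when
#' characterizing a reference annotation against itself.
#'
#' @param path Path to a GTF file.
#' @param min_len Minimum spliced length in bp (default 200).
#' @return Named list of `transcript_model` objects (names = transcript ids).
#' @export
load_gtf <- function(path, min_len = 200) {
  check_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  if (is.null(meta$transcript_id))
    stop("GTF has no transcript_id attributes: ", path)
  keep <- meta$type %in% c("exon", "CDS")
  gr <- gr[keep]
  meta <- S4Vectors::mcols(gr)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,  # to 0-based
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(meta$type),
                   transcript_id = as.character(meta$transcript_id),
                   gene_id = if (is.null(meta$gene_id)) NA_character_ else
                     as.character(meta$gene_id),
                   stringsAsFactors = FALSE)
  df$gene_id[is.na(df$gene_id)] <- df$transcript_id[is.na(df$gene_id)]
  out <- list()
  bad <- character(0)
  for (tid in unique(df$transcript_id)) {
    rows <- df[df$transcript_id == tid, , drop = FALSE]
    if (length(unique(rows$chrom)) > 1L || length(unique(rows$strand)) > 1L) {
      bad <- c(bad, tid)
      next
    }
    ex <- rows[rows$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0L) next
    cds_rows <- rows[rows$type == "CDS", , drop = FALSE]
    cds <- if (nrow(cds_rows) > 0L) c(min(cds_rows$start), max(cds_rows$end)) else NULL
    tm <- transcript_model(tid, gene_id = ex$gene_id[1L], chrom = ex$chrom[1L],
                           strand = ex$strand[1L],
                           exons = cbind(ex$start, ex$end), cds = cds)
    if (tm_spliced_length(tm) >= min_len) out[[tid]] <- tm
  }
  if (length(bad) > 0L)
    stop("transcript(s) with exons on mixed chrom/strand rejected: ",
         paste(bad, collapse = ", "))
  out
}

# Cheap structural pre-scan so malformed lines are reported by number
# (rtracklayer's errors are not line-addressed).
check_gtf_lines <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields", i))
    if (is.na(suppressWarnings(as.numeric(f[4L]))) ||
        is.na(suppressWarnings(as.numeric(f[5L]))))
      stop(sprintf("malformed GTF line %d: non-numeric coordinates", i))
  }
  invisible(TRUE)
}

#' Write transcript models to GTF
#'
#' Emits one `transcript` row plus per-exon `exon` rows (and `CDS` rows when
#' a CDS is present) per model, converting back to GTF 1-based inclusive
#' coordinates. `load_gtf(write_gtf(x))` round-trips ids and exon
#' coordinates exactly.
#'
#' @param transcripts Named list of `transcript_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tm in transcripts) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', tm$gene_id,
                     tm$transcript_id)
    writeLines(sprintf("%s\tisocurate\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       tm$chrom, as.integer(tm_start(tm)) + 1L,
                       as.integer(tm_end(tm)), tm$strand, attrs), con)
    for (i in seq_len(nrow(tm$exons))) {
      writeLines(sprintf("%s\tisocurate\texon\t%d\t%d\t.\t%s\t.\t%s",
                         tm$chrom, as.integer(tm$exons[i, 1L]) + 1L,
                         as.integer(tm$exons[i, 2L]), tm$strand, attrs), con)
    }
    if (!is.null(tm$cds)) {
      blocks <- intersect_blocks(tm$exons, tm$cds[1L], tm$cds[2L])
      for (i in seq_len(nrow(blocks))) {
        writeLines(sprintf("%s\tisocurate\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                           tm$chrom, as.integer(blocks[i, 1L]) + 1L,
                           as.integer(blocks[i, 2L]), tm$strand, attrs), con)
      }
    }
  }
  invisible(path)
}

# Intersect disjoint sorted blocks with [lo, hi); returns the clipped blocks.
intersect_blocks <- function(blocks, lo, hi) {
  s <- pmax(blocks[, 1L], lo)
  e <- pmin(blocks[, 2L], hi)
  keep <- s < e
  cbind(start = s[keep], end = e[keep])
}

#' Read a BED file of peak regions
#'
#' BED is consumed natively (0-based half-open). Returns a `peak_set`:
#' a data.frame of `chrom`, `start`, `end`, `strand` (`"*"` when the file has
#' no strand column) plus the midpoint `floor((start + end) / 2)`.
#'
#' @param path Path to a BED4/BED6 file.
#' @param kind One of `"five_prime"`, `"three_prime"`, `"generic"`.
#' @return A `peak_set` data.frame.
#' @export
load_bed_peaks <- function(path, kind = c("generic", "five_prime", "three_prime")) {
  kind <- match.arg(kind)
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df$mid <- floor((df$start + df$end) / 2)
  attr(df, "kind") <- kind
  class(df) <- c("peak_set", class(df))
  df
}

#' Read a bedGraph coverage track
#'
#' One replicate of short-read genome coverage. Gaps in the track count as
#' zero coverage; queries outside covered regions return 0.
#'
#' @param path Path to a bedGraph file.
#' @param replicate_id Label for the replicate.
#' @return A `coverage_track` object.
#' @export
load_bedgraph <- function(path, replicate_id = basename(path)) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   value = as.numeric(S4Vectors::mcols(gr)$score),
                   stringsAsFactors = FALSE)
  coverage_track(df, replicate_id)
}

#' Build a coverage track from a data.frame
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   `value` columns.
#' @param replicate_id Label for the replicate.
#' @return A `coverage_track` object.
#' @export
coverage_track <- function(df, replicate_id = "rep1") {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(df)))
  stopifnot(all(df$value >= 0))
  by_chrom <- split(df[c("start", "end", "value")], df$chrom)
  by_chrom <- lapply(by_chrom, function(x) x[order(x$start), , drop = FALSE])
  structure(list(replicate_id = replicate_id, by_chrom = by_chrom),
            class = "coverage_track")
}

#' Mean coverage over a genomic window
#'
#' @param track A `coverage_track`.
#' @param chrom Chromosome.
#' @param start,end 0-based half-open window. A zero-length window has mean 0.
#' @return Mean depth over the window (uncovered bases count as 0).
#' @export
coverage_mean <- function(track, chrom, start, end) {
  if (end <= start) return(0)
  seg <- track$by_chrom[[chrom]]
  if (is.null(seg)) return(0)
  hit <- seg$end > start & seg$start < end
  if (!any(hit)) return(0)
  seg <- seg[hit, , drop = FALSE]
  w <- pmin(seg$end, end) - pmax(seg$start, start)
  unname(sum(w * seg$value) / (end - start))
}

#' Read STAR SJ.out.tab splice-junction counts
#'
#' Consumes the STAR `SJ.out.tab` dialect: 1-based inclusive intron
#' start/end, strand code (0 = undefined, 1 = `+`, 2 = `-`), and the
#' unique-read count in column 7. Coordinates are converted to the internal
#' 0-based half-open convention. Junctions with strand code 0 are stored
#' strand-agnostically and match a query on either strand.
#'
#' @param paths Character vector of `SJ.out.tab` paths, one per replicate;
#'   names (or basenames) become replicate ids.
#' @return An `sj_support` object.
#' @export
load_sj_tab <- function(paths) {
  if (is.null(names(paths))) names(paths) <- basename(paths)
  reps <- lapply(paths, function(p) {
    if (file.size(p) == 0) {
      return(data.frame(key = character(0), count = numeric(0)))
    }
    tab <- tryCatch(
      utils::read.table(p, header = FALSE, colClasses = c(
        "character", rep("numeric", 8))),
      warning = function(w) stop("parse error in SJ.out.tab: ", p),
      error = function(e) stop("parse error in SJ.out.tab (non-integer fields?): ", p))
    strand <- c("*", "+", "-")[tab[[4L]] + 1L]
    data.frame(key = sprintf("%s:%s:%d-%d", tab[[1L]], strand,
                             as.integer(tab[[2L]]) - 1L, as.integer(tab[[3L]])),
               count = tab[[7L]], stringsAsFactors = FALSE)
  })
  sj_support(reps)
}

#' Construct splice-junction support from per-replicate tables
#'
#' @param reps Named list of data.frames with `key`
#'   (`"chrom:strand:start-end"`, 0-based half-open, strand `*` for
#'   undefined) and `count` columns.
#' @return An `sj_support` object.
#' @export
sj_support <- function(reps) {
  stopifnot(length(reps) >= 1L)
  if (is.null(names(reps))) names(reps) <- paste0("rep", seq_along(reps))
  structure(list(replicates = names(reps),
                 tables = lapply(reps, function(x) {
                   stats::setNames(x$count, x$key)
                 })),
            class = "sj_support")
}

#' Per-replicate unique-read counts for one junction
#'
#' Lookups are total: any junction yields a non-negative count per
#' replicate; missing junctions count 0. Strand-undefined (`*`) entries in
#' the support table match queries on either strand.
#'
#' @param sj An `sj_support` object.
#' @param key Junction key `"chrom:strand:start-end"`.
#' @return Named numeric vector, one count per replicate.
#' @export
sj_counts <- function(sj, key) {
  nostrand <- sub("^([^:]+):[+-]:", "\\1:*:", key)
  vapply(sj$tables, function(tab) {
    v <- tab[key]
    if (is.na(v)) v <- tab[nostrand]
    if (is.na(v)) 0 else unname(v)
  }, numeric(1))
}

#' Read a polyA motif list
#'
#' Plain text, one motif per line; motifs are uppercased and searched by
#' exact match in list order (list order breaks ties).
#'
#' @param path Path to the motif file.
#' @return Character vector of motifs.
#' @export
load_polya_motifs <- function(path) {
  m <- toupper(trimws(readLines(path)))
  m[nzchar(m)]
}

#' Write the classification / junction tables
#'
#' Tab-separated, one header row, one row per transcript (or junction).
#' Logical columns serialize as `TRUE`/`FALSE`; `read_table_tsv()` restores
#' them.
#'
#' @param records data.frame of records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_classification_table
#' @export
write_junction_table <- write_classification_table

#' @rdname write_classification_table
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
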