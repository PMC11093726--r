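#' Short-read TSS ratio
#'
#' Ratio of mean short-read coverage in the `window` bp just downstream of
#' the TSS (inside the first exon) to the mean coverage in the `window` bp
#' just upstream (outside), with a 0.01 pseudocount on both terms:
#' `(inside + 0.01) / (outside + 0.01)`. One ratio is computed per coverage
#' replicate and the replicate values are aggregated (the highest is
#' retained by default; mean, median and third quartile are available).
#' A ratio near 1 is what a 5'-degraded end looks like; a genuine TSS shows
#' depleted upstream coverage and a ratio well above 1. Windows extending
#' past the chromosome start are clipped; a zero-length clip counts as
#' coverage 0.
#'
#' @param tss 0-based genomic position of the first transcribed base.
#' @param strand `"+"` or `"-"`.
#' @param chrom Chromosome name.
#' @param coverage List of `coverage_track` objects (one per replicate).
#' @param window Window width in bp (default 100).
#' @param aggregate Aggregation across replicates: `"max"` (default),
#'   `"mean"`, `"median"`, `"q3"`.
#' @return Aggregated TSS ratio (positive).
#' @export
compute_tss_ratio <- function(tss, strand, chrom, coverage, window = 100,
                              aggregate = c("max", "mean", "median", "q3")) {
  aggregate <- match.arg(aggregate)
  stopifnot(window >= 1, length(coverage) >= 1L)
  if (strand == "+") {
    inside <- c(tss, tss + window)
    outside <- c(tss - window, tss)
  } else {
    inside <- c(tss + 1 - window, tss + 1)
    outside <- c(tss + 1, tss + 1 + window)
  }
  ratios <- vapply(coverage, function(tr) {
    ci <- coverage_mean(tr, chrom, max(0, inside[1L]), inside[2L])
    co <- coverage_mean(tr, chrom, max(0, outside[1L]), outside[2L])
    (ci + 0.01) / (co + 0.01)
  }, numeric(1))
  switch(aggregate,
         max = max(ratios),
         mean = mean(ratios),
         median = stats::median(ratios),
         q3 = unname(stats::quantile(ratios, 0.75)))
}

#' Intrapriming detection
#'
#' Computes the adenine fraction of the strand-aware genomic window
#' immediately downstream of the reported TTS (reverse-complemented on the
#' minus strand) and flags the transcript as a likely intrapriming artifact
#' when the fraction reaches `threshold` (inclusive). Windows clipped at the
#' chromosome edge use the available sequence; an empty window gives
#' fraction 0 and no flag.
#'
#' @param tts 0-based genomic position of the last transcribed base.
#' @param strand `"+"` or `"-"`.
#' @param chrom Chromosome name.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param window Downstream window in bp (default 20).
#' @param threshold Adenine fraction at or above which the flag is raised
#'   (default 0.60).
#' @return List with `perc_A` (fraction in \[0,1\]) and `flag` (logical).
#' @export
compute_intrapriming <- function(tts, strand, chrom, genome, window = 20,
                                 threshold = 0.60) {
  genome <- genome_chars(genome)
  s <- if (strand == "+") {
    genome_slice(genome, chrom, tts + 1, tts + 1 + window)
  } else {
    sl <- genome_slice(genome, chrom, tts - window, tts)
    if (nzchar(sl)) revcomp_chr(sl) else sl
  }
  if (!nzchar(s)) return(list(perc_A = 0, flag = FALSE))
  perc_A <- sum(strsplit(s, "")[[1L]] == "A") / nchar(s)
  list(perc_A = perc_A, flag = perc_A >= threshold)
}

#' Search the transcript 3' end for a polyadenylation motif
#'
#' Scans the spliced, strand-corrected transcript sequence for the supplied
#' motifs; a hit is reported when the motif's end lies within the final
#' `window` bases (distance from motif end to 3' end in `[0, window]`). The
#' motif ending closest to the 3' end wins; ties are broken by motif list
#' order. Transcripts shorter than the window are scanned whole.
#'
#' @param transcript_seq Spliced transcript sequence (5'→3'), character.
#' @param motifs Character vector of motifs, in priority order.
#' @param window Terminal window in bp (default 50).
#' @return List with `motif` and `polyA_dist` (bases from motif end to the
#'   3' end), or `NULL` when no motif qualifies.
#' @export
find_polya_motif <- function(transcript_seq, motifs, window = 50) {
  stopifnot(length(motifs) >= 1L)
  s <- toupper(transcript_seq)
  L <- nchar(s)
  best <- NULL
  for (mi in seq_along(motifs)) {
    m <- motifs[mi]
    hits <- gregexpr(m, s, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) next
    ends <- hits + nchar(m) - 1L
    dists <- L - ends
    ok <- dists >= 0 & dists <= window
    if (!any(ok)) next
    d <- min(dists[ok])
    if (is.null(best) || d < best$polyA_dist)
      best <- list(motif = m, polyA_dist = d)
  }
  best
}

#' Peak support for a transcript end
#'
#' Checks whether a TSS or TTS falls inside a peak region and measures the
#' signed distance to the midpoint of the nearest eligible peak. Eligible
#' peaks have their midpoint upstream of the TSS (`side = "five_prime"`) or
#' downstream of the TTS (`side = "three_prime"`), in transcription
#' direction; a peak containing the end is always eligible. Upstream
#' distances are negative, downstream positive.
#'
#' @param pos 0-based genomic position of the end.
#' @param strand `"+"` or `"-"`.
#' @param chrom Chromosome name.
#' @param peaks A `peak_set` (see [load_bed_peaks()]).
#' @param side `"five_prime"` or `"three_prime"`.
#' @return List with `within` (logical) and `dist` (signed bp or `NA` when
#'   no eligible peak exists).
#' @export
peak_support <- function(pos, strand, chrom, peaks,
                         side = c("five_prime", "three_prime")) {
  side <- match.arg(side)
  p <- peaks[peaks$chrom == chrom &
               (peaks$strand == "*" | peaks$strand == strand), , drop = FALSE]
  if (nrow(p) == 0L) return(list(within = FALSE, dist = NA_real_))
  contains <- p$start <= pos & pos < p$end
  dist <- vapply(p$mid, signed_end_diff, numeric(1), query_pos = pos,
                 strand = strand)
  # dist = signed offset of the end relative to the peak midpoint; the peak
  # midpoint is upstream of the end when dist > 0.
  eligible <- if (side == "five_prime") dist >= 0 | contains else
    dist <= 0 | contains
  if (!any(eligible)) return(list(within = any(contains), dist = NA_real_))
  d_end_to_mid <- -dist  # signed distance from the end to the midpoint
  cand <- which(eligible)
  best <- cand[which.min(abs(d_end_to_mid[cand]))]
  list(within = any(contains), dist = d_end_to_mid[best])
}

CANONICAL_SPLICE_MOTIFS <- c("GT-AG", "GC-AG", "AT-AC")

#' Junction-level QC
#'
#' Splice-site dinucleotide motif (strand-corrected, donor-acceptor as in
#' `"GT-AG"`), canonical status (motif in GT-AG / GC-AG / AT-AC), and
#' per-replicate plus total short-read support.
#'
#' @param key Junction key `"chrom:strand:start-end"` (0-based half-open
#'   intron).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param sj An `sj_support` object, or `NULL` for no short-read data.
#' @return List with `splice_motif`, `canonical`, `sample_cov` (named per
#'   replicate) and `total_cov`.
#' @export
junction_qc <- function(key, genome, sj = NULL) {
  genome <- genome_chars(genome)
  parts <- strsplit(key, ":", fixed = TRUE)[[1L]]
  chrom <- parts[1L]; strand <- parts[2L]
  j <- as.numeric(strsplit(parts[3L], "-", fixed = TRUE)[[1L]])
  left <- genome_slice(genome, chrom, j[1L], j[1L] + 2)
  right <- genome_slice(genome, chrom, j[2L] - 2, j[2L])
  motif <- if (strand == "+") paste0(left, "-", right) else
    paste0(revcomp_chr(right), "-", revcomp_chr(left))
  cov <- if (is.null(sj)) numeric(0) else sj_counts(sj, key)
  list(splice_motif = motif,
       canonical = motif %in% CANONICAL_SPLICE_MOTIFS,
       sample_cov = cov,
       total_cov = sum(cov))
}

#' Reverse-transcriptase template switching flag
#'
#' Flags a junction when an exact direct repeat of at least `repeat_len`
#' nucleotides is shared between the sequence around the donor exon/intron
#' boundary and the sequence around the acceptor intron/exon boundary
#' (windows of `repeat_len` nt on each side of both boundaries). Such
#' repeats allow the reverse transcriptase to switch templates and fabricate
#' the junction.
#'
#' @param key Junction key `"chrom:strand:start-end"`.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param repeat_len Minimum exact repeat length in nt (default 8).
#' @return Logical.
#' @export
rts_flag <- function(key, genome, repeat_len = 8) {
  genome <- genome_chars(genome)
  parts <- strsplit(key, ":", fixed = TRUE)[[1L]]
  chrom <- parts[1L]
  j <- as.numeric(strsplit(parts[3L], "-", fixed = TRUE)[[1L]])
  donor_win <- genome_slice(genome, chrom, j[1L] - repeat_len, j[1L] + repeat_len)
  accep_win <- genome_slice(genome, chrom, j[2L] - repeat_len, j[2L] + repeat_len)
  kd <- kmers(donor_win, repeat_len)
  ka <- kmers(accep_win, repeat_len)
  length(intersect(kd, ka)) > 0L
}

kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  vapply(seq_len(n - k + 1L), function(i) substr(s, i, i + k - 1L), character(1))
}

#' QC parameter defaults
#'
#' All tunable thresholds of the QC/filter stages in one place, overridable
#' per call.
#'
#' @param ref_match_window FSM reference-match end window, bp.
#' @param intrapriming_window Downstream A-content window, bp.
#' @param intrapriming_threshold A-fraction flag threshold.
#' @param polya_window Terminal polyA motif search window, bp.
#' @param tss_ratio_window TSS-ratio coverage window, bp.
#' @param tss_ratio_aggregate Replicate aggregation for the TSS ratio.
#' @param rts_repeat_len RTS direct-repeat length, nt.
#' @param min_junction_support Default-rules minimum short-read support.
#' @param ml_threshold Machine-learning isoform probability threshold.
#' @param min_ref_len Minimum reference spliced length, bp.
#' @return Named list of parameters.
#' @export
qc_params <- function(ref_match_window = 50,
                      intrapriming_window = 20,
                      intrapriming_threshold = 0.60,
                      polya_window = 50,
                      tss_ratio_window = 100,
                      tss_ratio_aggregate = "max",
                      rts_repeat_len = 8,
                      min_junction_support = 3,
                      ml_threshold = 0.7,
                      min_ref_len = 200) {
  list(ref_match_window = ref_match_window,
       intrapriming_window = intrapriming_window,
       intrapriming_threshold = intrapriming_threshold,
       polya_window = polya_window,
       tss_ratio_window = tss_ratio_window,
       tss_ratio_aggregate = tss_ratio_aggregate,
       rts_repeat_len = rts_repeat_len,
       min_junction_support = min_junction_support,
       ml_threshold = ml_threshold,
       min_ref_len = min_ref_len)
}

#' Compute the full classification and junction tables
#'
#' Runs the structural classifier and every QC attribute over a query set,
#' producing the transcript-level classification table and the
#' junction-level table consumed by the filter and rescue stages.
#'
#' @param queries Named list of `transcript_model` objects.
#' @param index A `reference_index`.
#' @param genome Named [Biostrings::DNAStringSet], or `NULL` to skip
#'   sequence-based attributes.
#' @param cage_peaks,polya_peaks Optional `peak_set`s for 5' and 3' support.
#' @param polya_motifs Optional character vector of polyA motifs.
#' @param coverage Optional list of `coverage_track`s.
#' @param sj Optional `sj_support`.
#' @param params See [qc_params()].
#' @return List with `classification` and `junctions` data.frames.
#' @export
compute_qc_tables <- function(queries, index, genome = NULL,
                              cage_peaks = NULL, polya_peaks = NULL,
                              polya_motifs = NULL, coverage = NULL, sj = NULL,
                              params = qc_params()) {
  if (!is.null(genome)) genome <- genome_chars(genome)
  cls <- classify_transcripts(queries, index,
                              ref_match_window = params$ref_match_window)
  n <- nrow(cls)
  cls$ratio_TSS <- NA_real_
  cls$perc_A_downstream_TTS <- NA_real_
  cls$intrapriming <- FALSE
  cls$polyA_motif <- NA_character_
  cls$polyA_dist <- NA_real_
  cls$polyA_motif_found <- FALSE
  cls$within_CAGE_peak <- FALSE
  cls$dist_to_CAGE_peak <- NA_real_
  cls$within_polyA_site <- FALSE
  cls$dist_to_polyA_site <- NA_real_
  cls$all_canonical <- TRUE
  cls$min_cov <- NA_real_
  cls$RTS_stage <- FALSE

  jrows <- list()
  rep_ids <- if (is.null(sj)) character(0) else sj$replicates

  for (i in seq_len(n)) {
    tm <- queries[[i]]
    tss <- tm_tss(tm); tts <- tm_tts(tm)
    if (!is.null(coverage) && length(coverage) > 0L) {
      cls$ratio_TSS[i] <- compute_tss_ratio(tss, tm$strand, tm$chrom, coverage,
                                            window = params$tss_ratio_window,
                                            aggregate = params$tss_ratio_aggregate)
    }
    if (!is.null(genome)) {
      ip <- compute_intrapriming(tts, tm$strand, tm$chrom, genome,
                                 window = params$intrapriming_window,
                                 threshold = params$intrapriming_threshold)
      cls$perc_A_downstream_TTS[i] <- ip$perc_A
      cls$intrapriming[i] <- ip$flag
      if (!is.null(polya_motifs)) {
        hit <- find_polya_motif(tm_sequence(tm, genome), polya_motifs,
                                window = params$polya_window)
        if (!is.null(hit)) {
          cls$polyA_motif[i] <- hit$motif
          cls$polyA_dist[i] <- hit$polyA_dist
          cls$polyA_motif_found[i] <- TRUE
        }
      }
    }
    if (!is.null(cage_peaks)) {
      ps <- peak_support(tss, tm$strand, tm$chrom, cage_peaks, "five_prime")
      cls$within_CAGE_peak[i] <- ps$within
      cls$dist_to_CAGE_peak[i] <- ps$dist
    }
    if (!is.null(polya_peaks)) {
      ps <- peak_support(tts, tm$strand, tm$chrom, polya_peaks, "three_prime")
      cls$within_polyA_site[i] <- ps$within
      cls$dist_to_polyA_site[i] <- ps$dist
    }
    keys <- junction_keys(tm)
    if (length(keys) > 0L) {
      covs <- numeric(length(keys))
      for (k in seq_along(keys)) {
        jq <- if (is.null(genome)) {
          list(splice_motif = NA_character_, canonical = NA,
               sample_cov = if (is.null(sj)) numeric(0) else sj_counts(sj, keys[k]),
               total_cov = if (is.null(sj)) NA_real_ else sum(sj_counts(sj, keys[k])))
        } else {
          junction_qc(keys[k], genome, sj)
        }
        rts <- if (is.null(genome)) FALSE else
          rts_flag(keys[k], genome, repeat_len = params$rts_repeat_len)
        covs[k] <- if (is.null(sj)) NA_real_ else jq$total_cov
        if (isFALSE(jq$canonical)) cls$all_canonical[i] <- FALSE
        if (rts) cls$RTS_stage[i] <- TRUE
        jc <- parse_junction_key(keys[k])
        jrows[[length(jrows) + 1L]] <- c(
          list(isoform = tm$transcript_id, junction_number = k,
               chrom = tm$chrom, strand = tm$strand,
               genomic_start = jc[1L], genomic_end = jc[2L],
               splice_motif = jq$splice_motif, canonical = jq$canonical,
               RTS_junction = rts, total_coverage = covs[k]),
          stats::setNames(as.list(jq$sample_cov),
                          paste0("cov_", rep_ids))[seq_along(rep_ids)])
      }
      if (!is.null(sj)) cls$min_cov[i] <- min(covs)
    }
  }
  junctions <- if (length(jrows) > 0L) {
    cols <- names(jrows[[1L]])
    out <- lapply(cols, function(cn) unlist(lapply(jrows, `[[`, cn),
                                            use.names = FALSE))
    names(out) <- cols
    as.data.frame(out, stringsAsFactors = FALSE)
  } else NULL
  list(classification = cls, junctions = junctions)
}
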